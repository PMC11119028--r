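# spiketer

Detecting **effective connectivity** — directed causal influence — between
pairs of neurons from their binary spike trains.

Functional measures such as cross-correlation cannot distinguish a genuine
synaptic drive from a shared input or a spurious dependence. `spiketer`
takes the information-theoretic route: for a pair of binarised spike trains
$(X, Y)$ modelled as a jointly stationary ergodic binary Markov chain with
memory at most $k$, the **transfer entropy rate**

$$T(X \to Y) \;=\; H(Y_0 \mid Y_{-k}^{-1}) \;-\; H(Y_0 \mid X_{-k}^{-1}, Y_{-k}^{-1})$$

is zero exactly when $Y$'s next symbol is conditionally independent of
$X$'s past given $Y$'s own past, i.e. when $X$ exerts no causal influence
on $Y$. The package

- estimates $T(X \to Y)$ by the **plug-in estimator** $\hat T_n^{(k)}$
  built from the empirical distribution of $(k{+}1)$-block pairs over $n$
  sliding windows;
- tests $H_0 : T(X \to Y) = 0$ with the likelihood-ratio statistic
  $\Delta_n = 2 n \hat T_n^{(k)}$, which under $H_0$ is asymptotically
  $\chi^2(d)$ with $d = 2^k(2^k - 1)$ degrees of freedom (at the default
  $k = 3$: $\chi^2(56)$);
- simulates networks of **stochastic neurons with variable-length memory**
  (Galves–Löcherbach type): each neuron fires with probability
  $\phi(v)$, where its membrane potential $v$ accumulates geometrically
  leaked synaptic input since its last spike and resets to 0 on firing;
- provides **exact small-network oracles** — the enumerated joint
  transition kernel, its stationary law, stationary firing rates and the
  exact transfer entropy rate — used to validate both the simulator and
  the estimator;
- runs the Monte-Carlo **power and size studies** that validate the test
  (rejection tables over sample sizes and significance levels,
  goodness-of-fit of the null statistic against $\chi^2(56)$, box-plot
  summaries of the estimated rates).

It is aimed at researchers analysing paired spike trains (typically 10 ms
bins) who want a parametric causality test with a known null distribution
instead of surrogate-data resampling.

## Worked example

Simulate the strong-excitatory benchmark microcircuit
($\omega_{x \to y} = 10$, $\omega_{y \to x} = 0$, memory $K = 3$,
offset-logistic $\phi$ with $c = \ln 4$ and calibrated baseline
$\beta = -2\ln 4$), then test both directions:

```r
library(spiketer)

net    <- scenario_network(1)                       # w_xy = 10, w_yx = 0
trains <- simulate_network(net, n = 40000, seed = 42)
round(colMeans(trains), 3)
#>     x     y
#> 0.501 0.698

te_causality_test(trains, x, y, k = 3, alpha = 0.05)
#> direction: x -> y   (k = 3, n = 40000)
#> Delta = 6350.1985, df = 56, p-value = 0
#> plug-in transfer entropy rate: 0.0793775 nats
#> decision at alpha = 0.05: reject (causal influence detected)

te_causality_test(trains, y, x, k = 3, alpha = 0.05)
#> direction: y -> x   (k = 3, n = 40000)
#> Delta = 48.1998, df = 56, p-value = 0.7613
#> plug-in transfer entropy rate: 0.000602497 nats
#> decision at alpha = 0.05: do not reject
```

The driven direction produces a statistic thousands of units above the
$\chi^2(56)$ critical value; the feedback-free direction lands squarely in
the bulk of the null distribution ($E[\chi^2(56)] = 56$). The exact oracle
confirms what the sample estimates:

```r
ker <- exact_joint_kernel(net)
ter_exact(ker)                          # 0.07561008  (x -> y)
ter_exact(ker, source = "y", target = "x")  # 0        (y -> x)
stationary_rate(ker, "x")               # 0.5  (input-free neuron)
```

Monte-Carlo power studies wrap the whole loop:

```r
study <- run_power_study(scenario_spec(1, n = c(5000, 20000),
                                       replicates = 100))
power_table_wide(study)   # rejection counts per direction, n, level
autoplot(study)           # power/size curves
```

Raw recordings enter through `bin_spike_times()` (spike times to 0/1
bins) and `read_spike_trains()` (plain-text or CSV); a command-line front
end with `simulate` / `test` / `power` / `nullcheck` verbs lives in
`inst/cli/spiketer.R`.

## Documentation

The methods vignette (`vignettes/transfer-entropy-causality.Rmd`) derives
the model, the estimator and the test, states all default parameters and
the reasoning behind them, and spells out what the simulation benchmarks
do and do not establish about real recordings.
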