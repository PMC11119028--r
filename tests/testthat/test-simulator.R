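test_that("identical seeds give bit-identical trajectories", {
  net <- scenario_network(1)
  a <- simulate_network(net, n = 2000, seed = 11)
  b <- simulate_network(net, n = 2000, seed = 11)
  expect_identical(a, b)
  c <- simulate_network(net, n = 2000, seed = 12)
  expect_false(identical(a, c))
  expect_equal(nrow(a), 2000 + net$memory)
})

test_that("context-free network is iid Bernoulli(phi(0))", {
  net <- network_spec(matrix(0, 2, 2), beta = 0, phi = phi_spec(offset = log(4)))
  tr <- simulate_network(net, n = 1e5, seed = 3)
  for (col in c("x", "y")) {
    r <- mean(tr[[col]])
    expect_lt(abs(r - 0.8), 4 * sqrt(0.8 * 0.2 / nrow(tr)))
  }
  # lag-1 autocorrelation should also vanish for an iid train
  x <- tr$x
  expect_lt(abs(cor(x[-1], x[-length(x)])), 4 / sqrt(length(x)))
})

test_that("zero coupling gives statistically independent trains", {
  net <- two_neuron_network(w_xy = 0, w_yx = 0)
  tr <- simulate_network(net, n = 1e5, seed = 7)
  x <- tr$x - mean(tr$x)
  y <- tr$y - mean(tr$y)
  n <- nrow(tr)
  for (lag in 0:net$memory) {
    cc <- mean(head(x, n - lag) * tail(y, n - lag)) /
      (stats::sd(tr$x) * stats::sd(tr$y))
    expect_lt(abs(cc), 4 / sqrt(n - lag))
  }
})

test_that("a spike resets the potential: next-spike frequency is phi(0)", {
  net <- scenario_network(2)
  tr <- simulate_network(net, n = 1e5, seed = 5)
  for (col in c("x", "y")) {
    v <- tr[[col]]
    after_spike <- v[-1][v[-length(v)] == 1]
    phat <- mean(after_spike)
    se <- sqrt(0.8 * 0.2 / length(after_spike))
    expect_lt(abs(phat - 0.8), 3 * se)
  }
})

test_that("empirical rates agree with the exact stationary oracle", {
  for (sc in 1:4) {
    net <- scenario_network(sc)
    ker <- exact_joint_kernel(net)
    tr <- simulate_network(net, n = 2e5, seed = 100 + sc)
    for (col in c("x", "y")) {
      r_exact <- stationary_rate(ker, col)
      se <- batch_se(tr[[col]], batches = 200)
      expect_lt(abs(mean(tr[[col]]) - r_exact), 3 * se)
    }
  }
})

test_that("compiled and pure-R recursions produce identical spike trains", {
  net <- two_neuron_network(w_xy = 5, w_yx = -2)
  total <- net$memory + 50 + 500
  set.seed(42)
  u <- matrix(runif(total * 2), total, 2)
  x_cpp <- spiketer:::sim_gl_logistic(u, net$weights, net$beta,
                                      net$phi$offset, net$memory)
  x_r <- spiketer:::sim_gl_r(u, net)
  expect_identical(unname(x_cpp), unname(x_r))
})

test_that("custom spiking-rate families go through the reference simulator", {
  phi_c <- phi_spec("custom", fn = function(u) 1 / (1 + exp(-(u + log(4)))))
  net_c <- two_neuron_network(w_xy = 2, phi = phi_c)
  net_l <- two_neuron_network(w_xy = 2)
  a <- simulate_network(net_c, n = 300, burn_in = 50, seed = 9)
  b <- simulate_network(net_l, n = 300, burn_in = 50, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("input-free neuron fires at 50% with the calibrated baseline", {
  net <- scenario_network(1)
  tr <- simulate_network(net, n = 1e5, seed = 21)
  expect_lt(abs(mean(tr$x) - 0.5), 0.01)
})
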