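test_that("degrees of freedom follow 2^k (2^k - 1)", {
  expect_identical(degrees_of_freedom(1), 2L)
  expect_identical(degrees_of_freedom(2), 12L)
  expect_identical(degrees_of_freedom(3), 56L)
  expect_error(degrees_of_freedom(0), "positive")
  expect_error(degrees_of_freedom(-2), "positive")
})

test_that("statistic is 2n times the plug-in estimate by definition", {
  tr <- simulate_network(scenario_network(2), n = 3000, seed = 14)
  bc <- suppressWarnings(count_blocks(tr, x, y, k = 3))
  expect_equal(lr_statistic(bc),
               2 * attr(bc, "n") * te_rate_plugin(bc)$value)
})

test_that("entropy and likelihood routes to the statistic coincide", {
  set.seed(15)
  cases <- expand.grid(k = 1:3, n = c(100L, 1000L, 10000L))
  nets <- list(two_neuron_network(w_xy = 10),
               two_neuron_network(w_xy = 0.375),
               two_neuron_network(w_xy = 0))
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]
    n <- cases$n[i]
    for (j in seq_along(nets)) {
      tr <- simulate_network(nets[[j]], n = n, burn_in = 200,
                             seed = 1000 * i + j)
      bc <- suppressWarnings(count_blocks(tr, x, y, k = k))
      d1 <- lr_statistic(bc)
      d2 <- lr_statistic_direct(bc)
      expect_lt(abs(d1 - d2), 1e-8 * max(1, d1))
    }
  }
})

test_that("degenerate samples give a zero statistic in both routes", {
  df <- tibble::tibble(x = rep(1L, 30), y = rep(0L, 30))
  bc <- suppressWarnings(count_blocks(df, x, y, k = 2))
  expect_equal(lr_statistic(bc), 0)
  expect_equal(lr_statistic_direct(bc), 0)
})

test_that("p-value mapping reproduces the worked chi-squared(56) values", {
  expect_equal(round(lr_p_value(51.08, k = 3), 4), 0.6612)
  expect_lt(lr_p_value(5881.70, k = 3), 1e-100)
  expect_equal(lr_p_value(0, k = 3), 1)
  expect_error(lr_p_value(-1, k = 3), "non-negative")
})

test_that("p-value is strictly decreasing in the statistic", {
  # strict decrease wherever the upper tail is resolvable in double precision
  deltas <- seq(15, 150, by = 5)
  p <- lr_p_value(deltas, k = 3)
  expect_true(all(diff(p) < 0))
  # and non-increasing from 0 out into the far tail
  expect_true(all(diff(lr_p_value(c(0, seq(5, 2000, by = 50)), k = 3)) <= 0))
})

test_that("test decision is reject iff p <= alpha", {
  tr <- simulate_network(scenario_network(1), n = 5000, seed = 17)
  res <- te_causality_test(tr, x, y, k = 3, alpha = 0.05)
  expect_true(res$reject)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$delta, 500)  # strong coupling: statistic far beyond critical
  null_res <- te_causality_test(tr, y, x, k = 3, alpha = 0.05)
  expect_equal(null_res$reject, null_res$p_value <= 0.05)
  # boundary: alpha exactly at the observed p rejects (p <= alpha rule)
  at <- te_causality_test(tr, y, x, k = 3, alpha = null_res$p_value)
  expect_true(at$reject)
  expect_error(te_causality_test(tr, x, y, alpha = 0), "alpha")
  expect_error(te_causality_test(tr, x, y, alpha = 1.2), "alpha")
})

test_that("small samples trigger the chi-squared guard warning", {
  tr <- simulate_network(scenario_network(1), n = 2000, seed = 18)
  expect_warning(res <- te_causality_test(tr, x, y, k = 3), "50 \\* 4\\^k")
  expect_true(any(grepl("chi-squared", res$warnings)))
  big <- simulate_network(scenario_network(1), n = 4000, seed = 18)
  expect_no_warning(te_causality_test(big, x, y, k = 3))
})

test_that("tidy/glance and the JSON report expose the full result", {
  tr <- simulate_network(scenario_network(1), n = 4000, seed = 19)
  res <- te_causality_test(tr, x, y, k = 3)
  td <- tidy(res)
  expect_named(td, c("source", "target", "k", "n", "te_rate", "statistic",
                     "df", "p.value", "alpha", "reject"))
  expect_equal(glance(res), td)
  f <- tempfile(fileext = ".json")
  write_test_report(res, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$direction, "x -> y")
  expect_equal(rep$df, 56L)
  expect_equal(rep$delta, res$delta)
  expect_equal(rep$reject, TRUE)
})
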