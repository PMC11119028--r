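small_spec <- function(scenario, ...) {
  scenario_spec(scenario, n = 1000L, replicates = 4L, burn_in = 200L,
                base_seed = 99L, ...)
}

test_that("power studies are bit-for-bit reproducible from the base seed", {
  a <- suppressWarnings(run_power_study(small_spec(1)))
  b <- suppressWarnings(run_power_study(small_spec(1)))
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$rejections, b$rejections)
  expect_true(all(c("seed", "replicate", "p_value") %in% names(a$estimates)))
  # seeds are recorded and distinct across replicates
  expect_equal(anyDuplicated(a$estimates$seed[a$estimates$direction == "x->y"]),
               0L)
})

test_that("rejection counts are consistent with per-replicate p-values", {
  ps <- suppressWarnings(run_power_study(small_spec(1)))
  for (i in seq_len(nrow(ps$rejections))) {
    row <- ps$rejections[i, ]
    sel <- ps$estimates$direction == row$direction & ps$estimates$n == row$n
    expect_equal(row$rejected, sum(ps$estimates$p_value[sel] <= row$alpha))
    expect_lte(row$rejected, row$replicates)
  }
  wide <- power_table_wide(ps)
  expect_equal(nrow(wide), 2L)  # two directions x one sample size
  expect_true(all(c("alpha=0.1%", "alpha=10%") %in% names(wide)))
})

test_that("power grows with sample size under weak coupling", {
  # weak-coupling power is calibration-sensitive, so this checks monotonicity
  # and that power clearly exceeds the nominal size, not exact cell values
  spec_lo <- scenario_spec(2, n = 5000L, replicates = 25L, alpha = 0.05,
                           burn_in = 500L, base_seed = 7L)
  spec_hi <- scenario_spec(2, n = 40000L, replicates = 25L, alpha = 0.05,
                           burn_in = 500L, base_seed = 7L)
  lo <- run_power_study(spec_lo)
  hi <- run_power_study(spec_hi)
  r_lo <- lo$rejections$rejected[lo$rejections$direction == "x->y"]
  r_hi <- hi$rejections$rejected[hi$rejections$direction == "x->y"]
  # non-decreasing within 2 binomial standard errors
  se <- sqrt(25 * 0.5 * 0.5)
  expect_gt(r_hi, r_lo - 2 * se)
  expect_gt(r_hi, 25 * 0.05 + 3 * sqrt(25 * 0.05 * 0.95))  # power >> size
})

test_that("estimated TER medians order by coupling strength", {
  # n large enough that the weak coupling clears the plug-in bias floor
  run1 <- run_power_study(scenario_spec(1, n = 40000L, replicates = 15L,
                                        burn_in = 500L, base_seed = 3L))
  run2 <- run_power_study(scenario_spec(2, n = 40000L, replicates = 15L,
                                        burn_in = 500L, base_seed = 3L))
  run4 <- run_power_study(scenario_spec(4, n = 40000L, replicates = 15L,
                                        burn_in = 500L, base_seed = 3L))
  s1 <- ter_distribution_summary(run1)
  s2 <- ter_distribution_summary(run2)
  s4 <- ter_distribution_summary(run4)
  med <- function(s, dir) s$median[s$direction == dir]
  expect_gt(med(s1, "x->y"), med(s2, "x->y"))   # strong > weak coupling
  expect_gt(med(s2, "x->y"), med(s2, "y->x"))   # weak coupling > null
  # the two strong-coupling scenarios have medians of similar magnitude
  expect_lt(abs(log(med(s1, "x->y") / med(s4, "x->y"))), log(3))
  # null-direction medians sit near the chi-squared median ~ df / (2n)
  expect_lt(med(s1, "y->x"), 3 * 56 / (2 * 40000))
  expect_named(s1, c("scenario", "direction", "n", "min", "q1", "median",
                     "q3", "max"))
})

test_that("null checks demand a direction with zero coupling", {
  expect_error(null_distribution_check(small_spec(2), direction = "x->y"),
               "nonzero coupling")
  expect_no_error(suppressWarnings(
    null_distribution_check(small_spec(1), direction = "y->x")))
})

test_that("single-replicate null checks are flagged unreliable", {
  spec <- scenario_spec(1, n = 1000L, replicates = 1L, burn_in = 200L)
  nc <- suppressWarnings(null_distribution_check(spec))
  expect_false(nc$reliable)
  expect_true(is.na(nc$ks_statistic))
  expect_equal(nc$replicates, 1L)
})

test_that("null-direction statistics match chi-squared moments at modest n", {
  spec <- scenario_spec(1, n = 5000L, replicates = 40L, burn_in = 500L,
                        base_seed = 5L)
  nc <- null_distribution_check(spec, direction = "y->x")
  expect_equal(nc$df, 56L)
  se_mean <- sqrt(2 * 56 / 40)
  expect_lt(abs(nc$mean - 56), 3 * se_mean)
  expect_true(nc$reliable)
  g <- glance(nc)
  expect_equal(g$replicates, 40L)
})

test_that("power tables round-trip through disk", {
  ps <- suppressWarnings(run_power_study(small_spec(1)))
  tsv <- tempfile(fileext = ".tsv")
  csv <- tempfile(fileext = ".csv")
  write_power_table(ps, tsv, long_csv = csv)
  back <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(nrow(back), nrow(power_table_wide(ps)))
  long <- utils::read.csv(csv)
  expect_equal(nrow(long), nrow(ps$rejections))
})

test_that("autoplot methods return ggplot objects", {
  ps <- suppressWarnings(run_power_study(small_spec(1)))
  expect_s3_class(autoplot(ps), "ggplot")
  expect_s3_class(autoplot(ps, type = "ter"), "ggplot")
  nc <- suppressWarnings(null_distribution_check(small_spec(1)))
  expect_s3_class(autoplot(nc), "ggplot")
})
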