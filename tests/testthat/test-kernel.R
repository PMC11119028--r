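test_that("kernel rows are probability distributions for random networks", {
  set.seed(1)
  for (rep in 1:5) {
    w <- matrix(c(0, rnorm(1, 0, 3), rnorm(1, 0, 3), 0), 2, 2)
    net <- network_spec(w, beta = rnorm(2), memory = sample(1:3, 1))
    ker <- exact_joint_kernel(net)
    expect_equal(nrow(ker$prob), 4^net$memory)
    expect_true(all(ker$prob >= 0 & ker$prob <= 1))
    expect_true(all(abs(rowSums(ker$prob) - 1) < 1e-12))
  }
})

test_that("context-free dynamics give identical product-Bernoulli rows", {
  net <- network_spec(matrix(0, 2, 2), beta = 0, phi = phi_spec(offset = log(4)))
  ker <- exact_joint_kernel(net)
  row <- c(0.2 * 0.2, 0.2 * 0.8, 0.8 * 0.2, 0.8 * 0.8)
  for (s in seq_len(nrow(ker$prob))) {
    expect_equal(unname(ker$prob[s, ]), row)
  }
})

test_that("post-spike reset makes the target's rate phi(0) in every context", {
  ker <- exact_joint_kernel(scenario_network(1))
  k <- ker$k
  ns <- 2^k
  for (cx in 0:(ns - 1)) {
    for (cy in 0:(ns - 1)) {
      if (bitwAnd(cy, 2^(k - 1)) > 0) {  # y spiked at t - 1
        s <- cx * ns + cy + 1
        p_y <- ker$prob[s, 2] + ker$prob[s, 4]
        expect_equal(p_y, 0.8)
      }
    }
  }
})

test_that("state enumeration is guarded to two neurons", {
  w <- matrix(0, 3, 3)
  expect_error(exact_joint_kernel(network_spec(w)), "2 neurons")
})

test_that("vlmc_kernel validates its rows", {
  expect_error(vlmc_kernel(matrix(0.3, 4, 4), k = 1), "sum to 1")
  expect_error(vlmc_kernel(matrix(0.25, 8, 4), k = 1), "4 x 4")
  bad <- matrix(c(1.2, -0.2, 0, 0), 1, 4)[rep(1, 4), ]
  expect_error(vlmc_kernel(bad, k = 1), "\\[0, 1\\]")
})

test_that("stationary rate of an iid product kernel is the marginal p", {
  ker <- product_kernel(px = 0.3, py = 0.65)
  expect_equal(stationary_rate(ker, 1), 0.3, tolerance = 1e-10)
  expect_equal(stationary_rate(ker, "y"), 0.65, tolerance = 1e-10)
})

test_that("calibrated input-free neuron has stationary rate exactly 1/2", {
  ker <- exact_joint_kernel(scenario_network(1))
  expect_equal(stationary_rate(ker, "x"), 0.5, tolerance = 1e-12)
})

test_that("weak-coupling scenarios reproduce the 52% / 48% target rates", {
  r2 <- stationary_rate(exact_joint_kernel(scenario_network(2)), "y")
  r3 <- stationary_rate(exact_joint_kernel(scenario_network(3)), "y")
  expect_equal(round(100 * r2), 52)
  expect_equal(round(100 * r3), 48)
})

test_that("a reducible kernel has no unique stationary law", {
  # each joint symbol repeats itself forever: four absorbing states
  prob <- matrix(0, 4, 4)
  for (cx in 0:1) for (cy in 0:1) prob[cx * 2 + cy + 1, 2 * cx + cy + 1] <- 1
  ker <- vlmc_kernel(prob, k = 1)
  expect_error(stationary_rate(ker, 1), "reducible|no unique")
})

test_that("exact TER: product kernel 0, copy chain log 2, null direction 0", {
  expect_equal(ter_exact(product_kernel(0.4, 0.7)), 0, tolerance = 1e-12)
  expect_equal(ter_exact(copy_chain_kernel()), log(2), tolerance = 1e-12)
  ker1 <- exact_joint_kernel(scenario_network(1))
  expect_gt(ter_exact(ker1), 0)
  expect_equal(ter_exact(ker1, source = "y", target = "x"), 0,
               tolerance = 1e-12)
  ker0 <- exact_joint_kernel(two_neuron_network(w_xy = 0))
  expect_equal(ter_exact(ker0), 0, tolerance = 1e-12)
})
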