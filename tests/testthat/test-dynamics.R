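# Truncated drift structure, heterosynaptic competition, integration
# invariants, balance perturbation.

kp0 <- table1_kp()

test_that("balanced rule gives zero drift on an empty network", {
  ms <- motif_set(kp0, table1_sp(13), 150)
  D <- stdp_drift(matrix(0, 5, 5), ms, 150)
  expect_equal(max(abs(D)), 0)
})

test_that("first-order drift matches the hand-written reciprocal pair", {
  ms <- motif_set(kp0, table1_sp(3), 150)
  # keep only the first-order coefficients
  nm <- c("M11", "M20", "M02", "M21", "M12", "M30", "M03", "Mtrip_a2g0",
          "Mtrip_a1g1", "Mtrip_a2g1_plus_a1g2", "Mtrip_a3g0", "Mtrip_101",
          "Mtrip_111")
  for (x in nm) ms[[x]] <- 0
  W <- matrix(0, 2, 2); W[1, 2] <- 0.04; W[2, 1] <- 0.09
  r <- c(140, 160)
  D <- stdp_drift(W, ms, r)
  expect_equal(D[1, 2], r[2] * W[1, 2] * ms$M10 + r[1] * W[2, 1] * ms$M01)
  expect_equal(D[2, 1], r[1] * W[2, 1] * ms$M10 + r[2] * W[1, 2] * ms$M01)
})

test_that("second- and third-order terms match explicit index sums", {
  ms <- motif_set(kp0, table1_sp(9), 150)
  set.seed(5)
  n <- 6
  W <- matrix(stats::runif(n * n, 0, 0.15), n, n); diag(W) <- 0
  r <- stats::runif(n, 100, 200)
  D <- stdp_drift(W, ms, r)
  W2 <- W %*% W; W3 <- W2 %*% W
  i <- 2; j <- 5
  ks <- setdiff(1:n, c(i, j))
  expected <- ms$M10 * r[j] * W[i, j] + ms$M01 * r[i] * W[j, i] +
    ms$M11 * sum(r[ks] * W[i, ks] * W[j, ks]) +
    ms$M20 * r[j] * W2[i, j] + ms$M02 * r[i] * W2[j, i] +
    ms$M21 * sum(r[ks] * W2[i, ks] * W[j, ks]) +
    ms$M12 * sum(r[ks] * W[i, ks] * W2[j, ks]) +
    ms$M30 * r[j] * W3[i, j] + ms$M03 * r[i] * W3[j, i] +
    ms$Mtrip_a2g0 * r[i] * r[j] * sum(W[i, ks] * W[ks, i]) +
    ms$Mtrip_a1g1 * r[j] * sum(r[ks] * W[i, ks]^2) +
    ms$Mtrip_a2g1_plus_a1g2 * r[j] * sum(r[ks] * W2[i, ks] * W[i, ks]) +
    ms$Mtrip_a3g0 * r[i] * r[j] * W3[i, i] +
    ms$Mtrip_101 * r[j] * W[i, j]^2 +
    ms$Mtrip_111 * sum(r[ks] * W[i, ks]^2 * W[j, ks])
  expect_equal(D[i, j], expected, tolerance = 1e-12)
})

test_that("term masks select exactly their motif groups", {
  ms <- motif_set(kp0, table1_sp(13), 150)
  set.seed(6)
  W <- matrix(stats::runif(36, 0, 0.15), 6, 6); diag(W) <- 0
  W2 <- W %*% W; W3 <- W2 %*% W
  full <- stdp_drift(W, ms, 150)
  cross <- stdp_drift(W, ms, 150, term_mask(TRUE, FALSE, FALSE, FALSE))
  crloop <- stdp_drift(W, ms, 150, term_mask(TRUE, FALSE, TRUE, FALSE))
  loops_only <- crloop - cross
  n <- 6; one <- rep(1, n)
  d2 <- diag(W2); d3 <- diag(W3)
  exp_loops <- 150^2 * (ms$Mtrip_a2g0 * (outer(d2, one) - W * t(W)) +
                          ms$Mtrip_a3g0 * outer(d3, one))
  diag(exp_loops) <- 0
  expect_equal(loops_only, exp_loops, tolerance = 1e-12)
  # all four groups together reconstruct the full drift
  nl <- stdp_drift(W, ms, 150, term_mask(TRUE, TRUE, FALSE, FALSE)) - cross
  third <- stdp_drift(W, ms, 150, term_mask(TRUE, FALSE, FALSE, TRUE)) - cross
  expect_equal(cross + nl + loops_only + third, full, tolerance = 1e-12)
})

test_that("heterosynaptic competition pushes only overloaded sums", {
  cfg <- network_config(N = 4, W_max = 0.85)
  W <- matrix(0.1, 4, 4); diag(W) <- 0 # sums 0.3, below bound
  expect_equal(max(abs(heterosynaptic_drift(W, cfg))), 0)
  # overload column 2 by 0.1
  W2 <- W; W2[, 2] <- c(0.4, 0, 0.3, 0.25)
  D <- heterosynaptic_drift(W2, cfg)
  expect_equal(D[1, 2], 0.85 - sum(W2[, 2]))
  expect_equal(D[1, 2], -0.1, tolerance = 1e-12)
  expect_equal(D[3, 4], 0) # untouched row and column
})

test_that("initial weights are tiny, seeded and diagonal-free", {
  cfg <- network_config()
  W <- initial_weights(cfg, 99)
  expect_true(all(W <= 0.85 / 48 * 0.001))
  expect_true(all(W >= 0))
  expect_equal(diag(W), rep(0, 48))
  expect_identical(W, initial_weights(cfg, 99))
  expect_false(identical(W, initial_weights(cfg, 100)))
})

test_that("integration keeps bounds and caps row/column sums", {
  cfg <- network_config(N = 16, mu = 150, W_max = 0.4, w_max = 0.17)
  sim <- integrate_weights(initial_weights(cfg, 3), cfg, kp0,
                           table1_sp(13), keep_trajectory = TRUE,
                           max_steps = 20000L, on_nonconvergence = "warn")
  for (W in c(sim$trajectory, list(sim$W))) {
    expect_true(all(W >= 0 & W <= 0.17 + 1e-12))
    expect_equal(diag(W), rep(0, 16))
  }
  tol <- 0.05 # soft competition allows a small boundary overshoot
  expect_true(all(rowSums(sim$W) <= cfg$W_max + tol))
  expect_true(all(colSums(sim$W) <= cfg$W_max + tol))
})

test_that("depression-dominated imbalance collapses all weights", {
  cfg <- network_config(N = 16, delta = -1e-4)
  sim <- integrate_weights(initial_weights(cfg, 4), cfg, kp0,
                           table1_sp(13), on_nonconvergence = "warn")
  expect_lt(max(sim$W), 1e-6)
})

test_that("external drive biases in-block pairs toward potentiation", {
  cfg <- network_config(N = 6)
  Cx <- build_external_covariance(rep(1:2, each = 3), 0.25, cfg)
  D0 <- external_drive_drift(matrix(0, 6, 6), NULL, kp0, table1_sp(1), 150)
  expect_equal(max(abs(D0)), 0)
  D <- external_drive_drift(matrix(0, 6, 6), Cx, kp0, table1_sp(1), 150)
  expect_gt(D[1, 2], 0)       # common input potentiates block mates
  expect_equal(D[1, 4], 0)    # no drive across blocks at W = 0
})

test_that("rate tracking stays near the external rate under balance", {
  cfg <- network_config(N = 12)
  sim <- integrate_weights(initial_weights(cfg, 5), cfg, kp0,
                           table1_sp(13), rates_mode = "track",
                           max_steps = 4000L, on_nonconvergence = "warn")
  r <- stationary_rates(sim$W, cfg, kp0)
  expect_lt(max(abs(r - 150) / 150), 0.05)
})

test_that("tidy and glance summarize a simulation", {
  sim <- steady_run(13, 1)
  td <- tidy(sim)
  expect_equal(nrow(td), 48 * 48)
  gl <- glance(sim)
  expect_true(all(c("mean_clustering", "modularity") %in% names(gl)))
  expect_s3_class(autoplot(sim), "ggplot")
})
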