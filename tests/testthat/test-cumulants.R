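# Resolvent-based rates and cumulants, series truncations, the balanced
# effective matrix, and the full-order drift oracle.

kp0 <- table1_kp()

weak_random_W <- function(N, rho, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(N * N), N, N)
  diag(W) <- 0
  W * rho / max(Mod(eigen(W, only.values = TRUE)$values))
}

test_that("stationary rates: no recurrence, hand-solved 2x2, balance", {
  cfg <- network_config(N = 2, mu = 10)
  expect_equal(stationary_rates(matrix(0, 2, 2), cfg, kp0,
                                effective = FALSE), c(10, 10))
  W <- matrix(0, 2, 2); W[2, 1] <- 0.1
  expect_equal(stationary_rates(W, cfg, kp0, effective = FALSE), c(10, 11))
  # balanced effective matrix leaves rates at the external input
  cfg5 <- network_config(N = 5, mu = 150)
  set.seed(2)
  W5 <- matrix(stats::runif(25, 0, 0.15), 5, 5); diag(W5) <- 0
  expect_equal(stationary_rates(W5, cfg5, kp0, effective = TRUE),
               rep(150, 5), tolerance = 1e-10)
  # non-stationary matrix is refused
  Wbig <- matrix(0.9, 3, 3); diag(Wbig) <- 0
  expect_error(stationary_rates(Wbig, network_config(N = 3), kp0,
                                effective = FALSE), "non-stationary")
})

test_that("inhibitory balance: row-sum algebra", {
  cfg <- network_config(N = 4, delta_inh = 1)
  W <- matrix(0.1, 4, 4); diag(W) <- 0 # constant rows
  Weff <- inhibitory_balance(W, cfg)
  expect_equal(max(abs(Weff[row(Weff) != col(Weff)])), 0)
  set.seed(3)
  W <- matrix(stats::runif(16), 4, 4); diag(W) <- 0
  for (di in c(0.5, 1, 1.5)) {
    cfg$delta_inh <- di
    Weff <- inhibitory_balance(W, cfg)
    expect_equal(rowSums(Weff), (1 - di) * rowSums(W), tolerance = 1e-12)
  }
})

test_that("resolvent: identity at W = 0, geometric series, symmetry", {
  N <- 4
  expect_equal(resolvent(37, matrix(0, N, N), kp0), diag(N) + 0i)
  W <- weak_random_W(N, 0.3, 11)
  w <- 85
  R <- resolvent(w, W, kp0)
  G <- epsc_ft(w, kp0) * W
  S <- diag(N) + 0i
  P <- diag(N) + 0i
  for (k in 1:50) { P <- P %*% G; S <- S + P }
  expect_equal(R, S, tolerance = 1e-8)
  expect_equal(resolvent(-w, W, kp0), Conj(R))
})

test_that("cross-covariance: Poisson diagonal, Hermitian structure,
           series truncation converges at the expected order", {
  N <- 5
  r <- c(8, 10, 12, 9, 11)
  C0 <- cross_covariance_ft(50, matrix(0, N, N), r, kp0)
  expect_equal(C0, diag(r) + 0i)
  series_C <- function(w, W, r, ord) {
    out <- matrix(0i, nrow(W), nrow(W))
    Wp <- list(diag(nrow(W)))
    for (k in seq_len(ord)) Wp[[k + 1]] <- Wp[[k]] %*% W
    for (a in 0:ord) for (b in 0:(ord - a))
      out <- out + epsc_ft(w, kp0)^a * epsc_ft(-w, kp0)^b *
        (Wp[[a + 1]] %*% (r * t(Wp[[b + 1]])))
    out
  }
  err_at <- function(rho) {
    W <- weak_random_W(N, rho, 21)
    Cfull <- cross_covariance_ft(40, W, r, kp0)
    Cneg <- cross_covariance_ft(-40, W, r, kp0)
    expect_equal(Conj(Cneg), Cfull, tolerance = 1e-12)  # real covariance
    expect_equal(t(Cfull), Cneg, tolerance = 1e-12)     # pair exchange
    max(Mod(Cfull - series_C(40, W, r, 3))) / max(Mod(Cfull))
  }
  e1 <- err_at(0.3); e2 <- err_at(0.15)
  expect_lt(e1, 0.02)
  expect_gt(e1 / e2, 8) # fourth-order scaling: halving rho gains ~16x
})

test_that("third cumulant: Poisson limit and series truncation", {
  N <- 4
  r <- c(7, 9, 11, 13)
  K0 <- third_cumulant_ft(30, -45, matrix(0, N, N), r, kp0)
  expect_equal(K0, diag(r) + 0i)
  # path-length series with straight and branched contributions
  series_K <- function(w1, w2, W, r, ord = 2) {
    N <- nrow(W)
    e <- function(w) epsc_ft(w, kp0)
    Wp <- list(diag(N)); for (k in 1:ord) Wp[[k + 1]] <- Wp[[k]] %*% W
    out <- matrix(0i, N, N)
    for (a in 0:ord) for (b in 0:(ord - a)) for (g in 0:(ord - a - b))
      out <- out + e(w1 + w2)^a * e(-w1)^b * e(-w2)^g *
        ((Wp[[a + 1]] * Wp[[g + 1]]) %*% (r * t(Wp[[b + 1]])))
    for (z in 1:ord) for (a in 0:(ord - z)) for (b in 0:(ord - z - a))
      for (g in 0:(ord - z - a - b)) {
        Wa <- Wp[[a + 1]]; Wb <- Wp[[b + 1]]; Wg <- Wp[[g + 1]]
        Wz <- Wp[[z + 1]]
        # branch on the current-post path
        Y <- Wa %*% (r * t(Wz))
        out <- out + e(w1 + w2)^(a + z) * e(-w1)^b * e(-w2)^g *
          ((Y * Wg) %*% t(Wb))
        # branch on the presynaptic path
        Z <- Wz %*% (r * t(Wb))
        out <- out + e(w1 + w2)^a * e(-w1)^(b + z) * e(-w2)^g *
          ((Wa * Wg) %*% Z)
        # branch on the delayed-post path
        U <- Wg %*% (r * t(Wz))
        out <- out + e(w1 + w2)^a * e(-w1)^b * e(-w2)^(g + z) *
          ((Wa * U) %*% t(Wb))
      }
    out
  }
  err_at <- function(rho) {
    W <- weak_random_W(N, rho, 31)
    Kfull <- third_cumulant_ft(30, -45, W, r, kp0)
    max(Mod(Kfull - series_K(30, -45, W, r, 2))) / max(Mod(Kfull))
  }
  e1 <- err_at(0.3); e2 <- err_at(0.15)
  expect_lt(e1, 0.15)
  expect_gt(e1 / e2, 4) # third-order truncation: halving rho gains ~8x
})

test_that("external covariance adds filtered common input", {
  N <- 4
  r <- rep(10, N)
  W <- weak_random_W(N, 0.2, 41)
  Cin <- cross_covariance_ft(60, W, r, kp0)
  expect_equal(external_covariance_ft(60, W, r, matrix(0, N, N), kp0), Cin)
  Cx <- diag(4) * 0; Cx[1, 2] <- Cx[2, 1] <- 2
  C0 <- external_covariance_ft(60, matrix(0, N, N), r, Cx, kp0)
  expect_equal(C0 - diag(r),
               epsc_ft(60, kp0) * Cx * epsc_ft(-60, kp0), tolerance = 1e-12)
  # block-structured input raises in-block zero-frequency covariance
  Cblk <- build_external_covariance(c(1, 1, 2, 2), 0.25, network_config(N = 4))
  Cw <- external_covariance_ft(0, W, r, Cblk, kp0)
  expect_gt(Re(Cw[1, 2]), Re(Cw[1, 3]))
  expect_error(external_covariance_ft(0, W, r, matrix(1:16, 4, 4), kp0),
               "symmetric")
})

test_that("full-order drift: zero at W = 0 under balance, rate shift
           under imbalance, truncation match on weak matrices", {
  cfg <- network_config(N = 6)
  sp <- table1_sp(13)
  D0 <- full_order_drift(matrix(0, 6, 6), cfg, kp0, sp,
                         n_line = 101, n_plane = 30)
  expect_lt(max(abs(D0)), 1e-12)
  cfgd <- network_config(N = 6, delta = 2e-4)
  Dd <- full_order_drift(matrix(0, 6, 6), cfgd, kp0, sp,
                         n_line = 101, n_plane = 30)
  off <- row(Dd) != col(Dd)
  expect_equal(Dd[off], rep(150^2 * 2e-4, sum(off)), tolerance = 1e-10)
})
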