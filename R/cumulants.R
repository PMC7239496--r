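# Stationary rates and spike-train cumulants of the linear Hawkes network,
# in the frequency domain through the resolvent (I - E~ W)^{-1}, plus the
# full-order drift used as the oracle for the motif-truncated dynamics.

#' Network configuration
#'
#' Sizes, external input rates, weight bounds and plasticity scales of the
#' recurrent excitatory network.
#'
#' @param N Number of excitatory neurons (>= 2).
#' @param mu External input firing rate(s) in Hz; scalar or length-`N`.
#' @param w_max Upper bound of each synaptic efficacy.
#' @param W_max Upper bound of the summed afferent (row) and efferent
#'   (column) efficacies of a neuron; `W_max / w_max` caps the number of
#'   saturated connections.
#' @param nu Learning-rate scale of the weight dynamics.
#' @param psi Relative strength of heterosynaptic competition.
#' @param delta Balance perturbation of the zero-order (rate) motif.
#' @param delta_inh Inhibitory scaling; 1 balances inhibition exactly
#'   against the mean excitatory input.
#' @return An object of class `network_config`.
#' @export
network_config <- function(N = 48, mu = 150, w_max = 0.17, W_max = 0.85,
                           nu = 3.5e-4, psi = 0.7, delta = 0,
                           delta_inh = 1) {
  stopifnot(N >= 2, all(mu > 0), w_max > 0, W_max >= w_max, nu > 0,
            psi >= 0, delta_inh >= 0)
  structure(list(N = as.integer(N), mu = rep_len(mu, N), w_max = w_max,
                 W_max = W_max, nu = nu, psi = psi, delta = delta,
                 delta_inh = delta_inh),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(paste0("network: N = %d, mu = %g Hz, w_max = %g, W_max = %g, ",
                     "nu = %g, psi = %g, delta = %g, delta_inh = %g\n"),
              x$N, mean(x$mu), x$w_max, x$W_max, x$nu, x$psi, x$delta,
              x$delta_inh))
  invisible(x)
}

#' Random initial weight matrix
#'
#' Entries drawn independently from `U(0, W_max / N * 0.001)` — three orders
#' of magnitude below the competition bound, so the initial condition only
#' seeds the symmetry breaking. Diagonal held at zero (no self-excitation).
#'
#' @param cfg A [network_config()] object.
#' @param seed Integer seed; the same seed reproduces the matrix.
#' @return An `N x N` numeric matrix.
#' @export
initial_weights <- function(cfg, seed) {
  stopifnot(inherits(cfg, "network_config"))
  N <- cfg$N
  if (!missing(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  W <- matrix(stats::runif(N * N, 0, cfg$W_max / N * 0.001), N, N)
  diag(W) <- 0
  W
}

#' Inhibitory-balanced effective connectivity
#'
#' A fast inhibitory population cancels the mean excitatory input of each
#' neuron: the inhibitory weight to neuron `l` is the row mean
#' `w_l = sum_k W_lk / (N - 1)`, subtracted from every off-diagonal entry of
#' row `l` and scaled by `delta_inh`. At `delta_inh = 1` effective
#' off-diagonal row sums vanish; in general they equal
#' `(1 - delta_inh)` times the excitatory row sums.
#'
#' @param W Excitatory weight matrix (nonnegative, zero diagonal).
#' @param cfg A [network_config()] object (supplies `delta_inh`).
#' @return The effective matrix `W_eff` (may contain negative entries).
#' @export
inhibitory_balance <- function(W, cfg) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  w_inh <- rowSums(W) / (nrow(W) - 1)
  Winh <- matrix(w_inh, nrow(W), ncol(W))
  diag(Winh) <- 0
  W - cfg$delta_inh * Winh
}

#' Stationary firing rates
#'
#' First-order cumulant of the Hawkes network,
#' \eqn{r = (I - \tilde E(0) W)^{-1}\mu}, requiring spectral radius of
#' \eqn{\tilde E(0) W} below one. With perfectly balanced inhibition the
#' effective matrix has zero row sums and the rates equal the external
#' input.
#'
#' @param W Weight matrix: the effective (balanced) matrix when
#'   `effective = TRUE` (default), the raw excitatory one otherwise.
#' @param cfg A [network_config()] object.
#' @param kp A [kernel_params()] object.
#' @param effective Apply [inhibitory_balance()] to `W` first?
#' @return Rate vector in Hz.
#' @export
stationary_rates <- function(W, cfg, kp = kernel_params(),
                             effective = TRUE) {
  if (effective) W <- inhibitory_balance(W, cfg)
  G <- Re(epsc_ft(0, kp)) * W
  if (max(Mod(eigen(G, only.values = TRUE)$values)) >= 1)
    stop("non-stationary network: spectral radius of E(0) * W is >= 1")
  r <- solve(diag(nrow(W)) - G, cfg$mu)
  if (any(r <= 0))
    stop("non-stationary network: negative stationary rate")
  as.numeric(r)
}

#' Resolvent of the interaction kernel
#'
#' \eqn{\tilde R(\omega) = (I - \tilde E(\omega) W)^{-1}}, the Fourier
#' transform of the convolution power series of the interaction kernel:
#' entry `(m, n)` propagates a spike of neuron `n` to the intensity of
#' neuron `m` through paths of every length.
#'
#' @param omega Angular frequency (rad/s), scalar.
#' @param W Weight matrix.
#' @param kp A [kernel_params()] object.
#' @return A complex `N x N` matrix.
#' @export
resolvent <- function(omega, W, kp) {
  N <- nrow(W)
  out <- tryCatch(solve(diag(N) - epsc_ft(omega, kp) * W),
                  error = function(e)
                    stop("singular resolvent at omega = ", omega))
  out
}

#' Cross-covariance of spike trains in the frequency domain
#'
#' Second-order cumulant
#' \eqn{\tilde C_{ij}(\omega) = \sum_k r_k \tilde R_{ik}(\omega)
#' \tilde R_{jk}(-\omega)}; at `W = 0` this is the Poisson diagonal
#' `diag(r)`.
#'
#' @inheritParams resolvent
#' @param rates Stationary rate vector (Hz).
#' @return A complex `N x N` matrix.
#' @export
cross_covariance_ft <- function(omega, W, rates, kp) {
  R <- resolvent(omega, W, kp)
  Rm <- resolvent(-omega, W, kp)
  R %*% (rates * t(Rm))
}

#' Third-order cumulant in the frequency domain
#'
#' \eqn{\tilde K_{ij}(\omega_1, \omega_2)} of the Hawkes network: the
#' four-term resolvent expression in which spike propagation either follows
#' straight paths from the source or branches at an intermediate neuron
#' (through \eqn{\tilde\Psi = \tilde R - I}). Reduces to the Poisson third
#' cumulant `r_i` on the diagonal at `W = 0`.
#'
#' @inheritParams cross_covariance_ft
#' @param omega1,omega2 Angular frequencies (rad/s), scalars.
#' @return A complex `N x N` matrix indexed (post `i`, pre `j`).
#' @export
third_cumulant_ft <- function(omega1, omega2, W, rates, kp) {
  N <- nrow(W)
  Rp <- resolvent(omega1 + omega2, W, kp)
  R1m <- resolvent(-omega1, W, kp)
  R2m <- resolvent(-omega2, W, kp)
  I <- diag(N)
  P <- Rp - I; P1 <- R1m - I; P2 <- R2m - I
  T1 <- (Rp * R2m) %*% (rates * t(R1m))
  T2 <- ((Rp %*% (rates * t(P))) * R2m) %*% t(R1m)
  T3 <- (Rp * R2m) %*% (P1 %*% (rates * t(R1m)))
  T4 <- (Rp * (R2m %*% (rates * t(P2)))) %*% t(R1m)
  T1 + T2 + T3 + T4
}

#' Covariance with structured external input
#'
#' Adds to the internal covariance the term conveying externally correlated
#' drive as common input,
#' \eqn{(I-\tilde E W)^{-1}\tilde E \tilde C^{ext} \tilde E^*(I-\tilde E^* W^T)^{-1}}.
#'
#' @inheritParams cross_covariance_ft
#' @param C_ext External input covariance matrix (symmetric, nonnegative
#'   definite), taken white (frequency-flat) on the scale of the kernel.
#' @return A complex `N x N` matrix.
#' @export
external_covariance_ft <- function(omega, W, rates, C_ext, kp) {
  if (!isSymmetric(unname(C_ext)))
    stop("`C_ext` must be symmetric")
  R <- resolvent(omega, W, kp)
  Rm <- resolvent(-omega, W, kp)
  internal <- R %*% (rates * t(Rm))
  e <- epsc_ft(omega, kp); em <- epsc_ft(-omega, kp)
  internal + R %*% (e * C_ext * em) %*% t(Rm)
}

#' Full-order weight drift from resolvent cumulants
#'
#' Numerically integrates the exact drift of the mean synaptic efficacies —
#' rate, cross-covariance, auto-covariance and third-cumulant contributions
#' at every order of the connectivity — using the resolvent cumulants, and
#' serves as the oracle for the motif-truncated [stdp_drift()]. Intended for
#' small networks (N of order 12).
#'
#' The self-spike atoms of the auto-covariance and of the third cumulant
#' (the same spike playing both postsynaptic roles) carry no plasticity and
#' are removed analytically before quadrature.
#'
#' @param W Excitatory weight matrix (zero diagonal).
#' @param cfg A [network_config()] object (`delta` provides the zero-order
#'   perturbation).
#' @param kp A [kernel_params()] object.
#' @param sp An [stdp_params()] object; `A_plus = NA` is balanced at the
#'   mean external rate.
#' @param rates Stationary rates; defaults to `cfg$mu` (balanced network).
#' @param n_line,n_plane Gauss-Legendre panel sizes of the line and plane
#'   rules.
#' @return Drift matrix in weight units per second, zero diagonal.
#' @export
full_order_drift <- function(W, cfg, kp, sp, rates = NULL,
                             n_line = 301L, n_plane = 80L) {
  N <- nrow(W)
  if (is.null(rates)) rates <- rep_len(cfg$mu, N)
  if (is.na(sp$A_plus))
    sp$A_plus <- balanced_potentiation(sp, mean(rates), cfg$delta)
  M0 <- cfg$delta
  D <- M0 * outer(rates, rates)

  g1 <- gauss_line(n_line)
  D1 <- matrix(0, N, N); D2v <- numeric(N)
  for (m in seq_along(g1$w)) {
    w <- g1$w[m]
    C <- cross_covariance_ft(w, W, rates, kp)
    l2 <- stdp_pair_ft(-w, sp)
    l3 <- stdp_triplet_ft(-w, 0, sp) + stdp_triplet_ft(w, -w, sp)
    D1 <- D1 + g1$wt[m] * (Re(C * l2) + rates * Re(C * l3))
    D2v <- D2v + g1$wt[m] * Re((diag(C) - rates) * stdp_triplet_ft(0, -w, sp))
  }
  D1 <- D1 / (2 * pi)
  D2 <- outer(D2v, rates) / (2 * pi) # r_j times the auto-covariance integral

  g2 <- gauss_line(n_plane)
  Rm_cache <- lapply(g2$w, function(w) resolvent(-w, W, kp))
  DK <- matrix(0, N, N)
  I <- diag(N)
  for (m1 in seq_along(g2$w)) {
    w1 <- g2$w[m1]
    R1m <- Rm_cache[[m1]]
    P1 <- R1m - I
    # same-spike atoms, constant in omega2: the current and previous
    # postsynaptic spike collapsing onto one spike of neuron i, either as
    # the source (straight term) or at the branch point (third term)
    atom <- rates * t(R1m) + P1 %*% (rates * t(R1m))
    for (m2 in seq_along(g2$w)) {
      w2 <- g2$w[m2]
      Rp <- resolvent(w1 + w2, W, kp)
      R2m <- Rm_cache[[m2]]
      P <- Rp - I; P2 <- R2m - I
      K <- (Rp * R2m) %*% (rates * t(R1m)) +
        ((Rp %*% (rates * t(P))) * R2m) %*% t(R1m) +
        (Rp * R2m) %*% (P1 %*% (rates * t(R1m))) +
        (Rp * (R2m %*% (rates * t(P2)))) %*% t(R1m) -
        atom
      DK <- DK + (g2$wt[m1] * g2$wt[m2]) *
        Re(K * stdp_triplet_ft(-w1, -w2, sp))
    }
  }
  DK <- DK / (2 * pi)^2

  out <- D + D1 + D2 + DK
  diag(out) <- 0
  out
}
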