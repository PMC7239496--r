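# Shared fixtures and independent time-domain oracles for the motif
# integrals. The oracles work entirely on discretized time grids (FFT
# convolutions and trapezoid sums) and never touch the frequency-domain
# code paths they are used to check.

table1_kp <- function(tau_iota = 5e-3) kernel_params(5e-3, tau_iota)

# linear convolution via zero-padded FFT (stats::convolve uses the exact
# output length, which can be prime and pathologically slow)
fft_conv <- function(x, y) {
  n <- length(x) + length(y) - 1L
  m <- stats::nextn(n, 2L)
  xr <- c(x, numeric(m - length(x)))
  yr <- c(y, numeric(m - length(y)))
  Re(stats::fft(stats::fft(xr) * stats::fft(yr), inverse = TRUE))[seq_len(n)] / m
}
table1_sp <- function(eta_minus = 1, A_plus = NA_real_)
  stdp_params(0.01, 33.7e-3, A_plus, 16.8e-3, 114e-3, eta_minus)

# integer time grid; summed integrands vanish at both ends, so plain
# rectangle sums are trapezoid-accurate (O(dt^2))
oracle_grid <- function(dt = 1e-5, horizon = 0.7) seq(0, horizon, by = dt)

# sum c(tau) * win(tau) over one side of the lag axis, evaluating both at
# cell midpoints (the windows have a kink at 0, so integer-lag rectangle
# sums would lose an O(dt) half cell there)
side_sum <- function(co, side = c("neg", "pos"), win) {
  side <- match.arg(side)
  dt <- co$lag[2] - co$lag[1]
  keep <- if (side == "neg") co$lag <= 0 else co$lag >= 0
  lag <- co$lag[keep]; val <- co$val[keep]
  m <- length(lag)
  midlag <- (lag[-1] + lag[-m]) / 2
  midval <- (val[-1] + val[-m]) / 2
  sum(midval * win(midlag)) * dt
}

# kernel self-convolution powers on the grid; power 0 is the delta symbol
conv_powers <- function(kp, kmax, tg) {
  dt <- tg[2] - tg[1]
  e <- epsc(tg, kp)
  out <- vector("list", kmax + 1)
  out[[1]] <- NULL # delta, handled by callers
  out[[2]] <- e
  if (kmax >= 2) for (k in 2:kmax) {
    v <- fft_conv(out[[k]], e)[seq_along(tg)] * dt
    out[[k + 1]] <- v
  }
  out
}

# correlation c(tau) = int E^a(u) E^b(u - tau) du, a, b >= 1; FFT-based
# (convolve open gives lags ascending from -(n-1) dt to (n-1) dt)
corr_ab <- function(pw, a, b, tg) {
  dt <- tg[2] - tg[1]
  n <- length(tg)
  ea <- pw[[a + 1]]; eb <- pw[[b + 1]]
  full <- fft_conv(ea, rev(eb)) * dt
  list(lag = ((-(n - 1)):(n - 1)) * dt, val = full)
}

# pair coefficient: int c(tau) L2(tau) dtau (support tau < 0)
oracle_pair <- function(a, b, kp, sp, tg = oracle_grid()) {
  dt <- tg[2] - tg[1]
  pw <- conv_powers(kp, max(a, b), tg)
  if (b == 0) return(0)
  if (a == 0) {
    # c(tau) = E^b(-tau): mass entirely at tau <= 0
    s <- tg
    return(-sum(pw[[b + 1]] * (sp$A_minus / sp$eta_minus) *
                  exp(-s / (sp$eta_minus * sp$tau_minus))) * dt)
  }
  co <- corr_ab(pw, a, b, tg)
  side_sum(co, "neg", function(l)
    -(sp$A_minus / sp$eta_minus) * exp(l / (sp$eta_minus * sp$tau_minus)))
}

# triplet (alpha, beta) coefficient: c against the tau2-integrated window
# plus c against the equal-time slice g(u) of the triplet window
oracle_trip_ab <- function(a, b, kp, sp, tg = oracle_grid()) {
  dt <- tg[2] - tg[1]
  pw <- conv_powers(kp, max(a, b, 1), tg)
  tpy <- sp$tau_plus * sp$tau_y / (sp$tau_plus + sp$tau_y)
  gpos <- sp$A_plus * tpy * exp(-tg / sp$tau_y)     # g(u), u >= 0
  gneg <- sp$A_plus * tpy * exp(-tg / sp$tau_plus)  # g(-u), u >= 0
  ell <- sp$A_plus * sp$tau_y * exp(-tg / sp$tau_plus) # int L3 dtau2
  if (a == 0) {
    # c(tau) = E^b(-tau): only negative lags; first term vanishes
    t2 <- sum(pw[[b + 1]] * gneg) * dt
    return(t2)
  }
  if (b == 0) {
    # c(tau) = E^a(tau): only positive lags
    t1 <- sum(pw[[a + 1]] * ell) * dt
    t2 <- sum(pw[[a + 1]] * gpos) * dt
    return(t1 + t2)
  }
  co <- corr_ab(pw, a, b, tg)
  t1 <- side_sum(co, "pos", function(l)
    sp$A_plus * sp$tau_y * exp(-l / sp$tau_plus))
  t2 <- side_sum(co, "pos", function(l) sp$A_plus * tpy * exp(-l / sp$tau_y)) +
    side_sum(co, "neg", function(l) sp$A_plus * tpy * exp(l / sp$tau_plus))
  t1 + t2
}

# gamma-path coefficient: c_{a,g}(tau) against A+ tau+ e^{-tau/tau_y}, tau>=0
oracle_trip_ag <- function(a, g, kp, sp, tg = oracle_grid()) {
  dt <- tg[2] - tg[1]
  pw <- conv_powers(kp, max(a, g, 1), tg)
  win <- sp$A_plus * sp$tau_plus * exp(-tg / sp$tau_y)
  if (a == 0) return(0) # support entirely at negative lags
  if (g == 0) return(sum(pw[[a + 1]] * win) * dt)
  co <- corr_ab(pw, a, g, tg)
  side_sum(co, "pos", function(l)
    sp$A_plus * sp$tau_plus * exp(-l / sp$tau_y))
}

# straight third-cumulant coefficient via the factorized triple integral:
# A+ int E^a(u) h_b(u) h_g(u) du with h the window-filtered kernels
oracle_trip_straight <- function(a, b, g, kp, sp, tg = oracle_grid()) {
  dt <- tg[2] - tg[1]
  pw <- conv_powers(kp, max(a, b, g, 1), tg)
  filt <- function(k, tau) {
    # int_0^u E^k(u - t) e^{-t/tau} dt on the grid u = tg; the t = 0
    # endpoint has a nonzero integrand, so apply the trapezoid correction
    if (k == 0) return(exp(-tg / tau)) # delta factor
    ker <- exp(-tg / tau)
    fft_conv(pw[[k + 1]], ker)[seq_along(tg)] * dt - 0.5 * dt * pw[[k + 1]]
  }
  ea <- if (a == 0) NULL else pw[[a + 1]]
  hb <- filt(b, sp$tau_plus)
  hg <- filt(g, sp$tau_y)
  if (a == 0) stop("alpha = 0 not needed by the tests")
  sp$A_plus * sum(ea * hb * hg) * dt
}

# directed-graph brute force: Fagiolo triangle count and geodesic
# efficiency by exhaustive enumeration (N <= 6)
bf_clustering <- function(A) {
  n <- nrow(A)
  per <- numeric(n)
  for (i in 1:n) {
    t_i <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j == i || h == i || j == h) next
      t_i <- t_i + (A[i, j] + A[j, i]) * (A[i, h] + A[h, i]) *
        (A[j, h] + A[h, j])
    }
    t_i <- t_i / 2
    dtot <- sum(A[i, ]) + sum(A[, i])
    dbi <- sum(A[i, ] * A[, i])
    den <- dtot * (dtot - 1) - 2 * dbi
    per[i] <- if (den > 0) t_i / den else 0
  }
  list(per_node = per, mean = mean(per))
}

bf_efficiency <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

# small steady-state run cache shared across test files (computed once)
steady_run <- local({
  cache <- NULL
  function(eta = 13, seed = 1, mask = term_mask()) {
    key <- paste(eta, seed, paste(unlist(mask), collapse = ""), sep = "_")
    if (is.null(cache)) cache <<- list()
    if (is.null(cache[[key]])) {
      cfg <- network_config()
      cache[[key]] <<- integrate_weights(
        initial_weights(cfg, seed), cfg, kernel_params(),
        stdp_params(eta_minus = eta), mask = mask,
        on_nonconvergence = "warn")
    }
    cache[[key]]
  }
})

# Gaussian-smoothed empirical third cumulant around a lag pair: the same
# functional as analytic_third_cumulant(smooth = sigma), estimated from
# binned counts with segment-wise standard errors
smoothed_k3 <- function(st, i, j, tau1, tau2, sigma = 3e-3, bin = 2e-3,
                        half = 5L, segments = 20L) {
  nb <- floor(st$horizon / bin)
  count <- function(v) {
    v <- v[v < nb * bin]
    tabulate(floor(v / bin) + 1L, nbins = nb)
  }
  ni <- count(st$times[[i]])
  nj <- count(st$times[[j]])
  offs <- (-half):half
  m1s <- round(tau1 / bin) + offs
  m2s <- round(tau2 / bin) + offs
  w1 <- stats::dnorm(m1s * bin, tau1, sigma)
  w2 <- stats::dnorm(m2s * bin, tau2, sigma)
  Wg <- outer(w1, w2)
  Wg <- Wg / sum(Wg)
  L <- max(abs(c(m1s, m2s))) + 1L
  seg <- pmin(floor(seq(0, segments) * nb / segments), nb)
  per_seg <- numeric(segments)
  for (s in seq_len(segments)) {
    idx <- (seg[s] + 1L):seg[s + 1L]
    idx <- idx[idx > L & idx <= nb - L]
    a <- ni[idx]
    ri <- mean(a) / bin
    bs <- lapply(m1s, function(m) nj[idx - m])
    ds <- lapply(m2s, function(m) ni[idx - m])
    tot <- 0
    for (p in seq_along(m1s)) for (q in seq_along(m2s)) {
      b <- bs[[p]]; d <- ds[[q]]
      rj <- mean(b) / bin
      m3 <- mean(a * b * d) / bin^3
      cij1 <- mean(a * b) / bin^2 - ri * rj
      cij2 <- mean(d * b) / bin^2 - ri * rj
      cii <- mean(a * d) / bin^2 - ri^2
      tot <- tot + Wg[p, q] * (m3 - ri * (cij1 + cij2) - rj * cii -
                                 ri^2 * rj)
    }
    per_seg[s] <- tot
  }
  list(value = mean(per_seg), se = stats::sd(per_seg) / sqrt(segments))
}
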