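# Mutually exciting point-process simulator (Ogata thinning, exact for the
# two-exponential EPSC kernel) and binned empirical cumulant estimators.
# The module is the stochastic oracle for the analytic cumulants.

#' Spike trains container
#'
#' @param times List of numeric vectors, one strictly increasing vector of
#'   spike times (seconds) per neuron.
#' @param horizon Simulation horizon T in seconds.
#' @return An object of class `spike_trains`.
#' @export
spike_trains <- function(times, horizon) {
  stopifnot(is.list(times), horizon > 0)
  for (v in times) {
    if (length(v) && (any(v < 0) || any(v > horizon) || is.unsorted(v, strictly = TRUE)))
      stop("spike times must be strictly increasing within [0, horizon]")
  }
  structure(list(times = times, horizon = horizon, N = length(times)),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("spike_trains: %d neurons, T = %g s, %d spikes\n",
              x$N, x$horizon, sum(lengths(x$times))))
  invisible(x)
}

#' Simulate the Hawkes network
#'
#' Exact sampling of the linear mutually exciting process with intensity
#' \eqn{\lambda_i(t) = \mu_i + \sum_k W_{ik} (E * S_k)(t)} by thinning with
#' a piecewise-constant dominating rate refreshed after every event. The
#' two-exponential structure of the EPSC makes the excitation state
#' Markovian (two decaying traces per neuron). When the effective matrix
#' carries negative (inhibitory-balanced) entries the intensity is
#' rectified at zero — an approximation of the linear theory, flagged in
#' the returned object.
#'
#' @param W Weight matrix (the raw excitatory one, or an effective matrix
#'   from [inhibitory_balance()]).
#' @param cfg A [network_config()] object (provides `mu`).
#' @param kp A [kernel_params()] object.
#' @param horizon Duration T in seconds.
#' @param seed Integer seed (same seed, same spike trains).
#' @return A [spike_trains()] object; attribute `rectified` counts rectified
#'   intensity evaluations.
#' @export
simulate_hawkes <- function(W, cfg, kp = kernel_params(), horizon = 100,
                            seed = 1L) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  N <- nrow(W)
  mu <- rep_len(cfg$mu, N)
  Wpos <- pmax(W, 0)
  if (max(Mod(eigen(Re(epsc_ft(0, kp)) * Wpos, only.values = TRUE)$values)) >= 1)
    stop("non-stationary network: spectral radius of E(0) * W is >= 1")
  te <- kp$tau_eps; ti <- kp$tau_iota
  cc <- if (ti == 0) 1 / te else (te + ti) / te^2
  rate1 <- 1 / te
  rate2 <- if (ti == 0) Inf else 1 / te + 1 / ti
  set.seed(seed)
  x1 <- numeric(N); x2 <- numeric(N) # per-neuron excitation traces
  colW <- colSums(Wpos) # bound uses positive weights only
  t <- 0
  nrect <- 0L
  times <- lapply(seq_len(N), function(i) numeric(0))
  buf <- vector("list", N)
  for (i in seq_len(N)) buf[[i]] <- numeric(256)
  cnt <- integer(N)
  mu_tot <- sum(mu)
  repeat {
    bound <- mu_tot + cc * sum(colW * x1)
    dt <- stats::rexp(1, bound)
    t <- t + dt
    if (t > horizon) break
    x1 <- x1 * exp(-rate1 * dt)
    x2 <- if (is.finite(rate2)) x2 * exp(-rate2 * dt) else numeric(N)
    lam <- mu + as.numeric(W %*% (cc * (x1 - x2)))
    if (any(lam < 0)) {
      nrect <- nrect + sum(lam < 0)
      lam[lam < 0] <- 0
    }
    s <- sum(lam)
    if (stats::runif(1) * bound <= s) {
      n <- sample.int(N, 1L, prob = lam)
      cnt[n] <- cnt[n] + 1L
      if (cnt[n] > length(buf[[n]])) buf[[n]] <- c(buf[[n]], numeric(length(buf[[n]])))
      buf[[n]][cnt[n]] <- t
      x1[n] <- x1[n] + 1
      if (is.finite(rate2)) x2[n] <- x2[n] + 1
    }
  }
  out <- spike_trains(lapply(seq_len(N), function(i) buf[[i]][seq_len(cnt[i])]),
                      horizon)
  attr(out, "rectified") <- nrect
  out
}

#' Empirical firing rates
#'
#' @param st A [spike_trains()] object.
#' @return Rate vector in Hz (spike counts over the horizon).
#' @export
empirical_rates <- function(st) {
  stopifnot(inherits(st, "spike_trains"))
  lengths(st$times) / st$horizon
}

bin_counts <- function(st, bin) {
  nb <- floor(st$horizon / bin)
  lapply(st$times, function(v) {
    v <- v[v < nb * bin]
    tabulate(floor(v / bin) + 1L, nbins = nb)
  })
}

#' Empirical cross-covariance of two spike trains
#'
#' Binned estimator of \eqn{C_{ij}(\tau) = \langle S_i(t) S_j(t-\tau)\rangle
#' - r_i r_j} on a lag grid, edge-corrected for the finite horizon. The
#' autocovariance (`i == j`) contains the point-process atom `r_i / bin` in
#' the zero-lag bin. Standard errors come from splitting the horizon into
#' segments.
#'
#' @param st A [spike_trains()] object.
#' @param i,j Neuron indices (post, pre).
#' @param max_lag Largest lag magnitude in seconds (default 0.2).
#' @param bin Bin width in seconds (default 1e-3).
#' @param segments Number of horizon segments for the standard error.
#' @return A tibble with columns `lag`, `value`, `se`.
#' @export
empirical_cross_covariance <- function(st, i, j, max_lag = 0.2, bin = 1e-3,
                                       segments = 20L) {
  stopifnot(inherits(st, "spike_trains"))
  if (!length(st$times[[i]]) || !length(st$times[[j]]))
    stop("covariance undefined for empty spike trains")
  L <- floor(max_lag / bin)
  nb <- floor(st$horizon / bin)
  if (nb <= 2L * L) stop("horizon too short for the requested lags")
  ni <- bin_counts(st, bin)[[i]]
  nj <- bin_counts(st, bin)[[j]]
  seg <- pmin(floor(seq(0, segments) * nb / segments), nb)
  lags <- (-L):L
  acc <- matrix(0, length(lags), segments)
  for (s in seq_len(segments)) {
    idx <- (seg[s] + 1L):seg[s + 1L]
    # guard the segment edges so every lag uses in-segment products only
    idx <- idx[idx > L & idx <= nb - L]
    a <- ni[idx]
    ri <- mean(a) / bin
    for (m in seq_along(lags)) {
      b <- nj[idx - lags[m]]
      acc[m, s] <- mean(a * b) / bin^2 - ri * mean(b) / bin
    }
  }
  est <- rowMeans(acc)
  se <- apply(acc, 1, stats::sd) / sqrt(segments)
  tibble::tibble(lag = lags * bin, value = est, se = se)
}

#' Empirical third-order cumulant at selected lag pairs
#'
#' Binned estimator of \eqn{K_{ij}(\tau_1, \tau_2)}: the triple moment
#' \eqn{\langle S_i(t) S_j(t-\tau_1) S_i(t-\tau_2)\rangle} with the
#' rate-and-covariance terms subtracted, per its cumulant definition.
#'
#' @inheritParams empirical_cross_covariance
#' @param lag_pairs Two-column matrix of (tau1, tau2) lags in seconds.
#' @return A tibble with columns `tau1`, `tau2`, `value`, `se`.
#' @export
empirical_third_cumulant <- function(st, i, j, lag_pairs, bin = 1e-3,
                                     segments = 20L) {
  stopifnot(inherits(st, "spike_trains"), ncol(lag_pairs) == 2)
  nb <- floor(st$horizon / bin)
  ni <- bin_counts(st, bin)[[i]]
  nj <- bin_counts(st, bin)[[j]]
  L <- max(ceiling(abs(lag_pairs) / bin)) + 1L
  seg <- pmin(floor(seq(0, segments) * nb / segments), nb)
  out <- vector("list", nrow(lag_pairs))
  for (p in seq_len(nrow(lag_pairs))) {
    m1 <- round(lag_pairs[p, 1] / bin); m2 <- round(lag_pairs[p, 2] / bin)
    vals <- numeric(segments)
    for (s in seq_len(segments)) {
      idx <- (seg[s] + 1L):seg[s + 1L]
      idx <- idx[idx > L & idx <= nb - L]
      a <- ni[idx]; b <- nj[idx - m1]; d <- ni[idx - m2]
      ri <- mean(a) / bin; rj <- mean(b) / bin
      # joint moment and the lower-order subtractions of the cumulant
      m3 <- mean(a * b * d) / bin^3
      cij1 <- mean(a * b) / bin^2 - ri * rj
      cij2 <- mean(d * b) / bin^2 - ri * rj # lag tau2 - tau1 between j and i
      cii <- mean(a * d) / bin^2 - ri^2
      vals[s] <- m3 - ri * (cij1 + cij2) - rj * cii - ri^2 * rj
    }
    out[[p]] <- tibble::tibble(tau1 = lag_pairs[p, 1], tau2 = lag_pairs[p, 2],
                               value = mean(vals),
                               se = stats::sd(vals) / sqrt(segments))
  }
  do.call(rbind, out)
}

#' Analytic covariance transformed to the time domain
#'
#' Inverse Fourier transform of [cross_covariance_ft()] on a lag grid, with
#' the Poisson atom (the frequency-flat part) removed and reported
#' separately; used to compare the linear theory against binned estimates.
#'
#' @inheritParams cross_covariance_ft
#' @param i,j Neuron indices.
#' @param lags Lag grid in seconds.
#' @param n_line Quadrature panel size.
#' @return A tibble with columns `lag` and `value`; attribute `atom` holds
#'   the zero-lag atom mass (`r_i` for `i == j`, else 0).
#' @export
analytic_cross_covariance <- function(W, rates, kp, i, j, lags,
                                      n_line = 2001L) {
  g <- gauss_line(n_line)
  vals <- numeric(length(lags))
  atom <- if (i == j) rates[i] else 0
  for (m in seq_along(g$w)) {
    w <- g$w[m]
    C <- cross_covariance_ft(w, W, rates, kp)
    vals <- vals + g$wt[m] * Re((C[i, j] - atom) * exp(1i * w * lags))
  }
  out <- tibble::tibble(lag = lags, value = vals / (2 * pi))
  attr(out, "atom") <- atom
  out
}

#' Analytic third cumulant transformed to the time domain
#'
#' Two-dimensional inverse transform of [third_cumulant_ft()] at selected
#' lag pairs, with the same-spike atoms removed. The bare inverse
#' transform is an oscillatory integral with polynomially decaying tails,
#' so a Gaussian smoothing of width `smooth` (seconds) is applied to the
#' lag plane — equivalently a Gaussian factor in frequency — making the
#' quadrature rapidly convergent; compare against an identically smoothed
#' empirical estimate.
#'
#' @inheritParams cross_covariance_ft
#' @param i,j Neuron indices.
#' @param lag_pairs Two-column matrix of (tau1, tau2) lags in seconds.
#' @param n_plane Quadrature panel size per dimension.
#' @param smooth Gaussian smoothing width in seconds (0 disables it).
#' @return A tibble with columns `tau1`, `tau2`, `value`.
#' @export
analytic_third_cumulant <- function(W, rates, kp, i, j, lag_pairs,
                                    n_plane = 160L, smooth = 3e-3) {
  g <- gauss_line(n_plane)
  N <- nrow(W)
  Rm <- lapply(g$w, function(w) resolvent(-w, W, kp))
  I <- diag(N)
  vals <- numeric(nrow(lag_pairs))
  for (m1 in seq_along(g$w)) {
    w1 <- g$w[m1]; R1m <- Rm[[m1]]; P1 <- R1m - I
    X <- P1 %*% (rates * t(R1m))
    for (m2 in seq_along(g$w)) {
      w2 <- g$w[m2]
      Rp <- resolvent(w1 + w2, W, kp)
      R2m <- Rm[[m2]]
      P <- Rp - I; P2 <- R2m - I
      # scalar (i,j) entry of the four resolvent terms; the same-spike
      # atoms (both postsynaptic roles taken by one spike) are removed
      t1 <- sum(rates * Rp[i, ] * R1m[j, ] * R2m[i, ]) -
        rates[i] * R1m[j, i] # post-post same-spike atom (straight term)
      t2 <- sum((Rp %*% (rates * t(P)))[i, ] * R1m[j, ] * R2m[i, ])
      t3 <- sum(X[, j] * Rp[i, ] * R2m[i, ]) - X[i, j] # branch-point atom
      t4 <- sum((R2m %*% (rates * t(P2)))[i, ] * Rp[i, ] * R1m[j, ])
      K <- t1 + t2 + t3 + t4
      ph <- exp(1i * (w1 * lag_pairs[, 1] + w2 * lag_pairs[, 2]))
      damp <- exp(-smooth^2 * (w1^2 + w2^2) / 2)
      vals <- vals + (g$wt[m1] * g$wt[m2] * damp) * Re(K * ph)
    }
  }
  tibble::tibble(tau1 = lag_pairs[, 1], tau2 = lag_pairs[, 2],
                 value = vals / (2 * pi)^2)
}

#' Write / read spike trains as two-column delimited text
#'
#' Columns: neuron id (1-based) and spike time in seconds.
#'
#' @param st A [spike_trains()] object.
#' @param path File path.
#' @param horizon Horizon to attach on reading (defaults to the largest
#'   time).
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` a [spike_trains()] object.
#' @export
write_spike_trains <- function(st, path) {
  stopifnot(inherits(st, "spike_trains"))
  df <- data.frame(
    neuron = rep.int(seq_len(st$N), lengths(st$times)),
    time = unlist(st$times, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param n_neurons Number of neurons (defaults to the largest id present).
#' @export
read_spike_trains <- function(path, horizon = NULL, n_neurons = NULL) {
  df <- utils::read.table(path, col.names = c("neuron", "time"))
  N <- if (is.null(n_neurons)) max(df$neuron) else n_neurons
  if (is.null(horizon)) horizon <- max(df$time)
  times <- lapply(seq_len(N), function(i) sort(df$time[df$neuron == i]))
  spike_trains(times, horizon)
}
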