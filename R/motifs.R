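# Motif coefficients: integrals of products of kernel transforms against the
# learning windows. A motif is a pattern of connectivity paths from a source
# neuron to the post- (alpha, and the delayed gamma) and presynaptic (beta)
# neuron of a synapse; its coefficient weighs the contribution of that
# pattern to the mean weight drift.

#' Pair-rule motif coefficient
#'
#' \eqn{M^{pair}_{\alpha,\beta} = \frac{1}{2\pi}\int \tilde E^\alpha(\omega)
#' \tilde E^\beta(-\omega)\tilde L_2(-\omega)\,d\omega}, equal to the
#' time-domain integral of the cross-correlation of the \eqn{\alpha}- and
#' \eqn{\beta}-fold convolved kernels against the pair window. Coefficients
#' with `beta = 0` vanish by support disjointness (the correlation lives at
#' positive lags, depression at negative lags).
#'
#' @param alpha,beta Nonnegative integer path lengths, `alpha + beta >= 1`.
#' @param kp A [kernel_params()] object.
#' @param sp An [stdp_params()] object.
#' @return A real scalar.
#' @export
motif_pair <- function(alpha, beta, kp, sp) {
  check_paths(alpha, beta)
  if (beta == 0) return(0) # disjoint support, exactly zero
  quad_line(function(w)
    epsc_ft(w, kp)^alpha * epsc_ft(-w, kp)^beta * stdp_pair_ft(-w, sp)) /
    (2 * pi)
}

#' Triplet-rule cross-covariance motif coefficient
#'
#' Coefficient of the \eqn{(\alpha,\beta)} path pattern arising from the
#' cross-covariance through the triplet window. The two Dirac deltas of the
#' defining double integral are collapsed analytically, leaving
#' \deqn{M^{trip}_{\alpha,\beta} = \frac{1}{2\pi}\int \tilde E^\alpha(\omega)
#'   \tilde E^\beta(-\omega)\,[\tilde L_3(-\omega, 0) +
#'   \tilde L_3(\omega, -\omega)]\,d\omega.}
#' The first term pairs the correlated pre-post spikes with an independent
#' earlier postsynaptic spike; the second pairs them with the current one.
#'
#' @inheritParams motif_pair
#' @return A real scalar (units of seconds; multiplied by the postsynaptic
#'   rate in the grouped coefficients).
#' @export
motif_triplet_ab <- function(alpha, beta, kp, sp) {
  check_paths(alpha, beta)
  if (sp$A_plus == 0) return(0)
  quad_line(function(w)
    epsc_ft(w, kp)^alpha * epsc_ft(-w, kp)^beta *
      (stdp_triplet_ft(-w, 0, sp) + stdp_triplet_ft(w, -w, sp))) / (2 * pi)
}

#' Auto-covariance (gamma-path) motif coefficient
#'
#' \eqn{M^{trip}_{\alpha,\gamma} = \frac{1}{2\pi}\int \tilde E^\alpha(\omega)
#' \tilde E^\gamma(-\omega)\tilde L_3(0,-\omega)\,d\omega}: the delayed
#' \eqn{\gamma} path to the postsynaptic neuron accounts for the earlier
#' spike of the triplet. Independent of `eta_minus` (the pair window does not
#' enter). For `alpha = 0, gamma >= 1` the coefficient vanishes by support.
#'
#' @param alpha,gamma Nonnegative integer path lengths, `alpha + gamma >= 1`.
#' @inheritParams motif_pair
#' @return A real scalar (seconds).
#' @export
motif_triplet_ag <- function(alpha, gamma, kp, sp) {
  check_paths(alpha, gamma)
  if (sp$A_plus == 0) return(0)
  quad_line(function(w)
    epsc_ft(w, kp)^alpha * epsc_ft(-w, kp)^gamma *
      stdp_triplet_ft(0, -w, sp)) / (2 * pi)
}

#' Straight-path third-cumulant motif coefficient
#'
#' Genuine two-dimensional quadrature
#' \deqn{M^{trip}_{\alpha,\beta,\gamma} = \frac{1}{(2\pi)^2}\iint
#'   \tilde E^\alpha(\omega_1+\omega_2)\tilde E^\beta(-\omega_1)
#'   \tilde E^\gamma(-\omega_2)\tilde L_3(-\omega_1,-\omega_2)\,
#'   d\omega_1 d\omega_2.}
#'
#' @param alpha,beta,gamma Nonnegative integer path lengths summing to at
#'   least 1.
#' @inheritParams motif_pair
#' @return A real scalar (seconds).
#' @export
motif_triplet_straight <- function(alpha, beta, gamma, kp, sp) {
  check_paths(alpha, beta, gamma)
  if (sp$A_plus == 0) return(0)
  quad_plane(function(w1, w2)
    epsc_ft(w1 + w2, kp)^alpha * epsc_ft(-w1, kp)^beta *
      epsc_ft(-w2, kp)^gamma * stdp_triplet_ft(-w1, -w2, sp),
    scale = 1 / (2 * (kp$tau_eps + kp$tau_iota))) / (2 * pi)^2
}

#' Branched-path third-cumulant motif coefficient
#'
#' Motifs whose propagation tree branches at an intermediate neuron reached
#' by `zeta >= 1` synapses from the source; the branch exponent is added to
#' the chosen path. Total order is at least four, so these coefficients are
#' excluded from the truncated drift and serve only full-order validation.
#'
#' @param alpha,beta,gamma Nonnegative integer path lengths.
#' @param zeta Branch path length (integer >= 1).
#' @param branch Which path carries the branch point: "alpha", "beta" or
#'   "gamma".
#' @inheritParams motif_pair
#' @return A real scalar (seconds).
#' @export
motif_triplet_branched <- function(alpha, beta, gamma, zeta,
                                   branch = c("alpha", "beta", "gamma"),
                                   kp, sp) {
  branch <- match.arg(branch)
  if (zeta < 1) stop("branched motifs require `zeta >= 1`: ",
                     "at least one synapse precedes the branch point")
  switch(branch,
         alpha = motif_triplet_straight(alpha + zeta, beta, gamma, kp, sp),
         beta  = motif_triplet_straight(alpha, beta + zeta, gamma, kp, sp),
         gamma = motif_triplet_straight(alpha, beta, gamma + zeta, kp, sp))
}

check_paths <- function(...) {
  v <- c(...)
  if (any(v != round(v)) || any(v < 0))
    stop("path lengths must be nonnegative integers")
  if (sum(v) < 1) stop("total path length must be at least 1")
  invisible(TRUE)
}

#' Potentiation rate under the balance condition
#'
#' Balance of total potentiation and depression,
#' \eqn{-A_-\tau_- + r A_+ \tau_+ \tau_y = \delta}, solved for
#' \eqn{A_+ = (A_-\tau_- + \delta) / (r \tau_+ \tau_y)}. Independent of
#' `eta_minus`. A nonzero `delta` tilts the rule toward potentiation
#' (`delta > 0`) or depression (`delta < 0`); the tilt reappears as the
#' zero-order (rate) motif `M0 = delta`.
#'
#' @param sp An [stdp_params()] object.
#' @param rate Stationary firing rate in Hz (> 0).
#' @param delta Balance perturbation (dimensionless, default 0).
#' @return The potentiation learning rate `A_plus`.
#' @examples
#' balanced_potentiation(stdp_params(), rate = 150) # ~ 1.173e-3
#' @export
balanced_potentiation <- function(sp, rate, delta = 0) {
  stopifnot(inherits(sp, "stdp_params"))
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive")
  (sp$A_minus * sp$tau_minus + delta) / (rate * sp$tau_plus * sp$tau_y)
}

# session cache: motif sets are reused at every integration step
the_motif_cache <- new.env(parent = emptyenv())

#' Grouped motif coefficients
#'
#' Computes every motif coefficient entering the truncated (third-order)
#' weight drift and groups the pair- and triplet-rule contributions that
#' share path lengths:
#' `M10 = r M^trip_{1,0}`, `M01 = M^pair_{0,1} + r M^trip_{0,1}`, and so on
#' up to order three, together with the auto-covariance (gamma-path)
#' coefficients — including the loop motifs `a2g0` and `a3g0`, in which the
#' postsynaptic neuron is both source and target of its path — and the
#' straight third-cumulant coefficients `(1,0,1)` and `(1,1,1)`.
#'
#' When `balance = TRUE` (default) `A_plus` is set from
#' [balanced_potentiation()] at the supplied rate and perturbation, and
#' `M0 = delta` exactly; otherwise `M0` is computed from the supplied
#' `A_plus` as the net area \eqn{\tilde L_2(0) + r\tilde L_3(0,0)}.
#'
#' Results are memoised per parameter tuple for the session.
#'
#' @param kp A [kernel_params()] object.
#' @param sp An [stdp_params()] object.
#' @param rate Stationary firing rate in Hz entering the groupings (> 0).
#' @param delta Balance perturbation applied to the zero-order motif.
#' @param balance Set `A_plus` by the balance condition?
#' @return An object of class `motif_set`: a list of named coefficients plus
#'   the parameters used.
#' @export
motif_set <- function(kp, sp, rate, delta = 0, balance = TRUE) {
  stopifnot(inherits(kp, "kernel_params"), inherits(sp, "stdp_params"))
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive")
  key <- paste(kp$tau_eps, kp$tau_iota, sp$A_minus, sp$tau_minus, sp$A_plus,
               sp$tau_plus, sp$tau_y, sp$eta_minus, rate, delta, balance,
               sep = "|")
  hit <- the_motif_cache[[key]]
  if (!is.null(hit)) return(hit)

  if (balance) sp$A_plus <- balanced_potentiation(sp, rate, delta)
  if (is.na(sp$A_plus)) stop("`A_plus` is NA and `balance = FALSE`")
  M0 <- if (balance) delta else
    Re(stdp_pair_ft(0, sp)) + rate * Re(stdp_triplet_ft(0, 0, sp))

  pair <- function(a, b) motif_pair(a, b, kp, sp)
  trip <- function(a, b) motif_triplet_ab(a, b, kp, sp)
  ag <- function(a, g) motif_triplet_ag(a, g, kp, sp)

  out <- structure(list(
    M0  = M0,
    M10 = rate * trip(1, 0),
    M01 = pair(0, 1) + rate * trip(0, 1),
    M20 = rate * trip(2, 0),
    M02 = pair(0, 2) + rate * trip(0, 2),
    M11 = pair(1, 1) + rate * trip(1, 1),
    M30 = rate * trip(3, 0),
    M03 = pair(0, 3) + rate * trip(0, 3),
    M21 = pair(2, 1) + rate * trip(2, 1),
    M12 = pair(1, 2) + rate * trip(1, 2),
    Mtrip_a2g0 = ag(2, 0),
    Mtrip_a1g1 = ag(1, 1),
    Mtrip_a2g1_plus_a1g2 = ag(2, 1) + ag(1, 2),
    Mtrip_a3g0 = ag(3, 0),
    Mtrip_101 = motif_triplet_straight(1, 0, 1, kp, sp),
    Mtrip_111 = motif_triplet_straight(1, 1, 1, kp, sp),
    rate = rate, delta = delta, A_plus = sp$A_plus,
    kernel = kp, stdp = sp), class = "motif_set")
  the_motif_cache[[key]] <- out
  out
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("motif_set (eta- = %g, tau_iota = %g ms, r = %g Hz, A+ = %.4g)\n",
              x$stdp$eta_minus, x$kernel$tau_iota * 1e3, x$rate, x$A_plus))
  co <- unlist(x[seq_len(16)])
  print(signif(co, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a motif set into a tibble
#'
#' @param x A [motif_set()] object.
#' @param ... Unused.
#' @return A tibble with columns `coefficient` and `value`.
#' @method tidy motif_set
#' @export
tidy.motif_set <- function(x, ...) {
  nm <- c("M0", "M10", "M01", "M20", "M02", "M11", "M30", "M03", "M21", "M12",
          "Mtrip_a2g0", "Mtrip_a1g1", "Mtrip_a2g1_plus_a1g2", "Mtrip_a3g0",
          "Mtrip_101", "Mtrip_111")
  tibble::tibble(coefficient = nm, value = unlist(x[nm], use.names = FALSE))
}

#' Serialize / read a motif set as a flat key-value text file
#'
#' @param x A [motif_set()] object.
#' @param path File path.
#' @return `write_motif_set` returns `path` invisibly; `read_motif_set`
#'   returns a named numeric vector of coefficients.
#' @export
write_motif_set <- function(x, path) {
  stopifnot(inherits(x, "motif_set"))
  df <- tidy(x)
  writeLines(sprintf("%s = %.17g", df$coefficient, df$value), path)
  invisible(path)
}

#' @rdname write_motif_set
#' @export
read_motif_set <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln, " = ", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                  vapply(kv, `[[`, "", 1))
}

#' Locate a sign change of a scalar function
#'
#' Bisection to a relative tolerance; used to locate the critical values of
#' the depression modulation parameter or the EPSC rise constant at which a
#' motif coefficient (or a difference of two) changes sign.
#'
#' @param fn A continuous scalar function of one parameter.
#' @param lower,upper Bracket; `fn` must change sign across it.
#' @param tol Relative tolerance on the root (default 1e-3).
#' @return The crossing parameter value.
#' @examples
#' find_crossing(function(x) x - 2, 0, 5)
#' @export
find_crossing <- function(fn, lower, upper, tol = 1e-3) {
  flo <- fn(lower); fhi <- fn(upper)
  if (!is.finite(flo) || !is.finite(fhi))
    stop("`fn` is not finite at the bracket ends")
  if (sign(flo) == sign(fhi))
    stop("no sign change of `fn` inside [", lower, ", ", upper, "]")
  for (i in 1:200) {
    mid <- (lower + upper) / 2
    fm <- fn(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) {
      lower <- mid; flo <- fm
    } else upper <- mid
    if ((upper - lower) <= tol * max(abs(mid), .Machine$double.eps)) break
  }
  (lower + upper) / 2
}

#' Motif coefficients along a parameter sweep
#'
#' Evaluates the grouped coefficients of [motif_set()] on a grid of either
#' the depression modulation parameter or the EPSC rise constant, holding
#' everything else fixed (with `A_plus` balanced at `rate`).
#'
#' @param param `"eta_minus"` or `"tau_iota"`.
#' @param values Grid of parameter values (dimensionless, or seconds for
#'   `tau_iota`).
#' @param kp,sp,rate,delta As in [motif_set()].
#' @return A tibble of class `motif_profile` with one row per (value,
#'   coefficient).
#' @export
motif_profile <- function(param = c("eta_minus", "tau_iota"), values,
                          kp = kernel_params(), sp = stdp_params(),
                          rate = 150, delta = 0) {
  param <- match.arg(param)
  rows <- lapply(values, function(v) {
    if (param == "eta_minus") sp$eta_minus <- v else kp$tau_iota <- v
    ms <- motif_set(kp, sp, rate, delta)
    df <- tidy(ms)
    df$param <- param
    df$value_of_param <- v
    df
  })
  out <- do.call(rbind, rows)
  class(out) <- c("motif_profile", class(out))
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a motif coefficient profile
#'
#' @param object A [motif_profile()] tibble.
#' @param coefficients Which coefficients to draw (default: the grouped
#'   cross-covariance family).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motif_profile
#' @export
autoplot.motif_profile <- function(object,
                                   coefficients = c("M10", "M01", "M11",
                                                    "M02", "M03", "M12"),
                                   ...) {
  df <- object[object$coefficient %in% coefficients, ]
  xlab <- if (df$param[1] == "eta_minus") "depression modulation eta-"
          else "EPSC rise constant tau_iota (s)"
  ggplot2::ggplot(df, ggplot2::aes(x = value_of_param, y = value,
                                   colour = coefficient)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "motif coefficient") +
    ggplot2::theme_minimal()
}
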