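#' EPSC kernel parameters
#'
#' Parameters of the excitatory postsynaptic current (EPSC) kernel
#' \deqn{E(t) = \frac{\tau_\epsilon + \tau_\iota}{\tau_\epsilon^2}
#'   e^{-t/\tau_\epsilon}\,(1 - e^{-t/\tau_\iota}), \quad t \ge 0,}
#' normalized to unit integral so that, on average, one presynaptic spike
#' contributes a number of postsynaptic spikes of the order of the synaptic
#' efficacy. `tau_eps` sets the decay of the current, `tau_iota` the rise;
#' in the limit `tau_iota -> 0` the current jumps instantaneously and decays
#' as a single exponential.
#'
#' @param tau_eps Decay time constant in seconds (> 0).
#' @param tau_iota Rise time constant in seconds (>= 0; 0 selects the pure
#'   exponential limit).
#' @return An object of class `kernel_params`.
#' @examples
#' kp <- kernel_params(5e-3, 5e-3)
#' integrate(function(t) epsc(t, kp), 0, 1)$value # ~ 1
#' @export
kernel_params <- function(tau_eps = 5e-3, tau_iota = 5e-3) {
  stopifnot(is.numeric(tau_eps), length(tau_eps) == 1L, is.finite(tau_eps),
            tau_eps > 0,
            is.numeric(tau_iota), length(tau_iota) == 1L, is.finite(tau_iota),
            tau_iota >= 0)
  structure(list(tau_eps = tau_eps, tau_iota = tau_iota),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("EPSC kernel: tau_eps = %g ms, tau_iota = %g ms\n",
              x$tau_eps * 1e3, x$tau_iota * 1e3))
  invisible(x)
}

#' Plasticity rule parameters
#'
#' Parameters of the minimal triplet STDP rule: depression is driven by
#' post-before-pre spike pairs through the window `L2`, potentiation by
#' pre-post-post spike triplets through the window `L3`. The depression
#' modulation parameter `eta_minus` reshapes `L2` by trading amplitude
#' (`A_minus / eta_minus`) against time constant (`eta_minus * tau_minus`),
#' leaving the total depression `A_minus * tau_minus` unchanged — the
#' signature of neuromodulatory reshaping of the learning window.
#'
#' `A_plus` may be left `NA` when it is to be set by the
#' potentiation/depression balance condition (see [balanced_potentiation()]).
#'
#' @param A_minus Depression learning rate (dimensionless, >= 0).
#' @param tau_minus Depression time constant (s).
#' @param A_plus Triplet potentiation learning rate (dimensionless, >= 0 or
#'   `NA`).
#' @param tau_plus First potentiation time constant (s).
#' @param tau_y Second potentiation time constant (s), gating the influence
#'   of the previous postsynaptic spike.
#' @param eta_minus Depression modulation parameter (>= 1).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(A_minus = 0.01, tau_minus = 33.7e-3, A_plus = NA_real_,
                        tau_plus = 16.8e-3, tau_y = 114e-3, eta_minus = 1) {
  stopifnot(A_minus >= 0, tau_minus > 0, tau_plus > 0, tau_y > 0,
            eta_minus >= 1, is.na(A_plus) || A_plus >= 0)
  structure(list(A_minus = A_minus, tau_minus = tau_minus, A_plus = A_plus,
                 tau_plus = tau_plus, tau_y = tau_y, eta_minus = eta_minus),
            class = "stdp_params")
}

#' @export
print.stdp_params <- function(x, ...) {
  cat(sprintf(paste0("triplet STDP rule: A- = %g, tau- = %g ms, eta- = %g; ",
                     "A+ = %s, tau+ = %g ms, tau_y = %g ms\n"),
              x$A_minus, x$tau_minus * 1e3, x$eta_minus,
              if (is.na(x$A_plus)) "(balance)" else format(x$A_plus),
              x$tau_plus * 1e3, x$tau_y * 1e3))
  invisible(x)
}

#' EPSC kernel in the time domain
#'
#' @param t Time in seconds (vectorized). Values `t < 0` return 0 (causality).
#' @param kp A [kernel_params()] object.
#' @return Numeric vector, the kernel evaluated at `t` (units 1/s).
#' @export
epsc <- function(t, kp) {
  stopifnot(inherits(kp, "kernel_params"))
  if (any(!is.finite(t))) stop("non-finite time in `t`")
  te <- kp$tau_eps; ti <- kp$tau_iota
  out <- numeric(length(t))
  pos <- t >= 0
  if (ti == 0) {
    out[pos] <- exp(-t[pos] / te) / te
  } else {
    out[pos] <- (te + ti) / te^2 * exp(-t[pos] / te) * (1 - exp(-t[pos] / ti))
  }
  out
}

#' EPSC kernel in the frequency domain
#'
#' Fourier transform with the `e^{-i w t}` convention, so that
#' `epsc_ft(0, kp) == 1` (unit-integral kernel) and
#' `epsc_ft(-w, kp) == Conj(epsc_ft(w, kp))`.
#'
#' @param omega Angular frequency in rad/s (vectorized).
#' @param kp A [kernel_params()] object.
#' @return Complex vector.
#' @export
epsc_ft <- function(omega, kp) {
  stopifnot(inherits(kp, "kernel_params"))
  te <- kp$tau_eps; ti <- kp$tau_iota
  a <- 1 / te
  cc <- if (ti == 0) 1 / te else (te + ti) / te^2
  out <- cc / (a + 1i * omega)
  if (ti > 0) out <- out - cc / (a + 1 / ti + 1i * omega)
  out
}

#' Pair-based depression window
#'
#' `L2(tau1)` with `tau1 = t_post - t_pre`: exponential depression for
#' post-before-pre pairs (`tau1 < 0`), zero otherwise. The integral is
#' `-A_minus * tau_minus` for every `eta_minus`.
#'
#' @param tau1 Time lag in seconds (vectorized).
#' @param sp An [stdp_params()] object.
#' @return Numeric vector (dimensionless weight change per spike pair).
#' @export
stdp_pair_window <- function(tau1, sp) {
  stopifnot(inherits(sp, "stdp_params"))
  out <- numeric(length(tau1))
  neg <- tau1 < 0
  out[neg] <- -(sp$A_minus / sp$eta_minus) *
    exp(tau1[neg] / (sp$eta_minus * sp$tau_minus))
  out
}

#' Fourier transform of the pair window
#'
#' @inheritParams stdp_pair_window
#' @param omega Angular frequency in rad/s (vectorized).
#' @return Complex vector; `stdp_pair_ft(0, sp) == -A_minus * tau_minus`.
#' @export
stdp_pair_ft <- function(omega, sp) {
  stopifnot(inherits(sp, "stdp_params"))
  tm <- sp$eta_minus * sp$tau_minus
  -sp$A_minus * sp$tau_minus * (1 + 1i * tm * omega) / (1 + tm^2 * omega^2)
}

#' Triplet potentiation window
#'
#' `L3(tau1, tau2)` with `tau1 = t_post - t_pre` and
#' `tau2 = t_post - t_post'` (lag to the previous postsynaptic spike):
#' potentiation only when both lags are nonnegative.
#'
#' @param tau1,tau2 Time lags in seconds (vectorized, recycled).
#' @param sp An [stdp_params()] object with a finite `A_plus`.
#' @return Numeric vector.
#' @export
stdp_triplet_window <- function(tau1, tau2, sp) {
  stopifnot(inherits(sp, "stdp_params"), !is.na(sp$A_plus))
  n <- max(length(tau1), length(tau2))
  tau1 <- rep_len(tau1, n); tau2 <- rep_len(tau2, n)
  out <- numeric(n)
  on <- tau1 >= 0 & tau2 >= 0
  out[on] <- sp$A_plus * exp(-tau1[on] / sp$tau_plus - tau2[on] / sp$tau_y)
  out
}

#' Fourier transform of the triplet window
#'
#' @inheritParams stdp_triplet_window
#' @param omega1,omega2 Angular frequencies in rad/s (vectorized, recycled).
#' @return Complex vector;
#'   `stdp_triplet_ft(0, 0, sp) == A_plus * tau_plus * tau_y`.
#' @export
stdp_triplet_ft <- function(omega1, omega2, sp) {
  stopifnot(inherits(sp, "stdp_params"), !is.na(sp$A_plus))
  sp$A_plus * sp$tau_plus * sp$tau_y /
    ((1 + 1i * sp$tau_plus * omega1) * (1 + 1i * sp$tau_y * omega2))
}
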