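# Internal quadrature helpers for motif and drift integrals. Integrands are
# smooth, polynomially decaying rational functions of frequency; the whole
# line is mapped to (-pi/2, pi/2) by the tangent substitution where a fixed
# scheme is used.

# adaptive integral of Re(f) over the real line, with the 1/(2pi) factor of
# the inverse-transform convention applied by the caller
quad_line <- function(f, rel_tol = 1e-9) {
  out <- tryCatch(
    stats::integrate(function(w) Re(f(w)), -Inf, Inf, rel.tol = rel_tol,
                     abs.tol = 1e-14, subdivisions = 500L),
    error = function(e) stop("line quadrature failed: ", conditionMessage(e),
                             call. = FALSE))
  if (out$message != "OK")
    stop("line quadrature did not converge: ", out$message, call. = FALSE)
  out$value
}

# adaptive 2-D integral of Re(f) over the plane: nested 1-D adaptive rules
# on the scaled tangent substitution w = scale * tan(theta). The scale pins
# the substitution pivot to the frequency band where the kernel and window
# transforms actually vary (without it the integrand structure collapses
# into the last fraction of the theta interval and tensor rules converge
# only algebraically).
quad_plane <- function(f, rel_tol = 1e-8, scale = 100) {
  inner <- function(w2) {
    r <- stats::integrate(function(th) {
      w1 <- scale * tan(th)
      Re(f(w1, w2)) * scale / cos(th)^2
    }, -pi / 2, pi / 2, rel.tol = rel_tol * 1e-1, abs.tol = 1e-16,
    subdivisions = 500L, stop.on.error = FALSE)
    r$value
  }
  out <- stats::integrate(Vectorize(function(th2) {
    w2 <- scale * tan(th2)
    inner(w2) * scale / cos(th2)^2
  }), -pi / 2, pi / 2, rel.tol = rel_tol, abs.tol = 1e-16,
  subdivisions = 500L, stop.on.error = FALSE)
  if (!is.finite(out$value))
    stop("plane quadrature failed: non-finite result", call. = FALSE)
  out$value
}

# fixed Gauss-Legendre rule on the scaled tangent-substituted line; returns
# nodes (frequencies) and weights including the substitution Jacobian
gauss_line <- function(n, scale = 100) {
  gl <- pracma::gaussLegendre(n, -pi / 2 + 1e-9, pi / 2 - 1e-9)
  list(w = scale * tan(gl$x), wt = scale * gl$w / cos(gl$x)^2)
}
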