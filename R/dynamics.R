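# Mean-field weight dynamics: motif-truncated STDP drift, heterosynaptic
# competition, inhibitory balance, adaptive Euler integration to steady
# state.

#' Term mask for the truncated drift
#'
#' Selects motif groups by the cumulant they originate from: the
#' cross-covariance family (`M10 ... M03`), the non-loop and loop parts of
#' the auto-covariance (gamma-path) family, and the third-cumulant straight
#' paths. Used to dissect which spike interactions drive assembly
#' formation.
#'
#' @param cross_cov,auto_cov_nonloop,auto_cov_loops,third_cumulant Logical
#'   flags.
#' @return An object of class `term_mask`.
#' @export
term_mask <- function(cross_cov = TRUE, auto_cov_nonloop = TRUE,
                      auto_cov_loops = TRUE, third_cumulant = TRUE) {
  if (!cross_cov)
    warning("dynamics without the cross-covariance terms are degenerate")
  structure(list(cross_cov = cross_cov,
                 auto_cov_nonloop = auto_cov_nonloop,
                 auto_cov_loops = auto_cov_loops,
                 third_cumulant = third_cumulant), class = "term_mask")
}

#' Motif-truncated STDP drift
#'
#' The mean synaptic drift truncated at third order in the connectivity:
#' zeroth- (rate), first-, second- and third-order terms with the grouped
#' coefficients of a [motif_set()], the index sums excluding the pre- and
#' postsynaptic neuron exactly as the expansion prescribes (exclusions that
#' reduce to the zero diagonal are left implicit). Matrix powers use the
#' raw excitatory matrix.
#'
#' @param W Excitatory weight matrix (zero diagonal).
#' @param motifs A [motif_set()] object.
#' @param rates Stationary rate vector in Hz (scalar recycled).
#' @param mask A [term_mask()].
#' @return Drift matrix in weight units per second, zero diagonal.
#' @export
stdp_drift <- function(W, motifs, rates, mask = term_mask()) {
  stopifnot(inherits(motifs, "motif_set"), inherits(mask, "term_mask"))
  n <- nrow(W)
  if (ncol(W) != n) stop("`W` must be square")
  r <- rep_len(rates, n)
  co <- motifs
  Wt <- t(W)
  W2 <- W %*% W; W3 <- W2 %*% W
  d2 <- diag(W2); d3 <- diag(W3)
  sq <- W * W
  rj <- matrix(r, n, n, byrow = TRUE) # r_j over columns
  ri <- matrix(r, n, n)               # r_i over rows
  D <- co$M0 * ri * rj
  if (mask$cross_cov) {
    D <- D + co$M10 * rj * W + co$M01 * ri * Wt +
      co$M11 * (W %*% (r * Wt)) +
      co$M20 * rj * W2 + co$M02 * ri * t(W2) +
      co$M21 * ((W2 %*% (r * Wt)) - (d2 * r) * Wt) +
      co$M12 * ((W %*% (r * t(W2))) - W * matrix(d2 * r, n, n, byrow = TRUE)) +
      co$M30 * rj * W3 + co$M03 * ri * t(W3)
  }
  if (mask$auto_cov_nonloop) {
    s1 <- as.numeric(sq %*% r)       # sum_k r_k W_ik^2
    s2 <- as.numeric((W2 * W) %*% r) # sum_k r_k (W^2)_ik W_ik
    D <- D + co$Mtrip_a1g1 * rj * (matrix(s1, n, n) - rj * sq) +
      co$Mtrip_a2g1_plus_a1g2 * rj * (matrix(s2, n, n) - rj * W2 * W)
  }
  if (mask$auto_cov_loops) {
    D <- D + co$Mtrip_a2g0 * ri * rj * (matrix(d2, n, n) - W * Wt) +
      co$Mtrip_a3g0 * ri * rj * matrix(d3, n, n)
  }
  if (mask$third_cumulant) {
    D <- D + co$Mtrip_101 * rj * sq +
      co$Mtrip_111 * (sq %*% (r * Wt))
  }
  diag(D) <- 0
  D
}

#' Heterosynaptic competition drift
#'
#' Each neuron's summed afferent (row) and efferent (column) efficacies are
#' limited to `W_max`: when the row sum of the postsynaptic neuron or the
#' column sum of the presynaptic neuron exceeds the bound, every synapse in
#' that row or column is pushed down proportionally to the excess. Zero
#' whenever both sums are within the bound.
#'
#' @param W Weight matrix.
#' @param cfg A [network_config()] object (provides `W_max`).
#' @return Drift matrix (weight units; dimensionless deficit), zero
#'   diagonal.
#' @export
heterosynaptic_drift <- function(W, cfg) {
  n <- nrow(W)
  rin <- rowSums(W)   # afferent sum of the postsynaptic neuron i
  cout <- colSums(W)  # efferent sum of the presynaptic neuron j
  D <- matrix(pmin(cfg$W_max - rin, 0), n, n) +
    matrix(pmin(cfg$W_max - cout, 0), n, n, byrow = TRUE)
  diag(D) <- 0
  D
}

#' External-drive drift from structured input correlations
#'
#' Contribution to the weight drift of externally correlated input acting
#' as common drive: the external covariance is filtered through the network
#' (expanded in powers of the interaction kernel to total order
#' `order`) and read out through both the pair and triplet windows, giving
#' \deqn{\sum_{a+b \le order} W^a C^{ext} (W^b)^T \cdot X_{a+1,b+1}} with
#' `X` the grouped pair-plus-rate-times-triplet coefficient of the
#' corresponding path lengths.
#'
#' @param W Weight matrix.
#' @param C_ext External covariance matrix (e.g. from
#'   [build_external_covariance()]); `NULL` or all-zero gives zero drift.
#' @param kp,sp Kernel and rule parameters (with `A_plus` resolved).
#' @param rate Stationary rate in Hz.
#' @param order Total truncation order in the connectivity (default 3).
#' @return Drift matrix in weight units per second, zero diagonal.
#' @export
external_drive_drift <- function(W, C_ext, kp, sp, rate, order = 3L) {
  n <- nrow(W)
  if (is.null(C_ext) || all(C_ext == 0)) return(matrix(0, n, n))
  if (is.na(sp$A_plus)) sp$A_plus <- balanced_potentiation(sp, rate)
  D <- matrix(0, n, n)
  Wp <- list(diag(n)) # powers 0 .. order
  for (a in seq_len(order)) Wp[[a + 1]] <- Wp[[a]] %*% W
  for (a in 0:order) for (b in 0:(order - a)) {
    key <- paste("ext", kp$tau_eps, kp$tau_iota, sp$A_minus, sp$tau_minus,
                 sp$A_plus, sp$tau_plus, sp$tau_y, sp$eta_minus, rate,
                 a, b, sep = "|")
    X <- the_motif_cache[[key]]
    if (is.null(X)) {
      X <- motif_pair(a + 1, b + 1, kp, sp) +
        rate * motif_triplet_ab(a + 1, b + 1, kp, sp)
      the_motif_cache[[key]] <- X
    }
    D <- D + X * (Wp[[a + 1]] %*% C_ext %*% t(Wp[[b + 1]]))
  }
  diag(D) <- 0
  D
}

#' Integrate the weight dynamics to steady state
#'
#' Euler integration of the combined drift
#' \eqn{\dot W = \nu\,(F_{stdp}(W) + \psi F_{hc}(W))} with an adaptive step
#' chosen so the largest per-step weight change equals `step_cap`. Weights
#' are clipped to `[0, w_max]` with the diagonal held at zero, and the
#' inhibitory balance is recomputed every step (with the default fixed-rate
#' convention it leaves the stationary rates at the external input rate, so
#' motif coefficients are computed once).
#'
#' The integration clock runs in milliseconds: Table-quoted time constants
#' and the dimensionless competition deficit are mutually consistent on
#' that base, and the STDP drift (natively per second) is converted
#' internally.
#'
#' Convergence is structural: the run stops once the matrix has changed by
#' less than `tol_w` (absolute) over a `window`-step window — after
#' saturation the adaptive step keeps the boundary chattering at `step_cap`
#' forever, so a pointwise per-step criterion cannot terminate.
#'
#' @param W0 Initial weight matrix (e.g. [initial_weights()]).
#' @param cfg A [network_config()] object.
#' @param kp,sp Kernel and rule parameters; `A_plus = NA` is balanced at
#'   the external rate with perturbation `cfg$delta`.
#' @param mask A [term_mask()].
#' @param C_ext Optional external covariance matrix.
#' @param rates_mode `"fixed"` (default) holds the rates entering the
#'   coefficients at the external input rate; `"track"` recomputes the
#'   stationary rates of the balanced network every `rate_update` steps.
#' @param max_steps,window,tol_w,step_cap,rate_update Integration controls.
#' @param keep_trajectory Record snapshots every `window` steps?
#' @param on_nonconvergence `"error"` (default) or `"warn"`.
#' @return An object of class `assembly_sim`: final `W`, `steps`,
#'   `converged`, the parameters, and optionally `trajectory` (list of
#'   matrices).
#' @export
integrate_weights <- function(W0, cfg, kp = kernel_params(),
                              sp = stdp_params(), mask = term_mask(),
                              C_ext = NULL,
                              rates_mode = c("fixed", "track"),
                              max_steps = 60000L, window = 500L,
                              tol_w = 1e-3, step_cap = 0.00035,
                              rate_update = 250L,
                              keep_trajectory = FALSE,
                              on_nonconvergence = c("error", "warn")) {
  rates_mode <- match.arg(rates_mode)
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(inherits(cfg, "network_config"))
  W <- W0
  n <- nrow(W)
  rate0 <- mean(cfg$mu)
  motifs <- motif_set(kp, sp, rate0, delta = cfg$delta,
                      balance = is.na(sp$A_plus))
  sp$A_plus <- motifs$A_plus
  rates <- rep_len(cfg$mu, n)
  traj <- list()
  Wref <- W
  converged <- FALSE
  ms <- 1e-3 # drift per millisecond: the integration time base
  s <- 0L
  while (s < max_steps) {
    s <- s + 1L
    if (rates_mode == "track" && s %% rate_update == 1L)
      rates <- stationary_rates(W, cfg, kp)
    Dstdp <- stdp_drift(W, motifs, rates, mask)
    Dext <- if (is.null(C_ext)) 0 else
      external_drive_drift(W, C_ext, kp, sp, rate0)
    D <- cfg$nu * (ms * (Dstdp + Dext) + cfg$psi * heterosynaptic_drift(W, cfg))
    mx <- max(abs(D))
    if (mx == 0) { converged <- TRUE; break }
    W <- W + (step_cap / mx) * D
    W[W < 0] <- 0
    W[W > cfg$w_max] <- cfg$w_max
    diag(W) <- 0
    if (s %% window == 0L) {
      if (keep_trajectory) traj[[length(traj) + 1L]] <- W
      if (max(abs(W - Wref)) < tol_w) { converged <- TRUE; break }
      Wref <- W
    }
  }
  if (!converged) {
    msg <- sprintf("weight dynamics not converged after %d steps", s)
    if (on_nonconvergence == "error") {
      cond <- simpleError(msg)
      cond$W <- W
      stop(cond)
    }
    warning(msg)
  }
  structure(list(W = W, steps = s, converged = converged, cfg = cfg,
                 kernel = kp, stdp = sp, mask = mask, motifs = motifs,
                 trajectory = if (keep_trajectory) traj else NULL),
            class = "assembly_sim")
}

#' @export
print.assembly_sim <- function(x, ...) {
  cat(sprintf("assembly_sim: N = %d, %d steps, converged = %s\n",
              nrow(x$W), x$steps, x$converged))
  cat(sprintf("  saturated weights: %.1f%%, mean row sum: %.3f\n",
              100 * mean(x$W > 0.95 * x$cfg$w_max),
              mean(rowSums(x$W))))
  invisible(x)
}

#' Tidy the steady-state weight matrix into long form
#'
#' @param x An `assembly_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `row_id`, `col_id`, `weight`.
#' @method tidy assembly_sim
#' @export
tidy.assembly_sim <- function(x, ...) {
  n <- nrow(x$W)
  tibble::tibble(row_id = rep(seq_len(n), n),
                 col_id = rep(seq_len(n), each = n),
                 weight = as.numeric(x$W))
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of an integration
#'
#' @param x An `assembly_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: steps, convergence flag, graph metrics of the
#'   binarized steady state.
#' @method glance assembly_sim
#' @export
glance.assembly_sim <- function(x, ...) {
  gm <- graph_metrics(x$W, threshold = x$cfg$w_max / 2)
  tibble::tibble(steps = x$steps, converged = x$converged,
                 mean_clustering = gm$mean_clustering,
                 global_efficiency = gm$global_efficiency,
                 modularity = gm$modularity,
                 frac_unidirectional = gm$frac_unidirectional,
                 frac_bidirectional = gm$frac_bidirectional)
}

#' Plot a steady-state weight matrix
#'
#' Heatmap of the (optionally k-means reordered) weight matrix.
#'
#' @param object An `assembly_sim` object.
#' @param reorder Reorder neurons by k-means connectivity clustering?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot assembly_sim
#' @export
autoplot.assembly_sim <- function(object, reorder = TRUE, ...) {
  W <- object$W
  if (reorder) W <- kmeans_reorder(W)$W
  n <- nrow(W)
  df <- tibble::tibble(row_id = rep(seq_len(n), n),
                       col_id = rep(seq_len(n), each = n),
                       weight = as.numeric(W))
  ggplot2::ggplot(df, ggplot2::aes(col_id, row_id, fill = weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "presynaptic neuron", y = "postsynaptic neuron") +
    ggplot2::theme_minimal()
}
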