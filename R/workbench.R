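# Orchestration: reference parameter sets, seeded multi-trial sweeps over
# the modulation parameters, block-structured external input, persistence.

#' Reference parameter sets
#'
#' The experimentally anchored defaults used throughout: N = 48 neurons,
#' 150 Hz external drive, weight bound 0.17 with row/column bound 0.85
#' (five saturated synapses per neuron), depression A- = 0.01 with
#' tau- = 33.7 ms, potentiation constants tau+ = 16.8 ms and tau_y = 114 ms
#' (fits of the minimal triplet rule to cortical slice data), EPSC decay
#' and rise constants of 5 ms, learning-rate scale 3.5e-4 and competition
#' scale 0.7.
#'
#' @return [default_network_config()], [default_kernel_params()] and
#'   [default_stdp_params()] return the corresponding parameter objects.
#' @param eta_minus Depression modulation parameter for the rule.
#' @export
default_network_config <- function() network_config()

#' @rdname default_network_config
#' @export
default_kernel_params <- function() kernel_params(5e-3, 5e-3)

#' @rdname default_network_config
#' @export
default_stdp_params <- function(eta_minus = 1) stdp_params(eta_minus = eta_minus)

#' Block-structured external covariance
#'
#' Covariance matrix of externally correlated drive that promotes the
#' joint activity of neurons sharing an assembly label: in-block
#' off-diagonal pairs get `strength * w_max`, everything else 0.
#'
#' @param assignment Integer vector of assembly labels covering all
#'   neurons.
#' @param strength Pairwise correlation strength as a ratio of the
#'   single-synapse bound `w_max` (presets 0.01, 0.05, 0.125, 0.25, 0.375,
#'   0.5; any nonnegative value allowed).
#' @param cfg A [network_config()] object.
#' @return A symmetric `N x N` matrix with zero diagonal.
#' @export
build_external_covariance <- function(assignment, strength, cfg) {
  stopifnot(inherits(cfg, "network_config"))
  if (length(assignment) != cfg$N)
    stop("`assignment` must label every neuron")
  if (anyNA(assignment)) stop("`assignment` must not contain NA")
  C <- (outer(assignment, assignment, "==") * 1) * strength * cfg$w_max
  diag(C) <- 0
  C
}

#' Seeded multi-trial parameter sweep
#'
#' For every grid value of the swept parameter and every trial: draw a
#' seeded random initial matrix, integrate the weight dynamics to steady
#' state, and compute graph metrics of the binarized steady state.
#' Per-trial seeds are `seed * 1000 + trial` (counter-based, below 2^31),
#' so trials are independent and reorderable, and the same base seed
#' reproduces the table exactly.
#'
#' @param param One of `"eta_minus"`, `"tau_iota"`, `"delta"`,
#'   `"ext_correlation"`, `"mu"`, `"delta_inh"`.
#' @param values Grid of parameter values.
#' @param trials Trials (independent initial conditions) per grid point.
#' @param seed Base seed.
#' @param cfg,kp,sp Base parameter objects.
#' @param mask A [term_mask()].
#' @param assignment Assembly labels for `param = "ext_correlation"`
#'   (default: two equal blocks).
#' @param keep_matrices Keep the steady-state matrices in the result?
#' @param ... Further arguments passed to [integrate_weights()].
#' @return An object of class `sweep_result`: a list with `metrics` (tibble
#'   of per-trial metrics), `summary` (per-grid-point means and standard
#'   errors) and optionally `matrices`.
#' @export
run_sweep <- function(param = c("eta_minus", "tau_iota", "delta",
                                "ext_correlation", "mu", "delta_inh"),
                      values, trials = 10L, seed = 1L,
                      cfg = default_network_config(),
                      kp = default_kernel_params(),
                      sp = default_stdp_params(),
                      mask = term_mask(), assignment = NULL,
                      keep_matrices = FALSE, ...) {
  param <- match.arg(param)
  stopifnot(length(values) >= 1L, trials >= 1L)
  rows <- list()
  mats <- list()
  for (v in values) {
    cfg_v <- cfg; kp_v <- kp; sp_v <- sp; C_ext <- NULL
    switch(param,
           eta_minus = { sp_v$eta_minus <- v },
           tau_iota = { kp_v$tau_iota <- v },
           delta = { cfg_v$delta <- v },
           mu = { cfg_v$mu <- rep_len(v, cfg$N) },
           delta_inh = { cfg_v$delta_inh <- v },
           ext_correlation = {
             if (is.null(assignment))
               assignment <- rep(1:2, each = ceiling(cfg$N / 2))[seq_len(cfg$N)]
             C_ext <- build_external_covariance(assignment, v, cfg_v)
           })
    for (tr in seq_len(trials)) {
      tr_seed <- as.integer(seed) * 1000L + tr
      W0 <- initial_weights(cfg_v, tr_seed)
      sim <- integrate_weights(W0, cfg_v, kp_v, sp_v, mask, C_ext = C_ext,
                               on_nonconvergence = "warn", ...)
      gm <- graph_metrics(sim$W, threshold = cfg_v$w_max / 2)
      gm$param <- param
      gm$param_value <- v
      gm$trial <- tr
      gm$seed <- tr_seed
      gm$steps <- sim$steps
      gm$converged <- sim$converged
      rows[[length(rows) + 1L]] <- gm
      if (keep_matrices)
        mats[[sprintf("%s=%g_trial%d", param, v, tr)]] <- sim$W
    }
  }
  metrics <- do.call(rbind, rows)
  long <- NULL
  for (m in c("mean_clustering", "global_efficiency", "modularity",
              "frac_unidirectional", "frac_bidirectional")) {
    agg <- stats::aggregate(metrics[[m]], list(param_value = metrics$param_value),
                            function(x) c(mean = mean(x, na.rm = TRUE),
                                          se = stats::sd(x, na.rm = TRUE) /
                                            sqrt(sum(!is.na(x)))))
    long <- rbind(long, tibble::tibble(param = param,
                                       param_value = agg$param_value,
                                       metric = m,
                                       mean_value = agg$x[, "mean"],
                                       se = agg$x[, "se"]))
  }
  structure(list(metrics = metrics, summary = long,
                 matrices = if (keep_matrices) mats else NULL,
                 param = param, base_seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep over %s (%d points x %d trials, base seed %d)\n",
              x$param, length(unique(x$metrics$param_value)),
              max(x$metrics$trial), x$base_seed))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Plot a sweep result
#'
#' Mean and standard error of each graph metric against the swept
#' parameter.
#'
#' @param object A [run_sweep()] result.
#' @param metrics Which metrics to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object,
                                  metrics = c("mean_clustering",
                                              "global_efficiency",
                                              "modularity"), ...) {
  df <- object$summary[object$summary$metric %in% metrics, ]
  ggplot2::ggplot(df, ggplot2::aes(param_value, mean_value)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean_value - se,
                                          ymax = mean_value + se)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = object$param, y = NULL) +
    ggplot2::theme_minimal()
}

#' Sweep presets reproducing the reference experiments
#'
#' Named presets for the main experiments: the depression-modulation sweep
#' (`"eta"`, with connection fractions and metrics), the motif-mask
#' comparison at fixed modulation (`"masks"`), the EPSC rise-constant sweep
#' (`"epsc"`), the external-correlation sweep (`"external"`) and the
#' balance-perturbation comparison (`"imbalance"`). Trial counts are scaled
#' to desk hardware; raise `trials` for publication-grade error bars.
#'
#' @param name Preset name.
#' @param trials Trials per grid point.
#' @param seed Base seed.
#' @param ... Passed to [run_sweep()].
#' @return A `sweep_result`, or for `"masks"` a named list of them.
#' @export
sweep_preset <- function(name = c("eta", "epsc", "external", "imbalance",
                                  "masks"),
                         trials = 5L, seed = 1L, ...) {
  name <- match.arg(name)
  switch(name,
    eta = run_sweep("eta_minus", c(1, 5, 9, 13), trials, seed, ...),
    epsc = run_sweep("tau_iota", c(5, 15, 25, 35) * 1e-3, trials, seed,
                     ...),
    external = run_sweep("ext_correlation",
                         c(0.01, 0.05, 0.125, 0.25, 0.375, 0.5), trials,
                         seed, ...),
    imbalance = run_sweep("delta", c(-1e-4, 0, 1e-4), trials, seed,
                          sp = default_stdp_params(eta_minus = 13), ...),
    masks = {
      masks <- list(
        cross_only = term_mask(TRUE, FALSE, FALSE, FALSE),
        no_loops = term_mask(TRUE, TRUE, FALSE, TRUE),
        cross_loops = term_mask(TRUE, FALSE, TRUE, FALSE),
        all = term_mask())
      lapply(masks, function(m)
        run_sweep("eta_minus", 13, trials, seed, mask = m, ...))
    })
}
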