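# Graph-theoretic characterization of steady-state connectivity, following
# the binary directed conventions of the Brain Connectivity Toolbox.

#' Binarize a weight matrix
#'
#' `A_ij = 1` iff `W_ij > threshold`, diagonal zero. Heterosynaptic
#' competition drives steady-state weights toward the bounds, so the
#' default cut at half the single-synapse bound is insensitive to its exact
#' placement.
#'
#' @param W Weight matrix.
#' @param threshold Cut value (strictly between 0 and the weight bound).
#' @return An integer adjacency matrix.
#' @export
binarize <- function(W, threshold) {
  stopifnot(is.matrix(W), threshold > 0)
  A <- (W > threshold) * 1L
  diag(A) <- 0L
  A
}

#' Directed clustering coefficient
#'
#' Per-node fraction of realized directed triangles among the possible ones
#' (the binary directed clustering of the Brain Connectivity Toolbox):
#' \eqn{C_i = t_i / [d^{tot}_i(d^{tot}_i - 1) - 2 d^{bi}_i]} with
#' \eqn{t_i = \frac{1}{2}[(A + A^T)^3]_{ii}}. Nodes without an admissible
#' triple contribute 0.
#'
#' @param A Binary adjacency matrix (directed, zero diagonal).
#' @return A list with `per_node` (numeric vector) and `mean`.
#' @export
clustering_coefficient <- function(A) {
  S <- A + t(A)
  t_i <- diag(S %*% S %*% S) / 2
  dtot <- rowSums(A) + colSums(A)
  dbi <- diag(A %*% A)
  den <- dtot * (dtot - 1) - 2 * dbi
  per <- ifelse(den > 0, t_i / den, 0)
  list(per_node = per, mean = mean(per))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs (unreachable
#' pairs contribute zero), normalized by the complete graph, for which the
#' measure equals 1. Degenerate (empty) graphs — as produced by binarizing
#' a matrix whose entries are all identical — are refused.
#'
#' @param A Binary adjacency matrix (directed).
#' @return A scalar in `[0, 1]`.
#' @export
global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) stop("at least two nodes required")
  off <- A[row(A) != col(A)]
  if (all(off == 0))
    stop("global efficiency undefined: degenerate (empty) graph")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  d <- igraph::distances(g, mode = "out")
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1)) # complete-graph reference value is 1
}

#' Modularity of the detected community partition
#'
#' Community detection (Louvain, or spectral leading-eigenvector) on the
#' symmetrized graph, scored by Newman's directed modularity
#' \eqn{Q = \frac{1}{m}\sum_{ij}(A_{ij} - k^{out}_i k^{in}_j / m)
#' \delta(c_i, c_j)} of the detected partition on the directed graph.
#' Louvain detection keeps the best of `restarts` runs.
#'
#' @param W Weight or adjacency matrix; binarized at `threshold` unless it
#'   already is binary.
#' @param method `"louvain"` or `"spectral"`.
#' @param threshold Binarization cut (default half the largest weight).
#' @param restarts Louvain restarts (default 5).
#' @return A list with `Q`, `membership` and `n_communities`.
#' @export
graph_modularity <- function(W, method = c("louvain", "spectral"),
                             threshold = max(W) / 2, restarts = 5L) {
  method <- match.arg(method)
  A <- if (all(W %in% c(0, 1))) W else binarize(W, threshold)
  if (sum(A) == 0) stop("modularity undefined for an empty graph")
  m <- sum(A)
  kin <- colSums(A); kout <- rowSums(A)
  score <- function(mem)
    sum((A - outer(kout, kin) / m) * outer(mem, mem, "==")) / m
  # Newman-style fine tuning: greedily move single nodes between the
  # detected communities while the directed Q improves
  refine <- function(mem) {
    n <- length(mem)
    repeat {
      improved <- FALSE
      for (v in seq_len(n)) {
        cur <- mem[v]
        qcur <- score(mem)
        for (cand in setdiff(unique(mem), cur)) {
          mem2 <- mem; mem2[v] <- cand
          if (score(mem2) > qcur + 1e-12) {
            mem <- mem2; qcur <- score(mem2); improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    mem
  }
  # detection must not depend on (or disturb) the caller's RNG stream
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  gu <- igraph::graph_from_adjacency_matrix(pmax(A, t(A)), mode = "undirected")
  if (method == "louvain") {
    best <- NULL; bestQ <- -Inf
    for (k in seq_len(restarts)) {
      set.seed(k)
      mem <- refine(as.integer(igraph::membership(igraph::cluster_louvain(gu))))
      q <- score(mem)
      if (q > bestQ) { bestQ <- q; best <- mem }
    }
  } else {
    best <- refine(as.integer(igraph::membership(
      igraph::cluster_leading_eigen(gu))))
    bestQ <- score(best)
  }
  list(Q = bestQ, membership = best, n_communities = length(unique(best)))
}

#' Unidirectional and bidirectional connection fractions
#'
#' Over unordered neuron pairs: bidirectional if both directions exceed the
#' threshold, unidirectional if exactly one does; fractions of all
#' `N(N-1)/2` pairs.
#'
#' @param W Weight matrix.
#' @param threshold Binarization cut.
#' @return A list with `frac_unidirectional` and `frac_bidirectional`.
#' @export
connection_fractions <- function(W, threshold) {
  A <- binarize(W, threshold)
  n <- nrow(A)
  nbi <- sum(A * t(A)) / 2
  nuni <- sum(A) - 2 * nbi
  np <- n * (n - 1) / 2
  list(frac_unidirectional = nuni / np, frac_bidirectional = nbi / np)
}

#' Graph metrics of a steady-state matrix
#'
#' Convenience wrapper: binarize and compute the mean clustering
#' coefficient, global efficiency, modularity (Louvain) and connection
#' fractions.
#'
#' @param W Weight matrix.
#' @param threshold Binarization cut (default half the single-synapse
#'   bound passed as `w_max`, or half the largest weight).
#' @param w_max Optional single-synapse bound.
#' @return A one-row tibble.
#' @export
graph_metrics <- function(W, threshold = NULL, w_max = NULL) {
  if (is.null(threshold))
    threshold <- if (!is.null(w_max)) w_max / 2 else max(W) / 2
  A <- binarize(W, threshold)
  cl <- clustering_coefficient(A)
  eff <- tryCatch(global_efficiency(A), error = function(e) NA_real_)
  mod <- tryCatch(graph_modularity(A)$Q, error = function(e) NA_real_)
  fr <- connection_fractions(W, threshold)
  tibble::tibble(mean_clustering = cl$mean, global_efficiency = eff,
                 modularity = mod,
                 frac_unidirectional = fr$frac_unidirectional,
                 frac_bidirectional = fr$frac_bidirectional)
}

#' Reorder a matrix by k-means connectivity clustering
#'
#' Clusters neurons on the concatenated outgoing and incoming weight
#' vectors (squared Euclidean distance) and reorders rows and columns by
#' cluster label; presentation only, never feeds the metrics. `k` defaults
#' to the community count found by spectral detection.
#'
#' @param W Weight matrix.
#' @param k Number of clusters (`NULL` for automatic).
#' @param seed Seed for the k-means initialization.
#' @return A list with the permutation `order`, reordered `W`, and
#'   `cluster` labels in the original order.
#' @export
kmeans_reorder <- function(W, k = NULL, seed = 1L) {
  n <- nrow(W)
  if (is.null(k)) {
    k <- tryCatch(graph_modularity(W, method = "spectral")$n_communities,
                  error = function(e) 1L)
    k <- max(1L, min(k, n - 1L))
  }
  if (k > n) stop("`k` must not exceed the number of neurons")
  feats <- cbind(W, t(W))
  if (k == 1L) {
    ord <- seq_len(n)
    cl <- rep(1L, n)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    km <- stats::kmeans(feats, centers = k, nstart = 10L)
    cl <- km$cluster
    ord <- order(cl)
  }
  list(order = ord, W = W[ord, ord], cluster = cl)
}

#' Average matrices elementwise
#'
#' Mean of a list of (typically k-means reordered) steady-state matrices
#' across trials.
#'
#' @param mats Nonempty list of equally sized matrices.
#' @return The elementwise mean matrix.
#' @export
trial_average <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 1L)
  Reduce(`+`, mats) / length(mats)
}
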