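#' Density grid for the threshold sweep
#'
#' @param delta_min,delta_max,step sweep bounds and step (defaults
#'   0.05, 0.35, 0.01: 31 densities).
#' @return numeric vector of densities, strictly increasing in (0, 1].
#' @export
density_grid <- function(delta_min = 0.05, delta_max = 0.35, step = 0.01) {
  if (!(delta_min > 0 && delta_min <= delta_max && delta_max <= 1 && step > 0))
    fc_stop("fconn_invalid_config", "need 0 < delta_min <= delta_max <= 1, step > 0")
  seq(delta_min, delta_max, by = step)
}

#' Proportional density thresholding of a connectivity matrix
#'
#' Retains exactly `round(delta * N(N-1)/2)` strongest edges by (signed)
#' weight, ties broken by ascending (i, j) index so the retained set is
#' platform-independent. Proportional thresholding (rather than an
#' absolute weight cutoff) fixes the edge count, so graphs from
#' different subjects are compared at identical density. Retaining any
#' non-positive edge is refused: comparing binarized negative
#' correlations is not meaningful, so the requested density must be
#' reachable with positive weights.
#'
#' @param cm N x N symmetric connectivity matrix (zero diagonal).
#' @param delta target connection density in (0, 1].
#' @param mode `"binary"` sets retained edges to 1; `"weighted"` keeps
#'   their original weights. Dropped edges become 0.
#' @return thresholded N x N matrix (same mode as requested), with an
#'   `n_edges` attribute.
#' @export
threshold_density <- function(cm, delta, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  cm <- as.matrix(cm)
  n <- nrow(cm)
  if (n < 2L)
    fc_stop("fconn_invalid_config", "matrix must have at least 2 nodes")
  if (delta <= 0 || delta > 1)
    fc_stop("fconn_invalid_config", "delta must be in (0, 1]")
  ut <- which(upper.tri(cm))
  w <- cm[ut]
  n_keep <- round(delta * n * (n - 1) / 2)
  # order by weight descending; ties by ascending linear (i, j) index
  ord <- order(-w, ut)
  keep <- ut[ord[seq_len(n_keep)]]
  if (n_keep > 0 && any(w[ord[seq_len(n_keep)]] <= 0))
    fc_stop("fconn_negative_edges",
            sprintf("density %.3f requires retaining non-positive edges", delta))
  out <- matrix(0, n, n, dimnames = dimnames(cm))
  out[keep] <- if (mode == "binary") 1 else cm[keep]
  out <- out + t(out)
  attr(out, "n_edges") <- n_keep
  out
}

#' Node degree of a binary graph
#'
#' @param adj binary symmetric adjacency matrix (0/1, zero diagonal).
#' @return integer vector of row sums; their total equals 2E.
#' @export
node_degree <- function(adj) {
  adj <- as.matrix(adj)
  if (!all(adj %in% c(0, 1)))
    fc_stop("fconn_invalid_config", "degree requires a binary adjacency matrix")
  as.integer(rowSums(adj))
}

#' Node strength of a weighted graph
#'
#' @param adj symmetric weighted adjacency matrix (zero diagonal).
#' @return numeric vector: sum of each node's retained edge weights.
#' @export
node_strength <- function(adj) {
  rowSums(as.matrix(adj))
}

#' Betweenness centrality (unnormalized shortest-path pair counts)
#'
#' Fraction counts of all shortest paths between other node pairs that
#' pass through each node, on the unweighted graph; each unordered pair
#' counts once and disconnected pairs contribute nothing.
#'
#' @param adj binary symmetric adjacency matrix.
#' @return numeric vector of betweenness values.
#' @export
node_betweenness <- function(adj) {
  adj <- as.matrix(adj)
  if (!all(adj %in% c(0, 1)))
    fc_stop("fconn_invalid_config", "betweenness requires a binary adjacency matrix")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::betweenness(g, directed = FALSE, normalized = FALSE)
}

#' Eigenvector centrality by power iteration
#'
#' Nonnegative dominant eigenvector of the (possibly disconnected)
#' adjacency matrix, L2-normalized. Power iteration from a uniform
#' start, relative tolerance 1e-10, at most 1000 iterations. Iteration
#' runs on A + I (same eigenvectors, shifted spectrum), which guarantees
#' convergence on bipartite graphs -- sparse density thresholds are
#' often forests, where the +/- lambda eigenvalue pair of A itself would
#' oscillate forever.
#'
#' @param adj binary (or nonnegative weighted) symmetric adjacency
#'   matrix with at least one edge.
#' @param tol relative convergence tolerance (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return numeric vector, L2 norm 1, all entries >= 0.
#' @export
eigenvector_centrality <- function(adj, tol = 1e-10, max_iter = 1000) {
  adj <- as.matrix(adj)
  if (sum(abs(adj)) == 0)
    fc_stop("fconn_empty_graph", "eigenvector centrality undefined for an empty graph")
  n <- nrow(adj)
  v <- rep(1 / sqrt(n), n)
  lambda <- 0
  for (i in seq_len(max_iter)) {
    w <- adj %*% v + v
    nw <- sqrt(sum(w^2))
    if (nw == 0)
      fc_stop("fconn_convergence_error", "power iteration collapsed to zero")
    w <- as.vector(w) / nw
    if (sqrt(sum((w - v)^2)) < tol * max(1, nw)) {
      v <- w
      lambda <- nw
      break
    }
    v <- w
    lambda <- nw
    if (i == max_iter)
      fc_stop("fconn_convergence_error",
              sprintf("power iteration did not converge in %d iterations", max_iter))
  }
  v <- abs(v) * sign(sum(v) + (sum(v) == 0))
  v <- abs(v)
  v / sqrt(sum(v^2))
}

#' Nodal metric curves over the density grid
#'
#' For each density in the grid: degree, betweenness and eigenvector
#' centrality on the binarized proportional threshold of the matrix;
#' strength on the weighted threshold. Curves are assembled per node.
#'
#' @param cm N x N connectivity matrix (one subject).
#' @param grid density grid from [density_grid()].
#' @param metrics subset of `c("degree", "strength", "betweenness",
#'   "eigenvector")` (default all four).
#' @return list of class `metric_curves`: one N x length(grid) matrix
#'   per metric, plus `grid`.
#' @export
metric_curves <- function(cm, grid = density_grid(),
                          metrics = c("degree", "strength", "betweenness",
                                      "eigenvector")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  cm <- as.matrix(cm)
  n <- nrow(cm)
  out <- lapply(metrics, function(m) matrix(NA_real_, n, length(grid)))
  names(out) <- metrics
  for (j in seq_along(grid)) {
    need_binary <- any(c("degree", "betweenness", "eigenvector") %in% metrics)
    if (need_binary) bin <- threshold_density(cm, grid[j], "binary")
    if ("degree" %in% metrics) out$degree[, j] <- node_degree(bin)
    if ("betweenness" %in% metrics) out$betweenness[, j] <- node_betweenness(bin)
    if ("eigenvector" %in% metrics) out$eigenvector[, j] <- eigenvector_centrality(bin)
    if ("strength" %in% metrics)
      out$strength[, j] <- node_strength(threshold_density(cm, grid[j], "weighted"))
  }
  structure(c(out, list(grid = grid)), class = "metric_curves")
}

#' Area under a nodal metric curve over the density grid
#'
#' Composite trapezoidal integral of each node's metric values over the
#' density range, the threshold-independent summary used for group
#' comparison.
#'
#' @param curve N x length(grid) matrix (or a vector for one node).
#' @param grid density grid matching the curve columns.
#' @return numeric vector: AUC per node.
#' @export
metric_auc <- function(curve, grid) {
  if (is.null(dim(curve))) curve <- matrix(curve, nrow = 1)
  if (ncol(curve) != length(grid))
    fc_stop("fconn_invalid_config", "curve length must match grid length")
  d <- diff(grid)
  mids <- (curve[, -1, drop = FALSE] + curve[, -ncol(curve), drop = FALSE]) / 2
  drop(mids %*% d)
}

#' Per-subject AUC table for one metric
#'
#' Convenience wrapper: computes metric curves for every subject's
#' connectivity matrix and returns the subjects x nodes AUC table that
#' [bootstrap_maxt_test()] consumes.
#'
#' @param cms list of N x N connectivity matrices, one per subject.
#' @param metric one of `"degree"`, `"strength"`, `"betweenness"`,
#'   `"eigenvector"`.
#' @param grid density grid (default [density_grid()]).
#' @return subjects x nodes numeric matrix of AUC values.
#' @export
auc_table <- function(cms, metric = "degree", grid = density_grid()) {
  rows <- lapply(cms, function(cm) {
    mc <- metric_curves(cm, grid, metrics = metric)
    metric_auc(mc[[metric]], grid)
  })
  do.call(rbind, rows)
}
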