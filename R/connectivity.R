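#' Average a set of series into one ROI time course
#'
#' @param ts nodes/voxels x timepoints matrix.
#' @param index nonempty integer vector of row indices.
#' @return numeric vector (length = timepoints): unweighted mean of the
#'   selected rows at each timepoint.
#' @export
roi_timeseries <- function(ts, index) {
  ts <- as.matrix(ts)
  index <- as.integer(index)
  if (length(index) == 0L)
    fc_stop("fconn_empty_roi", "ROI index set is empty")
  if (any(index < 1L) || any(index > nrow(ts)))
    fc_stop("fconn_invalid_config", "ROI indices out of range")
  colMeans(ts[index, , drop = FALSE])
}

#' Fisher r-to-z transform with clipping
#'
#' z = atanh(r), with |r| clipped at 1 - 1e-7 so perfect correlations
#' map to a large finite value while ordering is preserved. Strictly
#' increasing and odd.
#'
#' @param r correlation value(s) in [-1, 1].
#' @return z value(s).
#' @examples
#' fisher_z(0.5)  # 0.549306...
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    fc_stop("fconn_domain_error", "correlations must lie in [-1, 1]")
  atanh(pmin(abs(r), 1 - 1e-7) * sign(r))
}

#' Seed-based connectivity map
#'
#' Pearson correlation of one seed series with every target row,
#' Fisher z-transformed. Targets with (numerically) zero variance get
#' z = 0 and are recorded in the `constant_targets` attribute.
#'
#' @param seed_series numeric vector (timepoints).
#' @param targets targets x timepoints matrix.
#' @return list of class `seed_map`: `z` (per-target Fisher z), `r`
#'   (raw correlations), `constant_targets` (indices flagged).
#' @export
seed_connectivity_map <- function(seed_series, targets) {
  targets <- as.matrix(targets)
  tt <- length(seed_series)
  if (tt < 4L)
    fc_stop("fconn_insufficient_data", "need at least 4 timepoints")
  if (ncol(targets) != tt)
    fc_stop("fconn_invalid_config", "seed and targets disagree on timepoints")
  if (sd(seed_series) < 1e-12)
    fc_stop("fconn_degenerate_input", "seed series is constant")
  sc <- seed_series - mean(seed_series)
  xc <- targets - rowMeans(targets)
  num <- as.vector(xc %*% sc)
  den <- sqrt(rowSums(xc^2) * sum(sc^2))
  constant <- unname(which(sqrt(rowSums(xc^2) / tt) < 1e-12))
  r <- unname(ifelse(den > 0, num / den, 0))
  r[constant] <- 0
  r <- pmin(pmax(r, -1), 1)
  structure(list(z = fisher_z(r), r = r, constant_targets = constant),
            class = "seed_map")
}

#' Full pairwise adjacency (connectivity) matrix
#'
#' Pearson correlation between every pair of node series; diagonal set
#' to zero and exact symmetry enforced. Constant nodes are flagged and
#' their correlations set to 0.
#'
#' @param ts nodes x timepoints matrix (N >= 2, T >= 4).
#' @param scale `"r"` for raw correlations (default) or `"z"` for
#'   Fisher-z entries.
#' @return N x N matrix of class `conn_matrix`, with attributes `scale`
#'   and `constant_nodes`.
#' @export
build_adjacency <- function(ts, scale = c("r", "z")) {
  scale <- match.arg(scale)
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L)
    fc_stop("fconn_invalid_config", "need at least 2 nodes")
  if (ncol(ts) < 4L)
    fc_stop("fconn_insufficient_data", "need at least 4 timepoints")
  sds <- apply(ts, 1, sd)
  constant <- which(sds < 1e-12)
  a <- suppressWarnings(cor(t(ts)))
  if (length(constant) > 0L) {
    a[constant, ] <- 0
    a[, constant] <- 0
  }
  a[!is.finite(a)] <- 0
  a <- (a + t(a)) / 2
  a <- pmin(pmax(a, -1), 1)
  if (scale == "z") a <- fisher_z(a)
  diag(a) <- 0
  rownames(a) <- colnames(a) <- rownames(ts) %||% paste0("n", seq_len(nrow(ts)))
  structure(a, scale = scale, constant_nodes = constant,
            class = c("conn_matrix", "matrix", "array"))
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix: %d nodes (%s scale)\n", nrow(x),
              attr(x, "scale")))
  off <- x[upper.tri(x)]
  cat(sprintf("  off-diagonal range [%.3f, %.3f], mean %.3f\n",
              min(off), max(off), mean(off)))
  if (length(attr(x, "constant_nodes")) > 0L)
    cat("  constant nodes zeroed:", length(attr(x, "constant_nodes")), "\n")
  invisible(x)
}

#' Within- and between-network mean connectivity
#'
#' Aggregates a Fisher-z connectivity matrix over a node-to-network
#' assignment: within-network connectivity is the mean over unordered
#' intra-network node pairs; between-network connectivity for networks
#' (P, Q) is the mean over all P x Q pairs. Networks with a single node
#' have undefined (NA) within-network connectivity.
#'
#' @param cm N x N connectivity matrix on the z scale.
#' @param assignment either a character/factor vector of length N or a
#'   two-column data frame (node, network).
#' @return list of class `network_connectivity`: `within` (named per
#'   network), `between` (symmetric network x network matrix whose
#'   diagonal repeats `within`), `sizes`.
#' @export
lsn_connectivity <- function(cm, assignment) {
  cm <- as.matrix(cm)
  n <- nrow(cm)
  if (is.data.frame(assignment)) {
    assignment <- assignment[order(assignment[[1]]), ]
    labels <- as.character(assignment[[2]])
  } else {
    labels <- as.character(assignment)
  }
  if (length(labels) != n)
    fc_stop("fconn_invalid_config", "assignment length must equal node count")
  nets <- unique(labels)
  k <- length(nets)
  within <- setNames(rep(NA_real_, k), nets)
  between <- matrix(NA_real_, k, k, dimnames = list(nets, nets))
  idx <- split(seq_len(n), factor(labels, levels = nets))
  for (i in seq_len(k)) {
    ii <- idx[[i]]
    if (length(ii) >= 2L) {
      block <- cm[ii, ii]
      within[i] <- mean(block[upper.tri(block)])
    }
    between[i, i] <- within[i]
    if (i < k) for (j in (i + 1L):k) {
      jj <- idx[[j]]
      between[i, j] <- between[j, i] <- mean(cm[ii, jj])
    }
  }
  structure(list(within = within, between = between,
                 sizes = lengths(idx)),
            class = "network_connectivity")
}

#' @export
print.network_connectivity <- function(x, ...) {
  cat("Large-scale network connectivity (", length(x$within), " networks)\n",
      sep = "")
  df <- data.frame(network = names(x$within), nodes = as.integer(x$sizes),
                   within_z = round(x$within, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Overlap of a cluster with atlas labels
#'
#' Percentage of the cluster's voxels falling in each label of a label
#' map, relative to cluster size; an "unlabeled" remainder (label 0 or
#' NA) completes the sum to 100.
#'
#' @param cluster_voxels integer vector of linear voxel indices.
#' @param label_map integer vector or array of labels over the same
#'   coordinate frame (0/NA = unlabeled).
#' @param label_names optional named translation of label codes.
#' @return named numeric vector of percentages summing to 100.
#' @export
cluster_overlap <- function(cluster_voxels, label_map, label_names = NULL) {
  if (length(cluster_voxels) == 0L)
    fc_stop("fconn_empty_cluster", "cluster is empty")
  map <- as.vector(label_map)
  if (any(cluster_voxels < 1L) || any(cluster_voxels > length(map)))
    fc_stop("fconn_invalid_config", "cluster indices outside the label map")
  labs <- map[cluster_voxels]
  labs[is.na(labs) | labs == 0] <- NA
  n <- length(cluster_voxels)
  tab <- table(labs, useNA = "no")
  pct <- 100 * as.numeric(tab) / n
  names(pct) <- names(tab)
  if (!is.null(label_names))
    names(pct) <- ifelse(names(pct) %in% names(label_names),
                         unlist(label_names[names(pct)]), names(pct))
  unlabeled <- 100 - sum(pct)
  c(pct, unlabeled = unlabeled)
}
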