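#' Framewise displacement (relative RMS of the rigid transform)
#'
#' Summarizes head motion between consecutive frames as the root mean
#' square displacement of brain tissue, computed in closed form over a
#' solid sphere of radius `head_radius` centered at the origin: for the
#' relative transform with linear part difference `A` and translation
#' `b`, FD = sqrt(radius^2 / 5 * tr(A'A) + b'b). Pure translations give
#' FD equal to the translation magnitude.
#'
#' @param motion T x 6 matrix: three translations (mm) then three
#'   rotations (radians, applied as Rx, Ry, Rz about the sphere center).
#' @param head_radius sphere radius in mm (default 80, the conventional
#'   value for this algorithm).
#' @return list of class `fd_series`: `fd` (length T-1, mm) and
#'   `mean_fd` (mm).
#' @export
framewise_displacement <- function(motion, head_radius = 80) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L)
    fc_stop("fconn_insufficient_data", "need at least two frames to compute FD")
  if (ncol(motion) != 6L)
    fc_stop("fconn_invalid_config", "motion must have 6 columns (3 translations, 3 rotations)")
  if (!all(is.finite(motion)))
    fc_stop("fconn_invalid_config", "motion parameters must be finite")
  tt <- nrow(motion)
  mats <- lapply(seq_len(tt), function(i) rigid_transform(motion[i, ]))
  fd <- vapply(seq_len(tt - 1L), function(i) {
    m <- mats[[i + 1L]] %*% solve(mats[[i]]) - diag(4)
    a <- m[1:3, 1:3]
    b <- m[1:3, 4]
    sqrt(head_radius^2 / 5 * sum(a * a) + sum(b * b))
  }, numeric(1))
  structure(list(fd = fd, mean_fd = mean(fd)), class = "fd_series")
}

# 4x4 homogeneous rigid transform from (tx, ty, tz, rx, ry, rz)
#' @noRd
rigid_transform <- function(p) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  out <- diag(4)
  out[1:3, 1:3] <- rz %*% ry %*% rx
  out[1:3, 4] <- p[1:3]
  out
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("Framewise displacement: %d transitions, mean FD = %.4f mm, max = %.4f mm\n",
              length(x$fd), x$mean_fd, max(x$fd)))
  invisible(x)
}

#' Flag outlier timepoints from global intensity and motion
#'
#' A timepoint is flagged when the z-score of the global signal (mean
#' over nodes/voxels at that timepoint, standardized across time)
#' exceeds `z_thresh` in magnitude, or when the framewise displacement
#' of the transition into it exceeds `fd_thresh`.
#'
#' @param ts nodes/voxels x timepoints matrix.
#' @param fd an `fd_series` from [framewise_displacement()] (or NULL to
#'   skip the motion criterion).
#' @param z_thresh global-signal z-score threshold (default 3).
#' @param fd_thresh framewise-displacement threshold in mm (default 0.5).
#' @return list of class `outlier_mask`: `flagged` (logical per
#'   timepoint) and `reasons` (character: "", "intensity", "motion" or
#'   "intensity+motion").
#' @export
detect_outliers <- function(ts, fd = NULL, z_thresh = 3, fd_thresh = 0.5) {
  if (z_thresh <= 0 || fd_thresh <= 0)
    fc_stop("fconn_invalid_config", "outlier thresholds must be > 0")
  ts <- as.matrix(ts)
  tt <- ncol(ts)
  gs <- colMeans(ts)
  s <- sd(gs)
  z <- if (s > 0) (gs - mean(gs)) / s else rep(0, tt)
  intensity <- abs(z) > z_thresh
  motion <- rep(FALSE, tt)
  if (!is.null(fd)) {
    stopifnot(length(fd$fd) == tt - 1L)
    motion[-1L] <- fd$fd > fd_thresh
  }
  reasons <- character(tt)
  reasons[intensity] <- "intensity"
  reasons[motion] <- ifelse(intensity[motion], "intensity+motion", "motion")
  structure(list(flagged = intensity | motion, reasons = reasons),
            class = "outlier_mask")
}

#' Scale a run so its grand mean equals a target value
#'
#' Removes between-run differences in global intensity by one
#' multiplicative rescale making the mean over all entries equal
#' `target` (conventionally 100).
#'
#' @param ts nodes/voxels x timepoints matrix with positive grand mean.
#' @param target target grand mean (default 100).
#' @return rescaled matrix.
#' @export
grand_mean_scale <- function(ts, target = 100) {
  g <- mean(ts)
  if (!is.finite(g) || g <= 0)
    fc_stop("fconn_degenerate_input", "grand mean must be positive for scaling")
  ts * (target / g)
}

#' Regress nuisance signals out of every node/voxel series
#'
#' Ordinary least squares per row: the returned matrix holds the
#' residuals of each series on the full design, which are orthogonal to
#' every regressor. The design must include whatever intercept the
#' caller wants; [build_nuisance_design()] constructs the conventional
#' intercept + motion + outlier-indicator design.
#'
#' @param ts nodes/voxels x timepoints matrix.
#' @param design T x R numeric design matrix.
#' @return residual matrix, same shape as `ts`.
#' @export
nuisance_regress <- function(ts, design) {
  ts <- as.matrix(ts)
  design <- as.matrix(design)
  tt <- ncol(ts)
  if (nrow(design) != tt)
    fc_stop("fconn_design_error", "design rows must equal number of timepoints")
  if (ncol(design) >= tt)
    fc_stop("fconn_design_error", "design must have fewer columns than timepoints")
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design) %||% paste0("col", seq_len(ncol(design)))
    dropped <- bad[qr_d$pivot[(qr_d$rank + 1L):ncol(design)]]
    fc_stop("fconn_design_error",
            paste0("design is rank deficient; collinear column(s): ",
                   paste(dropped, collapse = ", ")))
  }
  t(qr.resid(qr_d, t(ts)))
}

#' Conventional nuisance design: intercept, motion, outlier indicators
#'
#' @param n_timepoints number of timepoints T.
#' @param motion optional T x 6 motion-parameter matrix.
#' @param outliers optional `outlier_mask`; each flagged timepoint
#'   contributes one indicator column (scrubbing regressor).
#' @return T x R design matrix with named columns.
#' @export
build_nuisance_design <- function(n_timepoints, motion = NULL, outliers = NULL) {
  design <- matrix(1, n_timepoints, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_timepoints)
    colnames(motion) <- colnames(motion) %||% paste0("motion", 1:6)
    design <- cbind(design, motion)
  }
  if (!is.null(outliers)) {
    flagged <- which(outliers$flagged)
    for (f in flagged) {
      col <- matrix(0, n_timepoints, 1,
                    dimnames = list(NULL, paste0("outlier_t", f)))
      col[f, 1] <- 1
      design <- cbind(design, col)
    }
  }
  design
}

#' CompCor nuisance components (anatomical + temporal variants)
#'
#' Extracts principal component time courses of physiological/structured
#' noise: `aCompCor` components are the top right singular vectors of
#' the row-centered noise-source matrix (e.g. white-matter/CSF voxel
#' series); `tCompCor` components are extracted the same way from the
#' `t_fraction` highest-variance rows of the full data. Components are
#' unit-norm and mutually orthogonal within each set.
#'
#' @param noise_source noise-region rows x timepoints matrix.
#' @param ts full data matrix (rows x timepoints), source for tCompCor.
#' @param n_components total component count, split evenly between the
#'   two variants (default 10: 5 aCompCor + 5 tCompCor).
#' @param t_fraction fraction of highest-variance rows feeding tCompCor
#'   (default 0.02).
#' @return list of class `compcor_components`: `components` (T x C),
#'   `variance_explained`, `source` ("aCompCor"/"tCompCor" per column).
#' @export
compcor_components <- function(noise_source, ts, n_components = 10,
                               t_fraction = 0.02) {
  if (n_components %% 2 != 0)
    fc_stop("fconn_invalid_config", "n_components must be even (split a/t)")
  n_each <- n_components / 2
  noise_source <- as.matrix(noise_source)
  ts <- as.matrix(ts)
  if (nrow(noise_source) < n_each)
    fc_stop("fconn_insufficient_data",
            "noise source has fewer rows than requested aCompCor components")
  a <- pca_components(noise_source, n_each)
  n_top <- max(n_each, ceiling(t_fraction * nrow(ts)))
  vars <- apply(ts, 1, var)
  top_rows <- order(vars, decreasing = TRUE)[seq_len(min(n_top, nrow(ts)))]
  tcc <- pca_components(ts[top_rows, , drop = FALSE], n_each)
  structure(list(
    components = cbind(a$components, tcc$components),
    variance_explained = c(a$variance_explained, tcc$variance_explained),
    source = rep(c("aCompCor", "tCompCor"), each = n_each)
  ), class = "compcor_components")
}

# Top-k right singular vectors of the row-centered matrix (component time
# courses), unit norm, with per-component variance fractions.
#' @noRd
pca_components <- function(x, k) {
  xc <- x - rowMeans(x)
  s <- svd(xc, nu = 0, nv = min(k, ncol(x)))
  d2 <- s$d^2
  tot <- sum(d2)
  if (tot < .Machine$double.eps)
    fc_stop("fconn_degenerate_input", "noise source has zero variance")
  if (sum(d2 > tot * 1e-12) < k)
    fc_stop("fconn_degenerate_input",
            paste0("noise source supports fewer than ", k,
                   " non-degenerate components"))
  list(components = s$v[, seq_len(k), drop = FALSE],
       variance_explained = d2[seq_len(k)] / tot)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero phase) to each row. Rows are demeaned first, so constant input
#' maps to (numerically) zero output.
#'
#' @param ts nodes/voxels x timepoints matrix (or a vector, treated as
#'   one row).
#' @param low_hz high-pass edge in Hz (default 0.01).
#' @param high_hz low-pass edge in Hz (default 0.1).
#' @param tr_seconds sampling interval in seconds.
#' @return filtered matrix (or vector), zero mean per row.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.1, tr_seconds = 2) {
  vec <- is.null(dim(ts))
  x <- if (vec) matrix(ts, nrow = 1) else as.matrix(ts)
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    fc_stop("fconn_invalid_config",
            sprintf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
                    low_hz, high_hz, nyq))
  x <- x - rowMeans(x)
  op <- bandpass_operator(ncol(x), low_hz, high_hz, nyq)
  out <- x %*% op
  if (vec) drop(out) else out
}

# Zero-phase filtering is linear in the input, so the whole
# forward-backward filter is a fixed T x T operator; build it once per
# (T, band, sampling rate) by filtering the identity columns and cache
# it, turning per-row filtering into one matrix multiply.
.bandpass_cache <- new.env(parent = emptyenv())

#' @noRd
bandpass_operator <- function(tt, low_hz, high_hz, nyq) {
  key <- paste(tt, low_hz, high_hz, nyq, sep = "_")
  cached <- .bandpass_cache[[key]]
  if (!is.null(cached)) return(cached)
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  op <- vapply(seq_len(tt), function(j) {
    e <- numeric(tt)
    e[j] <- 1
    signal::filtfilt(bf, e)
  }, numeric(tt))
  # column j of vapply output is the response to impulse at j; the
  # operator acting on row vectors from the right is its transpose
  op <- t(op)
  .bandpass_cache[[key]] <- op
  op
}

#' Drop the initial volumes of a run
#'
#' Removes the first `n` timepoints (scanner-stabilization volumes),
#' e.g. 300 acquired volumes -> 296 retained.
#'
#' @param ts nodes/voxels x timepoints matrix.
#' @param n number of leading timepoints to drop (default 4).
#' @return matrix with the first `n` columns removed.
#' @export
discard_initial_volumes <- function(ts, n = 4) {
  ts <- as.matrix(ts)
  if (ncol(ts) <= n)
    fc_stop("fconn_insufficient_data",
            sprintf("cannot discard %d volumes from a %d-volume run", n, ncol(ts)))
  if (n == 0L) return(ts)
  ts[, -seq_len(n), drop = FALSE]
}

#' Run the full denoising chain on one subject
#'
#' Applies, in order: initial-volume discard; framewise displacement and
#' outlier detection; grand-mean scaling; nuisance regression on
#' intercept + motion + outlier indicators; CompCor component
#' regression; band-pass filtering. The order is fixed and logged in the
#' returned `steps` field. Global-signal regression is deliberately not
#' part of the default chain (it can induce spurious negative
#' correlations at the group level) and is available via
#' `global_signal = TRUE`.
#'
#' @param ts nodes/voxels x timepoints matrix (raw, including initial
#'   volumes unless `n_discard = 0`).
#' @param motion optional motion-parameter matrix (rows matching the
#'   post-discard run length, or the full length, in which case the
#'   leading rows are dropped too).
#' @param noise_source optional noise-region matrix for CompCor (columns
#'   matching the post-discard run); `NULL` skips CompCor.
#' @param n_discard initial volumes to drop (default 4).
#' @param head_radius,z_thresh,fd_thresh see [framewise_displacement()]
#'   and [detect_outliers()].
#' @param n_compcor total CompCor components (default 10).
#' @param t_fraction tCompCor row fraction (default 0.02).
#' @param low_hz,high_hz,tr_seconds band-pass parameters.
#' @param grand_mean target grand mean, or `NULL` to skip scaling
#'   (required for zero-mean synthetic data without a baseline).
#' @param global_signal also regress the global mean series (default
#'   FALSE).
#' @return list of class `denoise_result`: `data` (cleaned matrix),
#'   `fd`, `outliers`, `steps` (character log of applied steps).
#' @export
denoise_subject <- function(ts, motion = NULL, noise_source = NULL,
                            n_discard = 4, head_radius = 80,
                            z_thresh = 3, fd_thresh = 0.5,
                            n_compcor = 10, t_fraction = 0.02,
                            low_hz = 0.01, high_hz = 0.1, tr_seconds = 2,
                            grand_mean = 100, global_signal = FALSE) {
  steps <- character(0)
  ts <- discard_initial_volumes(ts, n_discard)
  steps <- c(steps, sprintf("discard_initial_volumes(n=%d)", n_discard))
  tt <- ncol(ts)
  if (!is.null(motion) && nrow(motion) > tt)
    motion <- motion[(nrow(motion) - tt + 1L):nrow(motion), , drop = FALSE]
  fd <- if (!is.null(motion)) framewise_displacement(motion, head_radius) else NULL
  outliers <- detect_outliers(ts, fd, z_thresh, fd_thresh)
  steps <- c(steps, sprintf("detect_outliers(z=%g, fd=%g): %d flagged",
                            z_thresh, fd_thresh, sum(outliers$flagged)))
  if (!is.null(grand_mean)) {
    ts <- grand_mean_scale(ts, grand_mean)
    steps <- c(steps, sprintf("grand_mean_scale(target=%g)", grand_mean))
  }
  design <- build_nuisance_design(tt, motion, outliers)
  if (ncol(design) > 1L) {
    ts <- nuisance_regress(ts, design)
    steps <- c(steps, sprintf("nuisance_regress(%d regressors)", ncol(design)))
  }
  if (!is.null(noise_source)) {
    if (ncol(noise_source) > tt)
      noise_source <- noise_source[, (ncol(noise_source) - tt + 1L):ncol(noise_source),
                                   drop = FALSE]
    cc <- compcor_components(noise_source, ts, n_compcor, t_fraction)
    ts <- nuisance_regress(ts, cbind(1, cc$components))
    steps <- c(steps, sprintf("compcor_regress(%d components)", n_compcor))
  }
  if (global_signal) {
    ts <- nuisance_regress(ts, cbind(1, colMeans(ts)))
    steps <- c(steps, "global_signal_regress")
  }
  ts <- bandpass_filter(ts, low_hz, high_hz, tr_seconds)
  steps <- c(steps, sprintf("bandpass(%g-%g Hz)", low_hz, high_hz))
  structure(list(data = ts, fd = fd, outliers = outliers, steps = steps),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat("Denoised run:", nrow(x$data), "series x", ncol(x$data), "timepoints\n")
  cat("Steps applied:\n")
  for (s in x$steps) cat("  -", s, "\n")
  invisible(x)
}
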