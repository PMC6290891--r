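#' Group correlation matrix with a planted seed-target effect
#'
#' Constructs the node-by-node correlation matrix a group's signals are
#' drawn from: unit diagonal, `base_r` (group A) or
#' `tanh(atanh(base_r) + delta_z)` (group B) between the seed and each
#' target, and `r^2` between pairs of targets (the correlation implied by
#' the seed driving every target through a common-factor construction,
#' which is positive semidefinite by design). A nearest-PSD projection
#' (eigenvalue clipping, unit-diagonal rescale) is applied as a guard.
#'
#' @param config a [sim_config()].
#' @param group `"A"` or `"B"`.
#' @return correlation matrix (n_nodes x n_nodes), symmetric PSD.
#' @examples
#' S <- build_group_covariance(sim_config(n_nodes = 10), "B")
#' S[1, 2]  # tanh(atanh(0.3) + 0.3)
#' @export
build_group_covariance <- function(config, group = c("A", "B")) {
  group <- match.arg(group)
  validate_sim_config(config)
  r <- group_target_r(config, group)
  if (!is.finite(r) || abs(r) >= 1)
    fc_stop("fconn_invalid_config", "required seed-target correlation must be < 1 in magnitude")
  n <- config$n_nodes
  sigma <- diag(n)
  tg <- config$target_nodes
  sigma[config$seed_node, tg] <- r
  sigma[tg, config$seed_node] <- r
  if (length(tg) > 1L) {
    sigma[tg, tg] <- r^2
    diag(sigma)[tg] <- 1
  }
  nearest_psd(sigma)
}

#' @noRd
group_target_r <- function(config, group) {
  # exact round trip when the effect is zero, so a null configuration
  # yields bitwise-identical group structure
  if (group == "A" || config$delta_z == 0) config$base_r
  else tanh(atanh(config$base_r) + config$delta_z)
}

#' Generate a two-group ROI (node-level) dataset with a planted effect
#'
#' Each subject's signal is built by band-pass filtering white Gaussian
#' noise to the configured band (the same filter the denoising chain
#' uses), imposing the group correlation structure by multiplication with
#' its symmetric square root, then adding optional low-rank structured
#' noise (per-subject component time courses with per-node random
#' loadings), white measurement noise, and the constant baseline level.
#' All randomness derives from `config$rng_seed` through one sub-seed
#' per subject, drawn in documented order (group A ascending, then
#' group B), so output is reproducible regardless of parallelism.
#'
#' @param config a [sim_config()].
#' @return object of class `fconn_dataset`: list with `subjects` (each a
#'   list with `id`, `group`, `data` nodes x timepoints, and any
#'   `noise_components`), `motion` (per subject, from
#'   [generate_motion_traces()]), `truth` (planted ground truth), and
#'   `config`.
#' @export
generate_roi_dataset <- function(config) {
  validate_sim_config(config)
  n_sub <- 2L * config$n_per_group
  groups <- rep(c("A", "B"), each = config$n_per_group)
  ids <- sprintf("%s%02d", groups, c(seq_len(config$n_per_group),
                                     seq_len(config$n_per_group)))
  seeds <- derive_seeds(config$rng_seed, n_sub)
  roots <- list(A = sqrtm_sym(build_group_covariance(config, "A")),
                B = sqrtm_sym(build_group_covariance(config, "B")))
  subjects <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    set.seed(seeds[i])
    x <- simulate_subject_matrix(config, roots[[groups[i]]])
    subjects[[i]] <- c(list(id = ids[i], group = groups[i]), x)
  }
  truth <- list(
    seed_node = config$seed_node,
    target_nodes = config$target_nodes,
    group_correlations = c(A = group_target_r(config, "A"),
                           B = group_target_r(config, "B"))
  )
  motion <- generate_motion_traces(config)
  structure(list(subjects = subjects, motion = motion, truth = truth,
                 config = config),
            class = "fconn_dataset")
}

# One subject's nodes x timepoints matrix; assumes the RNG is already seeded.
#' @noRd
simulate_subject_matrix <- function(config, root) {
  n <- config$n_nodes
  tt <- config$n_timepoints
  white <- matrix(rnorm(n * tt), nrow = n)
  sig <- bandpass_filter(white, low_hz = config$band[1], high_hz = config$band[2],
                         tr_seconds = config$tr_seconds)
  sig <- root %*% sig
  out <- list()
  if (config$n_structured_noise > 0L) {
    comp <- bandpass_filter(
      matrix(rnorm(config$n_structured_noise * tt),
             nrow = config$n_structured_noise),
      low_hz = config$band[1], high_hz = config$band[2],
      tr_seconds = config$tr_seconds)
    comp <- comp / apply(comp, 1, sd)
    load <- matrix(rnorm(n * config$n_structured_noise), nrow = n)
    sig <- sig + load %*% comp
    out$noise_components <- comp
  }
  if (config$noise_sd > 0)
    sig <- sig + config$noise_sd * matrix(rnorm(n * tt), nrow = n)
  out$data <- sig + config$baseline
  out
}

#' Generate a two-group 3D lattice dataset with a contiguous planted effect
#'
#' Builds voxel x timepoint matrices on a 3D lattice. Each subject has a
#' band-limited seed series; voxels inside the effect region are
#' `r * seed + sqrt(1 - r^2) * noise` with the group-dependent `r`
#' (group A: `base_r`; group B: `tanh(atanh(base_r) + delta_z)`); voxels
#' outside are independent band-limited noise. White measurement noise
#' and the baseline offset are added as in [generate_roi_dataset()].
#'
#' @param config a [sim_config()]; `n_nodes`, `seed_node` and
#'   `target_nodes` are ignored for lattice data.
#' @param dims integer length-3 lattice dimensions.
#' @param region effect region: either a 3-column matrix of voxel
#'   coordinates, a list with `corner` and `size` (an axis-aligned box),
#'   or `NULL`/empty for a pure-null lattice.
#' @return `fconn_dataset` whose subjects carry `data`
#'   (voxels x timepoints, with a `dims` attribute) and `seed_series`;
#'   `truth$affected_region` holds the planted linear voxel indices.
#' @export
generate_lattice_dataset <- function(config, dims, region = NULL) {
  validate_sim_config(config)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    fc_stop("fconn_invalid_config", "dims must be three positive integers")
  idx <- region_to_indices(region, dims)
  n_vox <- prod(dims)
  n_sub <- 2L * config$n_per_group
  groups <- rep(c("A", "B"), each = config$n_per_group)
  ids <- sprintf("%s%02d", groups, c(seq_len(config$n_per_group),
                                     seq_len(config$n_per_group)))
  seeds <- derive_seeds(config$rng_seed, n_sub)
  tt <- config$n_timepoints
  subjects <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    set.seed(seeds[i])
    r <- group_target_r(config, groups[i])
    raw <- bandpass_filter(matrix(rnorm((n_vox + 1L) * tt), nrow = n_vox + 1L),
                           low_hz = config$band[1], high_hz = config$band[2],
                           tr_seconds = config$tr_seconds)
    seed_series <- raw[1L, ]
    vox <- raw[-1L, , drop = FALSE]
    if (length(idx) > 0L)
      vox[idx, ] <- r * matrix(seed_series, nrow = length(idx), ncol = tt,
                               byrow = TRUE) +
        sqrt(1 - r^2) * vox[idx, , drop = FALSE]
    if (config$noise_sd > 0)
      vox <- vox + config$noise_sd * matrix(rnorm(n_vox * tt), nrow = n_vox)
    vox <- vox + config$baseline
    attr(vox, "dims") <- dims
    subjects[[i]] <- list(id = ids[i], group = groups[i], data = vox,
                          seed_series = seed_series)
  }
  truth <- list(
    affected_region = idx,
    dims = dims,
    group_correlations = c(A = group_target_r(config, "A"),
                           B = group_target_r(config, "B"))
  )
  structure(list(subjects = subjects, motion = generate_motion_traces(config),
                 truth = truth, config = config),
            class = "fconn_dataset")
}

# Normalize a region spec to sorted linear voxel indices; errors when any
# voxel falls outside the lattice or the set is not contiguous (26-adjacency).
#' @noRd
region_to_indices <- function(region, dims) {
  if (is.null(region)) return(integer(0))
  if (is.list(region) && !is.null(region$corner)) {
    corner <- as.integer(region$corner)
    size <- as.integer(region$size)
    if (any(corner < 1L) || any(corner + size - 1L > dims))
      fc_stop("fconn_invalid_config", "effect region box extends outside the lattice")
    if (any(size == 0L)) return(integer(0))
    coords <- as.matrix(expand.grid(
      x = corner[1]:(corner[1] + size[1] - 1L),
      y = corner[2]:(corner[2] + size[2] - 1L),
      z = corner[3]:(corner[3] + size[3] - 1L)))
  } else {
    coords <- as.matrix(region)
    if (nrow(coords) == 0L) return(integer(0))
    if (ncol(coords) != 3L)
      fc_stop("fconn_invalid_config", "region must have 3 columns (x, y, z)")
    if (any(coords < 1L) || any(t(coords) > dims))
      fc_stop("fconn_invalid_config", "effect region extends outside the lattice")
  }
  idx <- sort(unique(as.integer(
    (coords[, 3] - 1L) * dims[1] * dims[2] + (coords[, 2] - 1L) * dims[1] + coords[, 1]
  )))
  mask <- logical(prod(dims))
  mask[idx] <- TRUE
  labs <- label_lattice_components(array(mask, dim = dims), connectivity = 26)
  if (max(labs) > 1L)
    fc_stop("fconn_invalid_config", "effect region must be contiguous")
  idx
}

#' Generate six-parameter rigid-body motion traces
#'
#' One trace per subject: three translations (mm) and three rotations
#' (radians) per timepoint, modeled as a smooth Gaussian random-walk
#' drift (increment sd `drift_sd` for translations, `drift_sd / 100` for
#' rotations) plus, at each frame transition with probability
#' `motion_spike_rate`, a one-frame spike of 1 mm on a random
#' translation axis and 0.01 rad on a random rotation axis.
#'
#' @param config a [sim_config()].
#' @return list of T x 6 matrices (columns tx, ty, tz, rx, ry, rz), one
#'   per subject in the order group A then group B; each carries a
#'   `spikes` attribute with the spiked frame indices.
#' @export
generate_motion_traces <- function(config) {
  validate_sim_config(config)
  n_sub <- 2L * config$n_per_group
  seeds <- derive_seeds(config$rng_seed + 1L, n_sub)
  tt <- config$n_timepoints
  lapply(seq_len(n_sub), function(i) {
    set.seed(seeds[i])
    inc <- cbind(matrix(rnorm(tt * 3, 0, config$drift_sd), ncol = 3),
                 matrix(rnorm(tt * 3, 0, config$drift_sd / 100), ncol = 3))
    m <- apply(inc, 2, cumsum)
    m[1, ] <- 0
    spikes <- which(runif(tt - 1L) < config$motion_spike_rate) + 1L
    for (s in spikes) {
      ax_t <- sample.int(3L, 1L)
      ax_r <- 3L + sample.int(3L, 1L)
      m[s, ax_t] <- m[s, ax_t] + 1.0
      m[s, ax_r] <- m[s, ax_r] + 0.01
    }
    colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    attr(m, "spikes") <- spikes
    attr(m, "drift_bound") <- 6 * config$drift_sd
    m
  })
}

#' @export
print.fconn_dataset <- function(x, ...) {
  n <- length(x$subjects)
  d <- dim(x$subjects[[1]]$data)
  kind <- if (!is.null(attr(x$subjects[[1]]$data, "dims"))) "lattice" else "ROI"
  cat(sprintf("Two-group synthetic %s dataset: %d subjects (%d per group)\n",
              kind, n, n / 2))
  cat(sprintf("  %d %s x %d timepoints each\n", d[1],
              if (kind == "lattice") "voxels" else "nodes", d[2]))
  if (!is.null(x$truth$seed_node))
    cat(sprintf("  planted: seed %d -> targets (r_A = %.3f, r_B = %.3f)\n",
                x$truth$seed_node, x$truth$group_correlations["A"],
                x$truth$group_correlations["B"]))
  if (!is.null(x$truth$affected_region))
    cat(sprintf("  planted lattice region: %d voxel(s)\n",
                length(x$truth$affected_region)))
  invisible(x)
}

#' Simulate per-subject behavioral scores from group summary statistics
#'
#' Draws independent Gaussian scores per measure and group and reports
#' them next to the sample summary in a demographics-table layout, with
#' the pooled-variance two-sample t-test of [t_from_summary()].
#'
#' @param specs data frame with columns `measure`, `mean_A`, `sd_A`,
#'   `mean_B`, `sd_B` (one row per behavioral measure).
#' @param n_per_group subjects per group (>= 2).
#' @param rng_seed integer seed.
#' @return list with `raw` (long data frame: measure, group, subject,
#'   value) and `summary` (per measure: sample means/SDs per group, t,
#'   df, p).
#' @export
generate_behavioral_table <- function(specs, n_per_group, rng_seed = 1L) {
  if (n_per_group < 2L)
    fc_stop("fconn_invalid_config", "n_per_group must be >= 2")
  if (any(specs$sd_A <= 0) || any(specs$sd_B <= 0))
    fc_stop("fconn_invalid_config", "all group standard deviations must be > 0")
  set.seed(rng_seed)
  raw <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    data.frame(
      measure = specs$measure[i],
      group = rep(c("A", "B"), each = n_per_group),
      subject = rep(seq_len(n_per_group), 2),
      value = c(rnorm(n_per_group, specs$mean_A[i], specs$sd_A[i]),
                rnorm(n_per_group, specs$mean_B[i], specs$sd_B[i]))
    )
  }))
  summary <- do.call(rbind, lapply(split(raw, raw$measure)[unique(raw$measure)],
                                   function(d) {
    a <- d$value[d$group == "A"]
    b <- d$value[d$group == "B"]
    tt <- t_from_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
    data.frame(measure = d$measure[1],
               mean_A = mean(a), sd_A = sd(a),
               mean_B = mean(b), sd_B = sd(b),
               t = tt$t, df = tt$df, p = tt$p)
  }))
  rownames(summary) <- NULL
  list(raw = raw, summary = summary)
}
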