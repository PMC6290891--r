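#' Simulation configuration for two-group connectivity datasets
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' Defaults emulate the study design the package targets: two groups of
#' 14 subjects, 296 retained timepoints at a 2 s sampling interval,
#' band-limited (0.01-0.1 Hz) signals, and a planted seed-target
#' connectivity increase of `delta_z` (Fisher-z scale) in group B.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param n_nodes number of nodes (regions).
#' @param n_timepoints timepoints per subject after initial-volume discard.
#' @param tr_seconds sampling interval (repetition time), seconds.
#' @param base_r baseline seed-target Pearson correlation, in [0, 1).
#' @param delta_z group effect added to atanh(base_r) for group B; the
#'   implied group-B correlation tanh(atanh(base_r) + delta_z) must be < 1.
#' @param seed_node index (1-based) of the seed node.
#' @param target_nodes integer vector of affected node indices
#'   (must exclude `seed_node`).
#' @param noise_sd standard deviation of additive white measurement noise.
#' @param n_structured_noise number of shared structured (low-rank) noise
#'   components added with per-subject random loadings; 0 disables them.
#' @param motion_spike_rate per-transition probability of a motion spike.
#' @param drift_sd standard deviation (mm / radians) of the per-step smooth
#'   motion drift increments.
#' @param baseline constant signal level added to every series so that
#'   grand-mean scaling operates on positive data.
#' @param band passband in Hz used to band-limit generated signals.
#' @param rng_seed integer master seed; all generator output is a pure
#'   function of the configuration including this seed.
#'
#' @return object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_per_group = 4, n_nodes = 10, n_timepoints = 60)
#' cfg$base_r
#' @export
sim_config <- function(n_per_group = 14,
                       n_nodes = 100,
                       n_timepoints = 296,
                       tr_seconds = 2,
                       base_r = 0.3,
                       delta_z = 0.3,
                       seed_node = 1,
                       target_nodes = 2:11,
                       noise_sd = 0.5,
                       n_structured_noise = 0,
                       motion_spike_rate = 0.02,
                       drift_sd = 0.02,
                       baseline = 100,
                       band = c(0.01, 0.1),
                       rng_seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_nodes = as.integer(n_nodes),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    base_r = base_r,
    delta_z = delta_z,
    seed_node = as.integer(seed_node),
    target_nodes = as.integer(target_nodes),
    noise_sd = noise_sd,
    n_structured_noise = as.integer(n_structured_noise),
    motion_spike_rate = motion_spike_rate,
    drift_sd = drift_sd,
    baseline = baseline,
    band = band,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (cfg$n_per_group < 2L)
    fc_stop("fconn_invalid_config", "n_per_group must be >= 2")
  if (cfg$n_nodes < 2L)
    fc_stop("fconn_invalid_config", "n_nodes must be >= 2")
  if (cfg$base_r < 0 || cfg$base_r >= 1)
    fc_stop("fconn_invalid_config", "base_r must be in [0, 1)")
  rb <- tanh(atanh(cfg$base_r) + cfg$delta_z)
  # the implied correlation must stay representably below 1 (the Fisher
  # clipping bound), not merely below 1 in exact arithmetic
  if (!is.finite(rb) || rb >= 1 - 1e-7)
    fc_stop("fconn_invalid_config",
            "implied group-B correlation tanh(atanh(base_r) + delta_z) must be < 1")
  if (cfg$seed_node %in% cfg$target_nodes)
    fc_stop("fconn_invalid_config", "seed_node must not be a target node")
  idx <- c(cfg$seed_node, cfg$target_nodes)
  if (any(idx < 1L) || any(idx > cfg$n_nodes))
    fc_stop("fconn_invalid_config", "seed/target indices must lie in 1..n_nodes")
  if (anyDuplicated(cfg$target_nodes))
    fc_stop("fconn_invalid_config", "target_nodes must be distinct")
  if (cfg$noise_sd < 0)
    fc_stop("fconn_invalid_config", "noise_sd must be >= 0")
  if (cfg$motion_spike_rate < 0 || cfg$motion_spike_rate > 1)
    fc_stop("fconn_invalid_config", "motion_spike_rate must be in [0, 1]")
  nyq <- 1 / (2 * cfg$tr_seconds)
  if (!(cfg$band[1] > 0 && cfg$band[1] < cfg$band[2] && cfg$band[2] < nyq))
    fc_stop("fconn_invalid_config", "band must satisfy 0 < low < high < Nyquist")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Two-group simulation configuration\n")
  cat(sprintf("  subjects: %d per group, nodes: %d, timepoints: %d (TR = %g s)\n",
              x$n_per_group, x$n_nodes, x$n_timepoints, x$tr_seconds))
  cat(sprintf("  planted effect: seed %d -> %d targets, base r = %g, delta z = %g\n",
              x$seed_node, length(x$target_nodes), x$base_r, x$delta_z))
  cat(sprintf("  noise: white sd %g, %d structured component(s)\n",
              x$noise_sd, x$n_structured_noise))
  cat(sprintf("  rng_seed: %d\n", x$rng_seed))
  invisible(x)
}

#' Read or write a simulation configuration as YAML/JSON
#'
#' @param path file path; format chosen by extension (.yaml/.yml or .json).
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    fc_stop("fconn_config_error", paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param cfg a `sim_config` object.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
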