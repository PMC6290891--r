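#' Run the group connectivity analysis pipeline end to end
#'
#' Orchestrates: data simulation (or loading), per-subject denoising,
#' adjacency construction, and the enabled analysis branches
#' (large-scale-network aggregation, seed-map cluster inference on
#' lattice data, density-swept graph metrics with bootstrap max-t
#' inference). Every artifact is written under `output_dir` in the
#' package's TSV/JSON formats; the run report summarizes parameters,
#' file hashes and results. A full run is a pure function of
#' (inputs, config, rng_seed); result files are timestamp-free so two
#' identical runs are hash-identical (timings live only in the report).
#'
#' @param config either a path to a YAML/JSON pipeline configuration or
#'   an equivalent named list. Recognized top-level fields:
#'   \describe{
#'     \item{output_dir}{artifact directory (required).}
#'     \item{simulate}{a [sim_config()] argument list; mutually
#'       exclusive with `inputs`.}
#'     \item{inputs}{list with `timeseries` (vector of TSV paths),
#'       `groups` (label per subject), optional `motion` paths.}
#'     \item{stages}{logical toggles: `denoise`, `connectivity`, `lsn`,
#'       `cluster`, `graph` (all default TRUE except `lsn`/`cluster`,
#'       which need their inputs).}
#'     \item{denoise}{argument list for [denoise_subject()].}
#'     \item{lsn}{list with `assignment` (path to a 2-column TSV or a
#'       label vector).}
#'     \item{cluster}{argument list for
#'       [cluster_correct_permutation()] (lattice datasets only).}
#'     \item{graph}{list: `metrics`, `delta_min`, `delta_max`, `step`,
#'       `n_boot`, `alpha`, `mode`.}
#'     \item{rng_seed}{master seed (default 1).}
#'   }
#' @return object of class `run_report` (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      fc_stop("fconn_config_error", paste0("config file not found: ", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg$output_dir))
    fc_stop("fconn_config_error", "config must name an output_dir")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$rng_seed %||% 1L)
  stages <- modifyList(list(denoise = TRUE, connectivity = TRUE, lsn = FALSE,
                            cluster = FALSE, graph = TRUE),
                       as.list(cfg$stages %||% list()))
  report <- list(package_version = as.character(utils::packageVersion("fconn")),
                 rng_seed = seed, stages = stages, timing_s = list(),
                 parameters = list(), results = list(), files = list())
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      marker <- file.path(cfg$output_dir, "FAILED")
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)), marker)
      fc_stop("fconn_stage_error",
              sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)))
    })
    report$timing_s[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  # --- data: simulate or load ------------------------------------------
  dataset <- NULL
  if (!is.null(cfg$simulate)) {
    dataset <- run_stage("simulate", function() {
      sim_args <- cfg$simulate
      sim_args$rng_seed <- sim_args$rng_seed %||% seed
      sc <- do.call(sim_config, sim_args)
      report$parameters$simulate <<- unclass(sc)
      if (!is.null(cfg$lattice_dims))
        generate_lattice_dataset(sc, cfg$lattice_dims, cfg$lattice_region)
      else generate_roi_dataset(sc)
    })
    jsonlite::write_json(dataset$truth,
                         file.path(cfg$output_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (!is.null(cfg$inputs)) {
    dataset <- run_stage("load", function() {
      paths <- cfg$inputs$timeseries
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0)
        fc_stop("fconn_config_error",
                paste0("input path(s) not found: ",
                       paste(missing, collapse = ", ")))
      groups <- cfg$inputs$groups
      if (length(groups) != length(paths))
        fc_stop("fconn_config_error", "one group label per time-series path required")
      subjects <- lapply(seq_along(paths), function(i)
        list(id = sprintf("%s%02d", groups[i], i), group = groups[i],
             data = read_timeseries(paths[i])))
      motion <- NULL
      if (!is.null(cfg$inputs$motion))
        motion <- lapply(cfg$inputs$motion, function(p)
          as.matrix(utils::read.delim(p, sep = "\t")))
      structure(list(subjects = subjects, motion = motion, truth = NULL,
                     config = NULL), class = "fconn_dataset")
    })
  } else if (any(unlist(stages))) {
    fc_stop("fconn_config_error", "config needs either `simulate` or `inputs`")
  }

  design <- if (!is.null(dataset))
    group_design(vapply(dataset$subjects, `[[`, "", "group"),
                 ids = vapply(dataset$subjects, `[[`, "", "id"))

  # --- denoise ---------------------------------------------------------
  if (isTRUE(stages$denoise) && !is.null(dataset)) {
    den_args <- as.list(cfg$denoise %||% list())
    if (is.null(den_args$n_discard)) den_args$n_discard <- 0L
    report$parameters$denoise <- den_args
    dataset <- run_stage("denoise", function() {
      for (i in seq_along(dataset$subjects)) {
        res <- do.call(denoise_subject,
                       c(list(ts = dataset$subjects[[i]]$data,
                              motion = dataset$motion[[i]]), den_args))
        dataset$subjects[[i]]$data <- res$data
        dataset$subjects[[i]]$mean_fd <- res$fd$mean_fd
      }
      dataset
    })
  }

  is_lattice <- !is.null(dataset) &&
    !is.null(attr(dataset$subjects[[1]]$data, "dims"))

  # --- connectivity ----------------------------------------------------
  adjacency <- NULL
  if (isTRUE(stages$connectivity) && !is_lattice) {
    adjacency <- run_stage("connectivity", function()
      lapply(dataset$subjects, function(s) build_adjacency(s$data)))
    mean_a <- Reduce(`+`, adjacency[design$idx_a]) / length(design$idx_a)
    mean_b <- Reduce(`+`, adjacency[design$idx_b]) / length(design$idx_b)
    write_matrix(mean_a, file.path(cfg$output_dir, "adjacency_mean_A.tsv"))
    write_matrix(mean_b, file.path(cfg$output_dir, "adjacency_mean_B.tsv"))
    report$results$connectivity <- list(
      n_subjects = length(adjacency), n_nodes = nrow(mean_a),
      mean_offdiag_A = mean(mean_a[upper.tri(mean_a)]),
      mean_offdiag_B = mean(mean_b[upper.tri(mean_b)]))
  }

  # --- large-scale networks -------------------------------------------
  if (isTRUE(stages$lsn)) {
    if (is.null(adjacency))
      fc_stop("fconn_config_error", "lsn stage requires the connectivity stage")
    lsn_res <- run_stage("lsn", function() {
      assign <- cfg$lsn$assignment
      if (is.character(assign) && length(assign) == 1L && file.exists(assign)) {
        tab <- utils::read.delim(assign, sep = "\t")
        assign <- as.character(tab[[2]])[order(tab[[1]])]
      }
      per_subject <- lapply(adjacency, function(a)
        lsn_connectivity(fisher_z(unclass(a)), assign))
      within <- t(vapply(per_subject, `[[`, per_subject[[1]]$within, "within"))
      within_tests <- apply(within, 2, function(v)
        roi_mean_compare(v, design), simplify = FALSE)
      list(within = within, tests = within_tests)
    })
    report$results$lsn <- lapply(lsn_res$tests, function(x)
      list(t = x$t, df = x$df, p = x$p))
    utils::write.table(
      data.frame(subject = design$ids, group = design$groups, lsn_res$within,
                 check.names = FALSE),
      file.path(cfg$output_dir, "lsn_within.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- seed-map cluster inference (lattice data) -----------------------
  if (isTRUE(stages$cluster)) {
    if (!is_lattice)
      fc_stop("fconn_config_error", "cluster stage requires lattice data")
    cl_args <- as.list(cfg$cluster %||% list())
    report$parameters$cluster <- cl_args
    cluster_res <- run_stage("cluster", function() {
      maps <- t(vapply(dataset$subjects, function(s)
        seed_connectivity_map(s$seed_series, s$data)$z,
        numeric(nrow(dataset$subjects[[1]]$data))))
      attr(maps, "dims") <- attr(dataset$subjects[[1]]$data, "dims")
      cl_args$rng_seed <- cl_args$rng_seed %||% seed
      do.call(cluster_correct_permutation,
              c(list(maps = maps, design = design), cl_args))
    })
    tab <- cluster_table(cluster_res$clusters)
    utils::write.table(tab, file.path(cfg$output_dir, "cluster_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$results$cluster <- list(
      n_clusters = length(cluster_res$clusters),
      n_significant = sum(tab$significant),
      method = cluster_res$method)
  }

  # --- graph metrics + bootstrap max-t --------------------------------
  if (isTRUE(stages$graph)) {
    if (is.null(adjacency))
      fc_stop("fconn_config_error", "graph stage requires the connectivity stage")
    g <- modifyList(list(metrics = c("degree", "strength"),
                         delta_min = 0.05, delta_max = 0.35, step = 0.01,
                         n_boot = 10000, alpha = 0.05, mode = "bootstrap"),
                    as.list(cfg$graph %||% list()))
    report$parameters$graph <- g
    graph_res <- run_stage("graph", function() {
      grid <- density_grid(g$delta_min, g$delta_max, g$step)
      lapply(setNames(g$metrics, g$metrics), function(metric) {
        auc <- auc_table(adjacency, metric, grid)
        bootstrap_maxt_test(auc, design, n_boot = g$n_boot, alpha = g$alpha,
                            rng_seed = seed, mode = g$mode)
      })
    })
    for (metric in names(graph_res)) {
      res <- graph_res[[metric]]
      jsonlite::write_json(
        list(metric = metric, t_obs = res$t_obs, p_obs = res$p_obs,
             p_corr = res$p_corr, significant = res$significant,
             df = res$df, config = res$config),
        file.path(cfg$output_dir, paste0("maxt_", metric, ".json")),
        auto_unbox = TRUE, digits = NA)
      report$results$graph[[metric]] <- list(
        significant_nodes = which(res$significant),
        min_p_corr = min(res$p_corr),
        top_t_obs = max(abs(res$t_obs)))
    }
  }

  files <- list.files(cfg$output_dir, full.names = TRUE)
  files <- files[!basename(files) %in% c("report.json")]
  report$files <- as.list(tools::md5sum(files))
  report_path <- file.path(cfg$output_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  structure(c(report, list(output_dir = cfg$output_dir)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (fconn", x$package_version, ")\n")
  cat("  output:", x$output_dir, "\n")
  cat("  stages run:", paste(names(x$timing_s), collapse = ", "), "\n")
  if (!is.null(x$results$graph)) {
    for (m in names(x$results$graph)) {
      sig <- x$results$graph[[m]]$significant_nodes
      cat(sprintf("  graph/%s: %d significant node(s)%s\n", m, length(sig),
                  if (length(sig) > 0)
                    paste0(" [", paste(sig, collapse = ", "), "]") else ""))
    }
  }
  if (!is.null(x$results$cluster))
    cat(sprintf("  cluster: %d cluster(s), %d significant\n",
                x$results$cluster$n_clusters,
                x$results$cluster$n_significant))
  invisible(x)
}
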