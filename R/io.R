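# Shared TSV reader: first column = row labels, remaining columns numeric.
# Reports the first offending line on malformed input. NA/NaN preserved.
#' @noRd
read_tsv_numeric <- function(path, what) {
  if (!file.exists(path))
    fc_stop("fconn_config_error", paste0(what, " file not found: ", path))
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    fc_stop("fconn_format_error",
            paste0(what, ": expected a label column plus numeric columns (line 1)"))
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(vals, function(col) as.numeric(as.character(col)),
           numeric(nrow(vals))))
  if (nrow(vals) == 1L) num <- matrix(num, nrow = 1)
  bad <- which(is.na(num) & !is.na(as.matrix(vals)) &
                 toupper(as.matrix(vals)) != "NAN", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    fc_stop("fconn_format_error",
            sprintf("%s: non-numeric value at line %d, column %d of %s",
                    what, bad[1, 1] + 1L, bad[1, 2] + 1L, path))
  rownames(num) <- as.character(df[[1]])
  num
}

#' Write/read a time-series matrix as TSV
#'
#' Rows are nodes/voxels, columns timepoints; the header row carries
#' timepoint indices and the first column the node labels. Missing
#' values are preserved. A lattice `dims` attribute round-trips through
#' a `#dims:` comment line.
#'
#' @param ts nodes/voxels x timepoints matrix.
#' @param path file path.
#' @return `write_timeseries()` returns `path` invisibly;
#'   `read_timeseries()` the matrix.
#' @export
write_timeseries <- function(ts, path) {
  ts <- as.matrix(ts)
  labels <- rownames(ts) %||% paste0("n", seq_len(nrow(ts)))
  con <- file(path, "w")
  on.exit(close(con))
  dims <- attr(ts, "dims")
  if (!is.null(dims))
    writeLines(paste0("#dims:", paste(dims, collapse = "x")), con)
  writeLines(paste(c("node", paste0("t", seq_len(ncol(ts)))), collapse = "\t"),
             con)
  utils::write.table(cbind(labels, format(ts, digits = 17, trim = TRUE,
                                          scientific = TRUE)),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  first <- readLines(path, n = 1L)
  dims <- NULL
  if (startsWith(first, "#dims:")) {
    dims <- as.integer(strsplit(sub("^#dims:", "", first), "x")[[1]])
    tmp <- tempfile()
    writeLines(readLines(path)[-1L], tmp)
    on.exit(unlink(tmp))
    out <- read_tsv_numeric(tmp, "time series")
  } else {
    out <- read_tsv_numeric(path, "time series")
  }
  if (!is.null(dims)) attr(out, "dims") <- dims
  out
}

#' Write/read a square connectivity matrix as TSV
#'
#' Square TSV with node labels as header and first column. On read the
#' matrix must be square and symmetric (within 1e-8) unless
#' `check_symmetric = FALSE`.
#'
#' @param m square numeric matrix.
#' @param path file path.
#' @param check_symmetric validate symmetry on read (default TRUE).
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   the matrix.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  labels <- rownames(m) %||% paste0("n", seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("node", labels), collapse = "\t"), con)
  utils::write.table(cbind(labels, format(unclass(m), digits = 17, trim = TRUE,
                                          scientific = TRUE)),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, check_symmetric = TRUE) {
  m <- read_tsv_numeric(path, "matrix")
  if (nrow(m) != ncol(m))
    fc_stop("fconn_format_error",
            sprintf("matrix is not square (%d x %d): %s", nrow(m), ncol(m), path))
  colnames(m) <- colnames(m) %||% rownames(m)
  if (check_symmetric) {
    d <- m - t(m)
    if (any(abs(d[!is.na(d)]) > 1e-8))
      fc_stop("fconn_format_error",
              paste0("matrix is not symmetric within 1e-8: ", path))
  }
  m
}

#' Write a dataset's per-subject artifacts to a directory
#'
#' Emits one time-series TSV per subject, one 6-column motion TSV per
#' subject, the ground truth and a config echo as JSON.
#'
#' @param dataset an `fconn_dataset`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fconn_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_along(dataset$subjects)) {
    s <- dataset$subjects[[i]]
    f <- file.path(dir, paste0("timeseries_", s$id, ".tsv"))
    write_timeseries(s$data, f)
    files <- c(files, f)
    mf <- file.path(dir, paste0("motion_", s$id, ".tsv"))
    utils::write.table(dataset$motion[[i]], mf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, mf)
  }
  tf <- file.path(dir, "truth.json")
  jsonlite::write_json(dataset$truth, tf, auto_unbox = TRUE, digits = NA)
  cf <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(dataset$config), cf, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(files, tf, cf))
}

#' Write/read a lattice map or 4D lattice time series as NIfTI
#'
#' Optional NIfTI export for lattice data (statistical maps, label maps
#' or voxel time series); delimited text remains the primary format.
#'
#' @param x a 3D array, or a voxels x timepoints matrix carrying a
#'   `dims` attribute (written as a 4D volume).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_lattice_nifti()` returns `path` invisibly;
#'   `read_lattice_nifti()` returns a 3D array or a voxels x timepoints
#'   matrix with a `dims` attribute.
#' @export
write_lattice_nifti <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    fc_stop("fconn_config_error", "NIfTI support requires the RNifti package")
  if (is.matrix(x) && !is.null(attr(x, "dims"))) {
    dims <- attr(x, "dims")
    x <- array(x, dim = c(dims, ncol(x)))
  }
  RNifti::writeNifti(x, path)
  invisible(path)
}

#' @rdname write_lattice_nifti
#' @export
read_lattice_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    fc_stop("fconn_config_error", "NIfTI support requires the RNifti package")
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4L) {
    dims <- dim(arr)[1:3]
    out <- matrix(arr, nrow = prod(dims), ncol = dim(arr)[4])
    attr(out, "dims") <- as.integer(dims)
    return(out)
  }
  arr
}
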