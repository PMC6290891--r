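#' Two-group design descriptor
#'
#' @param groups character/factor vector of group labels, one per
#'   subject; exactly two distinct labels, each with >= 2 subjects.
#' @param ids optional subject identifiers.
#' @param ref reference (first) group for the A-B direction convention;
#'   defaults to the first label in order of appearance.
#' @return list of class `group_design` with `groups`, `ids`, `levels`
#'   (A first), `idx_a`, `idx_b`.
#' @export
group_design <- function(groups, ids = NULL, ref = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L)
    fc_stop("fconn_invalid_config", "design must contain exactly two groups")
  if (!is.null(ref)) {
    if (!ref %in% lev)
      fc_stop("fconn_invalid_config", "ref group not present in design")
    lev <- c(ref, setdiff(lev, ref))
  }
  idx_a <- which(groups == lev[1])
  idx_b <- which(groups == lev[2])
  if (length(idx_a) < 2L || length(idx_b) < 2L)
    fc_stop("fconn_invalid_config", "each group needs at least 2 subjects")
  structure(list(groups = groups,
                 ids = ids %||% paste0("s", seq_along(groups)),
                 levels = lev, idx_a = idx_a, idx_b = idx_b),
            class = "group_design")
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' t = (m1 - m2) / sqrt(sp^2 (1/n1 + 1/n2)) with
#' sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2), df = n1 + n2 - 2,
#' two-tailed p. This is the test a demographics table's printed
#' means/SDs support.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @return list with `t`, `df`, `p`.
#' @examples
#' t_from_summary(32.00, 9.57, 14, 33.21, 12.15, 14)$t  # -0.29
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2)
    fc_stop("fconn_invalid_config", "both groups need n >= 2")
  if (s1 < 0 || s2 < 0)
    fc_stop("fconn_invalid_config", "standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(m1 - m2) * Inf, df = df, p = 0))
  }
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Vectorized pooled two-sample t over columns of a subjects x elements
# matrix, given 0/1 group-A membership rows in `pa` (one surrogate per
# row). Returns a matrix of t values (surrogates x elements); elements
# with zero pooled variance get t = 0.
#' @noRd
pooled_t_matrix <- function(x, pa, na, nb) {
  x2 <- x * x
  sa <- pa %*% x
  sb <- matrix(colSums(x), nrow(pa), ncol(x), byrow = TRUE) - sa
  qa <- pa %*% x2
  qb <- matrix(colSums(x2), nrow(pa), ncol(x), byrow = TRUE) - qa
  ma <- sa / na
  mb <- sb / nb
  df <- na + nb - 2
  sp2 <- (qa - na * ma^2 + qb - nb * mb^2) / df
  sp2[sp2 < 0] <- 0
  den <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / den
  t[!is.finite(t)] <- 0
  t
}

# As above but for resampled rows: `idx` is a surrogates x n matrix of
# subject row indices (with replacement); first na columns form group A.
# Vectorized through rowsum() over chunks of surrogates to bound memory.
#' @noRd
resampled_t_matrix <- function(x, idx, na, nb) {
  n_sur <- nrow(idx)
  nc <- ncol(x)
  x2 <- x * x
  df <- na + nb - 2
  out <- matrix(0, n_sur, nc)
  chunk <- max(1L, floor(5e6 / ((na + nb) * max(1L, nc))))
  for (b1 in seq(1L, n_sur, by = chunk)) {
    b2 <- min(b1 + chunk - 1L, n_sur)
    k <- b2 - b1 + 1L
    ia <- as.vector(t(idx[b1:b2, seq_len(na), drop = FALSE]))
    ib <- as.vector(t(idx[b1:b2, na + seq_len(nb), drop = FALSE]))
    ga <- rep(seq_len(k), each = na)
    gb <- rep(seq_len(k), each = nb)
    sa <- rowsum(x[ia, , drop = FALSE], ga, reorder = FALSE)
    qa <- rowsum(x2[ia, , drop = FALSE], ga, reorder = FALSE)
    sb <- rowsum(x[ib, , drop = FALSE], gb, reorder = FALSE)
    qb <- rowsum(x2[ib, , drop = FALSE], gb, reorder = FALSE)
    ma <- sa / na
    mb <- sb / nb
    sp2 <- (qa - na * ma^2 + qb - nb * mb^2) / df
    sp2[sp2 < 0] <- 0
    t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    t[!is.finite(t)] <- 0
    out[b1:b2, ] <- t
  }
  out
}

#' Element-wise two-sample t-test across subjects
#'
#' Pooled-variance independent-samples t at every node/voxel of
#' per-subject maps, direction A - B. Zero-pooled-variance elements are
#' flagged and get t = 0.
#'
#' @param maps subjects x elements matrix (one row per subject); an
#'   optional `dims` attribute marks lattice-shaped maps.
#' @param design a [group_design()] aligned with the rows of `maps`.
#' @return list of class `tstat_map`: `t` (per element), `df`,
#'   `direction`, `dims` (or NULL), `zero_variance` (flagged indices).
#' @export
nodewise_ttest <- function(maps, design) {
  maps <- as.matrix(maps)
  stopifnot(inherits(design, "group_design"))
  if (nrow(maps) != length(design$groups))
    fc_stop("fconn_invalid_config", "one map row per design subject required")
  na <- length(design$idx_a)
  nb <- length(design$idx_b)
  pa <- matrix(0, 1, nrow(maps))
  pa[1, design$idx_a] <- 1
  t <- drop(pooled_t_matrix(maps, pa, na, nb))
  xa <- maps[design$idx_a, , drop = FALSE]
  xb <- maps[design$idx_b, , drop = FALSE]
  ssa <- colSums(xa^2) - na * colMeans(xa)^2
  ssb <- colSums(xb^2) - nb * colMeans(xb)^2
  sp_zero <- which(ssa + ssb <= 0)
  structure(list(t = t, df = na + nb - 2,
                 direction = paste(design$levels, collapse = "-"),
                 dims = attr(maps, "dims"),
                 zero_variance = sp_zero),
            class = "tstat_map")
}

#' @export
print.tstat_map <- function(x, ...) {
  cat(sprintf("t-statistic map: %d elements, df = %d, direction %s\n",
              length(x$t), x$df, x$direction))
  cat(sprintf("  range [%.3f, %.3f]\n", min(x$t), max(x$t)))
  invisible(x)
}

#' Mann-Whitney U test (rank-sum) with exact small-sample enumeration
#'
#' U is the smaller of the two pair-count statistics (with 1/2 credit
#' for ties); Z uses the normal approximation with tie-corrected
#' variance and a 0.5 continuity correction. When n1 + n2 <= 12 the
#' two-sided p comes from exact enumeration of all rank assignments
#' (doubled one-tail probability, capped at 1); otherwise from the
#' normal approximation.
#'
#' @param xs,ys numeric samples (both nonempty).
#' @return list with `U`, `Z`, `p`, `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(xs, ys) {
  if (length(xs) == 0L || length(ys) == 0L)
    fc_stop("fconn_invalid_config", "both samples must be nonempty")
  n1 <- length(xs)
  n2 <- length(ys)
  r <- rank(c(xs, ys))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # #{x > y} + ties/2
  u <- min(u1, n1 * n2 - u1)
  mu <- n1 * n2 / 2
  ties <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) {
    d <- u1 - mu
    cc <- if (d != 0) 0.5 * sign(d) else 0
    (d - cc) / sqrt(sigma2)
  } else 0
  if (n <= 12L) {
    u1_null <- exact_u_distribution(r, n1)
    p_lo <- mean(u1_null <= u1)
    p_hi <- mean(u1_null >= u1)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    method <- "normal"
  }
  list(U = u, Z = z, p = p, method = method)
}

# All values of U1 over the choose(n, n1) assignments of the observed
# (mid)ranks to sample 1.
#' @noRd
exact_u_distribution <- function(r, n1) {
  sets <- combn(length(r), n1)
  colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Compare per-subject scalar ROI values between groups
#'
#' Pooled two-sample t on one scalar per subject (e.g. mean
#' connectivity extracted from a binarized mask), direction A - B.
#'
#' @param values numeric vector, one scalar per subject.
#' @param design a [group_design()] aligned with `values`.
#' @return list with `t`, `df`, `p`.
#' @export
roi_mean_compare <- function(values, design) {
  stopifnot(inherits(design, "group_design"))
  if (length(values) != length(design$groups))
    fc_stop("fconn_invalid_config", "one value per design subject required")
  a <- values[design$idx_a]
  b <- values[design$idx_b]
  t_from_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
}
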