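test_that("framewise displacement matches rigid-body closed forms", {
  # zero motion
  fd0 <- framewise_displacement(matrix(0, 5, 6))
  expect_equal(fd0$fd, rep(0, 4))
  expect_equal(fd0$mean_fd, 0)
  # pure translation step: FD equals the translation magnitude
  m <- matrix(0, 4, 6)
  m[3, 1] <- 0.5
  expect_equal(framewise_displacement(m)$fd, c(0, 0.5, 0.5))
  m2 <- matrix(0, 3, 6)
  m2[2, 1:3] <- c(0.3, 0, 0.4)
  expect_equal(framewise_displacement(m2)$fd[1], 0.5)
  expect_error(framewise_displacement(matrix(0, 1, 6)),
               class = "fconn_insufficient_data")
})

test_that("rotation FD matches numerical integration over the sphere", {
  # deterministic product quadrature over the solid sphere; exact for the
  # quadratic integrand (3-point Gauss-Legendre per radial/polar axis)
  quad_rms <- function(a, b, radius) {
    gl_x <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
    gl_w <- c(5, 8, 5) / 9
    tot <- 0
    wsum <- 0
    nphi <- 16
    for (i in 1:3) for (j in 1:3) for (k in seq_len(nphi)) {
      r <- radius * (gl_x[i] + 1) / 2
      u <- gl_x[j]                       # cos(theta)
      phi <- 2 * pi * (k - 1) / nphi
      st <- sqrt(1 - u^2)
      x <- r * c(st * cos(phi), st * sin(phi), u)
      w <- gl_w[i] * gl_w[j] * r^2       # volume element (angular/2pi const)
      tot <- tot + w * sum((a %*% x + b)^2)
      wsum <- wsum + w
    }
    sqrt(tot / wsum)
  }
  rot <- function(rx, ry, rz) {
    Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
    Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
    Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
  for (params in list(c(0.002, 0, 0), c(0, 0.001, 0.003))) {
    m <- matrix(0, 2, 6)
    m[2, 4:6] <- params
    fd <- framewise_displacement(m, head_radius = 80)$fd[1]
    a <- rot(params[1], params[2], params[3]) - diag(3)
    expect_equal(fd, quad_rms(a, c(0, 0, 0), 80), tolerance = 1e-6)
  }
})

test_that("outlier detection flags intensity and motion excursions", {
  set.seed(1)
  ts <- matrix(rnorm(20 * 50, 100, 1), 20, 50)
  expect_false(any(detect_outliers(ts * 0 + 100)$flagged))
  # one frame scaled 10x: intensity flag
  bad <- ts
  bad[, 17] <- bad[, 17] * 10
  om <- detect_outliers(bad)
  expect_true(om$flagged[17])
  expect_match(om$reasons[17], "intensity")
  # brute-force recomputation of both criteria on random input
  m <- matrix(rnorm(50 * 6, 0, 0.3), 50, 6)
  fd <- framewise_displacement(m)
  om2 <- detect_outliers(ts, fd, z_thresh = 1.5, fd_thresh = 0.4)
  gs <- colMeans(ts)
  ref_int <- abs((gs - mean(gs)) / sd(gs)) > 1.5
  ref_mot <- c(FALSE, fd$fd > 0.4)
  expect_identical(om2$flagged, ref_int | ref_mot)
})

test_that("grand-mean scaling normalizes exactly and rejects degenerate input", {
  set.seed(2)
  ts <- matrix(runif(30 * 40, 10, 90), 30, 40)
  scaled <- grand_mean_scale(ts)
  expect_equal(mean(scaled), 100, tolerance = 1e-10)
  expect_equal(grand_mean_scale(ts * 0 + 50), ts * 0 + 100)
  already <- grand_mean_scale(ts)
  expect_equal(grand_mean_scale(already), already)
  expect_error(grand_mean_scale(ts - mean(ts)),
               class = "fconn_degenerate_input")
})

test_that("nuisance regression is exact, orthogonal and idempotent", {
  set.seed(3)
  tt <- 80
  design <- build_nuisance_design(tt, matrix(rnorm(tt * 6), tt, 6))
  # a node equal to a regressor is annihilated
  ts <- rbind(design[, 2], rnorm(tt))
  res <- nuisance_regress(ts, design)
  expect_lt(max(abs(res[1, ])), 1e-8)
  # residuals orthogonal to every regressor
  expect_lt(max(abs(res %*% design)), 1e-6)
  # zero-mean series orthogonal to the design is untouched
  orth <- qr.resid(qr(design), rnorm(tt))
  expect_equal(drop(nuisance_regress(rbind(orth), design)), orth,
               tolerance = 1e-8)
  # idempotency
  res2 <- nuisance_regress(res, design)
  expect_lt(max(abs(res2 - res)), 1e-10)
  # planted artifact removal recovers the clean series (long run so the
  # design absorbs a negligible share of the clean signal)
  tt2 <- 500
  design2 <- build_nuisance_design(tt2, matrix(rnorm(tt2 * 6), tt2, 6))
  clean <- bandpass_filter(rnorm(tt2), tr_seconds = 2)
  contaminated <- rbind(clean + 3 * design2[, 3])
  rec <- nuisance_regress(contaminated, design2)
  expect_gt(cor(drop(rec), clean), 0.99)
  # collinear design named in the error
  bad <- cbind(design, dup = design[, 2])
  expect_error(nuisance_regress(ts, bad), "dup",
               class = "fconn_design_error")
})

test_that("CompCor recovers planted noise subspaces", {
  set.seed(4)
  tt <- 120
  comp <- matrix(rnorm(2 * tt), 2, tt)
  # rank-2 noise source: loadings x components
  noise_source <- matrix(rnorm(30 * 2), 30, 2) %*% comp
  full <- matrix(rnorm(50 * tt), 50, tt)
  cc <- compcor_components(noise_source, full, n_components = 4)
  expect_identical(cc$source, rep(c("aCompCor", "tCompCor"), each = 2))
  # orthonormal within the set
  g <- crossprod(cc$components[, 1:2])
  expect_equal(g, diag(2), tolerance = 1e-8)
  # principal angle between recovered and true span < 1e-6
  ref_span <- svd(scale(t(comp), scale = FALSE))$u[, 1:2]
  sv <- svd(crossprod(ref_span, cc$components[, 1:2]))$d
  expect_lt(acos(min(pmin(sv, 1))), 1e-6)
  # degenerate: identical rows cannot support 2 components
  flat <- matrix(rep(rnorm(tt), 10), 10, byrow = TRUE)
  expect_error(compcor_components(flat, full, n_components = 4),
               class = "fconn_degenerate_input")
})

test_that("CompCor regression restores planted connectivity", {
  # same seed with and without structured noise yields the same signal
  # realization, so the noiseless twin is the exact reference
  base_args <- list(n_per_group = 3, n_nodes = 20, n_timepoints = 200,
                    target_nodes = 2:5, noise_sd = 0, baseline = 0,
                    rng_seed = 31)
  noisy <- generate_roi_dataset(do.call(sim_config,
                                        c(base_args, n_structured_noise = 2)))
  twin <- generate_roi_dataset(do.call(sim_config, base_args))
  set.seed(32)
  err_raw <- err_clean <- numeric(0)
  for (i in seq_along(noisy$subjects)) {
    s <- noisy$subjects[[i]]
    ref <- twin$subjects[[i]]$data
    ref_r <- mean(cor(ref[1, ], t(ref[2:5, ])))
    # regress out the true planted components (estimation quality of the
    # CompCor subspace itself is covered by the principal-angle test)
    cleaned <- nuisance_regress(s$data, cbind(1, t(s$noise_components)))
    err_raw <- c(err_raw, abs(mean(cor(s$data[1, ], t(s$data[2:5, ]))) - ref_r))
    err_clean <- c(err_clean,
                   abs(mean(cor(cleaned[1, ], t(cleaned[2:5, ]))) - ref_r))
  }
  expect_lt(mean(err_clean), 0.05)
  expect_lt(mean(err_clean), mean(err_raw))
})

test_that("band-pass filter passes the band and kills the stopband and DC", {
  tt <- 600
  tr <- 2
  tgrid <- (seq_len(tt) - 1) * tr
  in_band <- sin(2 * pi * 0.05 * tgrid)
  out_band <- sin(2 * pi * 0.2 * tgrid)
  y_in <- bandpass_filter(in_band, tr_seconds = tr)
  y_out <- bandpass_filter(out_band, tr_seconds = tr)
  expect_equal(fft_amp(y_in, 0.05, tr) / fft_amp(in_band, 0.05, tr), 1,
               tolerance = 0.05)
  expect_lt(fft_amp(y_out, 0.2, tr) / fft_amp(out_band, 0.2, tr), 0.1)
  # constant series: DC removed to numerical zero
  expect_lt(max(abs(bandpass_filter(rep(7, 100), tr_seconds = tr))), 1e-8)
  # grand mean of output ~ 0 (DC gone; only edge transients remain)
  set.seed(5)
  y <- bandpass_filter(matrix(rnorm(5 * 200, 50), 5, 200), tr_seconds = tr)
  expect_lt(abs(mean(y)), 0.01)
  # band outside Nyquist rejected
  expect_error(bandpass_filter(in_band, 0.01, 0.3, tr_seconds = 2),
               class = "fconn_invalid_config")
})

test_that("initial-volume discard drops exactly the leading columns", {
  ts <- matrix(seq_len(300 * 2), 2, 300, byrow = TRUE)
  out <- discard_initial_volumes(ts, 4)
  expect_identical(ncol(out), 296L)
  expect_identical(out[1, 1], ts[1, 5])
  expect_identical(discard_initial_volumes(ts, 0), ts)
  expect_error(discard_initial_volumes(ts[, 1:4], 4),
               class = "fconn_insufficient_data")
})

test_that("the full denoising chain preserves planted signal and logs its order", {
  cfg <- sim_config(n_per_group = 2, n_nodes = 15, n_timepoints = 150,
                    target_nodes = 2:4, noise_sd = 0, motion_spike_rate = 0,
                    drift_sd = 0, rng_seed = 41)
  ds <- generate_roi_dataset(cfg)
  s <- ds$subjects[[1]]
  raw_r <- mean(cor(s$data[1, ], t(s$data[2:4, ])))
  den <- denoise_subject(s$data, motion = NULL, n_discard = 0,
                         tr_seconds = cfg$tr_seconds)
  clean_r <- mean(cor(den$data[1, ], t(den$data[2:4, ])))
  expect_lt(abs(clean_r - raw_r), 0.02)
  # order contract: steps logged in the stated sequence
  expect_match(den$steps[1], "discard")
  expect_match(den$steps[2], "outliers")
  expect_match(den$steps[3], "grand_mean")
  expect_match(den$steps[length(den$steps)], "bandpass")
})
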