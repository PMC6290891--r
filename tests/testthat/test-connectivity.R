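test_that("ROI averaging is the plain unweighted mean", {
  ts <- rbind(rep(0, 5), rep(2, 5), 1:5)
  expect_equal(roi_timeseries(ts, 3), 1:5)
  expect_equal(roi_timeseries(ts, c(1, 2)), rep(1, 5))
  expect_equal(roi_timeseries(rbind(ts[3, ], ts[3, ]), 1:2), 1:5)
  expect_error(roi_timeseries(ts, integer(0)), class = "fconn_empty_roi")
})

test_that("Fisher z matches the closed form and is odd and increasing", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.5), 6), 0.549306)
  expect_equal(round(fisher_z(-0.3), 6), -0.309520)
  expect_equal(fisher_z(-0.3), -atanh(0.3), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  r <- seq(-1, 1, by = 0.01)
  z <- fisher_z(r)
  expect_true(all(diff(z) > 0))
  expect_equal(fisher_z(-r), -z)
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.01), class = "fconn_domain_error")
})

test_that("seed maps clip perfect correlations and flag constant targets", {
  set.seed(6)
  seed <- rnorm(50)
  targets <- rbind(seed, -seed, rep(1, 50), rnorm(50))
  sm <- seed_connectivity_map(seed, targets)
  zmax <- atanh(1 - 1e-7)
  expect_equal(sm$z[1], zmax)
  expect_equal(sm$z[2], -zmax)
  expect_equal(sm$z[3], 0)
  expect_identical(sm$constant_targets, 3L)
  expect_error(seed_connectivity_map(rep(1, 50), targets),
               class = "fconn_degenerate_input")
})

test_that("null seed-map z values have the known 1/sqrt(T-3) spread", {
  set.seed(7)
  tt <- 296
  sm <- seed_connectivity_map(rnorm(tt), matrix(rnorm(10000 * tt), 10000, tt))
  expect_equal(sd(sm$z), 1 / sqrt(tt - 3), tolerance = 0.05)
})

test_that("adjacency equals the direct correlation formula and its invariants", {
  set.seed(8)
  ts <- matrix(rnorm(5 * 100), 5, 100)
  a <- build_adjacency(ts)
  # entry-by-entry oracle: covariance over sd products
  for (i in 1:4) for (j in (i + 1):5) {
    xi <- ts[i, ] - mean(ts[i, ])
    xj <- ts[j, ] - mean(ts[j, ])
    expect_equal(a[i, j], sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)),
                 tolerance = 1e-12)
  }
  expect_equal(unclass(a), t(unclass(a)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(diag(a), setNames(rep(0, 5), rownames(a)))
  # proportional rows correlate at 1; orthogonal zero-mean rows at 0
  prop <- rbind(1:10, 2 * (1:10) + 3, rnorm(10))
  expect_equal(build_adjacency(prop)[1, 2], 1)
  orth <- rbind(rep(c(1, -1), 5), rep(c(1, 1, -1, -1), length.out = 10))
  expect_lt(abs(build_adjacency(orth)[1, 2]), 1e-12)
  # constant node flagged and zeroed
  withc <- rbind(ts, rep(3, 100))
  ac <- build_adjacency(withc)
  expect_identical(attr(ac, "constant_nodes"), 6L)
  expect_equal(ac[6, ], setNames(rep(0, 6), rownames(ac)))
})

test_that("seed map of all nodes equals the adjacency row", {
  set.seed(9)
  ts <- matrix(rnorm(8 * 60), 8, 60)
  a <- build_adjacency(ts, scale = "z")
  sm <- seed_connectivity_map(ts[3, ], ts)
  expect_equal(sm$z[-3], a[3, -3], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("network aggregation averages the right pair sets", {
  # constant off-diagonal: every within/between value equals the constant
  n <- 9
  cm <- matrix(0.4, n, n)
  diag(cm) <- 0
  assign <- rep(c("DMN", "FPCN", "VIS"), each = 3)
  nc <- lsn_connectivity(cm, assign)
  expect_equal(unname(nc$within), rep(0.4, 3))
  expect_equal(unname(nc$between[upper.tri(nc$between)]), rep(0.4, 3))
  expect_equal(nc$between, t(nc$between))
  # single-node network: within undefined, not zero
  nc1 <- lsn_connectivity(cm, c(rep("A", 8), "solo"))
  expect_true(is.na(nc1$within[["solo"]]))
  expect_false(is.na(nc1$between["A", "solo"]))
  # shift property: adding c shifts every summary by exactly c
  set.seed(10)
  cm2 <- matrix(rnorm(n * n), n, n)
  cm2 <- (cm2 + t(cm2)) / 2
  diag(cm2) <- 0
  base <- lsn_connectivity(cm2, assign)
  shifted <- lsn_connectivity(cm2 + 0.25 - diag(0.25, n), assign)
  expect_equal(shifted$within, base$within + 0.25)
  expect_equal(shifted$between, base$between + 0.25)
})

test_that("planted two-network structure is recovered by the aggregation", {
  # two 8-node networks, within-r 0.6, between-r 0: draw long series from
  # the exact covariance and aggregate the z-scaled adjacency
  set.seed(11)
  blk <- matrix(0.6, 8, 8)
  diag(blk) <- 1
  sigma <- rbind(cbind(blk, matrix(0, 8, 8)), cbind(matrix(0, 8, 8), blk))
  ch <- chol(sigma)
  ts <- t(ch) %*% matrix(rnorm(16 * 20000), 16, 20000)
  a <- build_adjacency(ts, scale = "z")
  nc <- lsn_connectivity(a, rep(c("n1", "n2"), each = 8))
  expect_equal(unname(nc$within), rep(atanh(0.6), 2), tolerance = 0.02)
  expect_equal(nc$between["n1", "n2"], 0, tolerance = 0.02)
})

test_that("cluster-label overlap percentages complete to 100", {
  map <- array(0L, c(4, 4, 2))
  map[1:2, , 1] <- 1L   # label 1
  map[3, , 1] <- 2L     # label 2
  cl_in <- which(map == 1)[1:5]
  ov <- cluster_overlap(cl_in, map)
  expect_equal(ov[["1"]], 100)
  expect_equal(ov[["unlabeled"]], 0)
  # 10-voxel cluster: 4 in label 1, 6 unlabeled
  cl_mix <- c(which(map == 1)[1:4], which(map == 0)[1:6])
  ov2 <- cluster_overlap(cl_mix, map)
  expect_equal(ov2[["1"]], 40)
  expect_equal(ov2[["unlabeled"]], 60)
  expect_error(cluster_overlap(integer(0), map), class = "fconn_empty_cluster")
  # brute-force set-intersection oracle on random clusters/maps
  set.seed(12)
  for (rep in 1:10) {
    rmap <- array(sample(0:3, 64, replace = TRUE), c(4, 4, 4))
    cl <- sample(64, 20)
    ov3 <- cluster_overlap(cl, rmap)
    for (lab in 1:3) {
      expected <- 100 * length(intersect(cl, which(rmap == lab))) / 20
      got <- if (as.character(lab) %in% names(ov3)) ov3[[as.character(lab)]] else 0
      expect_equal(got, expected)
    }
    expect_equal(sum(ov3), 100)
  }
})
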