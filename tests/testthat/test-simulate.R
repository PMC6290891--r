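test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_per_group = 1), class = "fconn_invalid_config")
  expect_error(sim_config(base_r = 1), class = "fconn_invalid_config")
  expect_error(sim_config(seed_node = 2, target_nodes = 2:4),
               class = "fconn_invalid_config")
  expect_error(sim_config(n_nodes = 5, target_nodes = 2:9),
               class = "fconn_invalid_config")
  # implied group-B correlation must stay below 1
  expect_error(sim_config(base_r = 0.99, delta_z = 10),
               class = "fconn_invalid_config")
})

test_that("group covariance plants the configured seed-target correlation", {
  cfg <- sim_config(n_nodes = 12, base_r = 0.3, delta_z = 0.3,
                    target_nodes = 2:5)
  sa <- build_group_covariance(cfg, "A")
  sb <- build_group_covariance(cfg, "B")
  expect_equal(diag(sa), rep(1, 12))
  expect_equal(sa, t(sa))
  expect_true(min(eigen(sa, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10)
  expect_true(min(eigen(sb, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10)
  # closed forms
  expect_equal(sa[1, 2], 0.3, tolerance = 0.01)
  expect_equal(sb[1, 2], tanh(atanh(0.3) + 0.3), tolerance = 0.01)
  expect_equal(tanh(atanh(0.3) + 0.3), 0.5437888, tolerance = 1e-6)
  # zero effect: groups identical
  cfg0 <- sim_config(n_nodes = 12, delta_z = 0, target_nodes = 2:5)
  expect_identical(build_group_covariance(cfg0, "A"),
                   build_group_covariance(cfg0, "B"))
  # full independence: identity
  cfgi <- sim_config(n_nodes = 8, base_r = 0, delta_z = 0, target_nodes = 2:3)
  expect_equal(build_group_covariance(cfgi, "A"), diag(8))
})

test_that("ROI datasets are deterministic with the documented shapes", {
  cfg <- sim_config(n_per_group = 3, n_nodes = 10, n_timepoints = 60,
                    target_nodes = 2:4, rng_seed = 9)
  d1 <- generate_roi_dataset(cfg)
  d2 <- generate_roi_dataset(cfg)
  expect_identical(d1, d2)
  expect_length(d1$subjects, 6)
  for (s in d1$subjects) expect_identical(dim(s$data), c(10L, 60L))
  expect_identical(vapply(d1$subjects, `[[`, "", "group"),
                   rep(c("A", "B"), each = 3))
  # different seed changes the data
  d3 <- generate_roi_dataset(sim_config(n_per_group = 3, n_nodes = 10,
                                        n_timepoints = 60, target_nodes = 2:4,
                                        rng_seed = 10))
  expect_false(identical(d1$subjects[[1]]$data, d3$subjects[[1]]$data))
})

test_that("empirical seed-target correlation recovers the planted value", {
  # large groups, no measurement noise: Monte-Carlo check against the
  # planted covariance
  cfg <- sim_config(n_per_group = 200, n_nodes = 12, n_timepoints = 296,
                    base_r = 0.3, delta_z = 0.3, target_nodes = 2:4,
                    noise_sd = 0, baseline = 0, rng_seed = 21)
  ds <- generate_roi_dataset(cfg)
  mean_r <- function(group) {
    subs <- Filter(function(s) s$group == group, ds$subjects)
    mean(vapply(subs, function(s)
      mean(cor(s$data[1, ], t(s$data[2:4, , drop = FALSE]))), numeric(1)))
  }
  expect_equal(mean_r("A"), ds$truth$group_correlations[["A"]], tolerance = 0.02)
  expect_equal(mean_r("B"), ds$truth$group_correlations[["B"]], tolerance = 0.02)
})

test_that("lattice datasets honor the effect region contract", {
  cfg <- sim_config(n_per_group = 2, n_timepoints = 40, rng_seed = 4)
  # region outside lattice errors
  expect_error(
    generate_lattice_dataset(cfg, c(6, 6, 6),
                             list(corner = c(5, 5, 5), size = c(3, 3, 3))),
    class = "fconn_invalid_config")
  # zero-voxel region: pure null allowed
  d0 <- generate_lattice_dataset(cfg, c(5, 5, 5), NULL)
  expect_length(d0$truth$affected_region, 0)
  expect_identical(dim(d0$subjects[[1]]$data), c(125L, 40L))
  # zero effect: both groups get the same planted correlation
  cfg0 <- sim_config(n_per_group = 2, n_timepoints = 40, delta_z = 0,
                     rng_seed = 4)
  dz <- generate_lattice_dataset(cfg0, c(5, 5, 5),
                                 list(corner = c(2, 2, 2), size = c(2, 2, 2)))
  expect_identical(dz$truth$group_correlations[["A"]],
                   dz$truth$group_correlations[["B"]])
  # planted region recorded as linear indices inside the lattice
  dr <- generate_lattice_dataset(cfg, c(6, 6, 6),
                                 list(corner = c(2, 2, 2), size = c(3, 3, 3)))
  expect_length(dr$truth$affected_region, 27)
  expect_true(all(dr$truth$affected_region >= 1 &
                    dr$truth$affected_region <= 216))
  # non-contiguous explicit region rejected
  expect_error(
    generate_lattice_dataset(cfg, c(6, 6, 6),
                             rbind(c(1, 1, 1), c(4, 4, 4))),
    class = "fconn_invalid_config")
})

test_that("motion traces respect drift and spike configuration", {
  cfg <- sim_config(n_per_group = 2, n_timepoints = 100,
                    motion_spike_rate = 0, rng_seed = 5)
  m <- generate_motion_traces(cfg)
  expect_length(m, 4)
  expect_identical(dim(m[[1]]), c(100L, 6L))
  # no spikes: frame-to-frame translation stays below the drift bound
  for (tr in m)
    expect_lt(max(abs(diff(tr[, 1:3]))), attr(tr, "drift_bound"))
  # rate 1: a spike at every transition
  cfg1 <- sim_config(n_per_group = 2, n_timepoints = 50,
                     motion_spike_rate = 1, rng_seed = 5)
  m1 <- generate_motion_traces(cfg1)
  expect_identical(attr(m1[[1]], "spikes"), 2:50)
  # spike count matches the binomial rate over many subjects
  cfg2 <- sim_config(n_per_group = 50, n_timepoints = 296,
                     motion_spike_rate = 0.1, rng_seed = 6)
  total <- sum(vapply(generate_motion_traces(cfg2),
                      function(x) length(attr(x, "spikes")), integer(1)))
  n_trials <- 100 * 295
  ci99 <- qbinom(c(0.005, 0.995), n_trials, 0.1)
  expect_gte(total, ci99[1])
  expect_lte(total, ci99[2])
})

test_that("a null configuration keeps the end-to-end flag rate at alpha", {
  # delta_z = 0: the family-wise rate of flagging any node's degree or
  # strength AUC must stay at the nominal 5% level over replicates
  reps <- 50
  hits_deg <- hits_str <- 0
  for (r in seq_len(reps)) {
    cfg <- sim_config(delta_z = 0, rng_seed = 2000 + r)
    ds <- generate_roi_dataset(cfg)
    cms <- lapply(ds$subjects, function(s) build_adjacency(s$data))
    des <- group_design(vapply(ds$subjects, `[[`, "", "group"))
    for (metric in c("degree", "strength")) {
      auc <- auc_table(cms, metric)
      bt <- bootstrap_maxt_test(auc, des, n_boot = 1000,
                                rng_seed = 2200 + r)
      if (min(bt$p_corr) < 0.05) {
        if (metric == "degree") hits_deg <- hits_deg + 1
        else hits_str <- hits_str + 1
      }
    }
  }
  ci <- qbinom(c(0.025, 0.975), reps, 0.05)
  expect_gte(hits_deg, ci[1])
  expect_lte(hits_deg, ci[2])
  expect_gte(hits_str, ci[1])
  expect_lte(hits_str, ci[2])
})

test_that("behavioral tables reproduce their generating summary statistics", {
  specs <- data.frame(measure = c("wm", "mindfulness"),
                      mean_A = c(32, 13.4), sd_A = c(9.6, 3.5),
                      mean_B = c(33.2, 11.9), sd_B = c(12.2, 3.4))
  expect_error(generate_behavioral_table(specs, 1),
               class = "fconn_invalid_config")
  bad <- specs
  bad$sd_A[1] <- 0
  expect_error(generate_behavioral_table(bad, 10),
               class = "fconn_invalid_config")
  # seeded reproducibility
  b1 <- generate_behavioral_table(specs, 14, rng_seed = 2)
  b2 <- generate_behavioral_table(specs, 14, rng_seed = 2)
  expect_identical(b1, b2)
  # law of large numbers at n = 1e5
  big <- generate_behavioral_table(specs[1, ], 1e5, rng_seed = 3)
  expect_equal(big$summary$mean_A, 32, tolerance = 0.02 * 9.6)
  expect_equal(big$summary$mean_B, 33.2, tolerance = 0.02 * 12.2)
  # identical specs for both groups give t = 0 on population values
  expect_equal(t_from_summary(32, 9.6, 14, 32, 9.6, 14)$t, 0)
})
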