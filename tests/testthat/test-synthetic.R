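test_that("zero-speed cells never move", {
  cfg <- one_group_config(speed_median = 0, n_cells = 10, n_frames = 20)
  tr <- simulate_trajectories(cfg, "Control")
  per_cell <- tapply(seq_len(nrow(tr)), tr$cell_id, function(i)
    max(abs(tr$x_um[i] - tr$x_um[i][1]), abs(tr$y_um[i] - tr$y_um[i][1])))
  expect_true(all(per_cell == 0))
})

test_that("identical config and seed reproduce byte-identical tables", {
  cfg <- one_group_config(n_cells = 40, n_frames = 30, n_replicates = 3,
                          seed = 99)
  a <- simulate_trajectories(cfg, "Control")
  b <- simulate_trajectories(cfg, "Control")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  readr::write_csv(a, f1); readr::write_csv(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  cfg2 <- one_group_config(n_cells = 40, n_frames = 30, n_replicates = 3,
                           seed = 100)
  expect_false(identical(simulate_trajectories(cfg2, "Control")$x_um, a$x_um))
})

test_that("per-cell speed draws recover the configured median", {
  cfg <- preset_group_config("xray-control", n_cells = 1e5, n_frames = 2,
                             seed = 12)
  tr <- simulate_trajectories(cfg, "Control")
  sp <- attr(tr, "cell_params")$speed_umph
  expect_equal(length(sp), 1e5)
  expect_equal(median(sp), 5.73, tolerance = 0.01)
})

test_that("fitted log-sigma reproduces the quartiles it was fitted from", {
  # symmetric-in-log IQR: the fit is exact for a lognormal truth
  s <- lognormal_sigma_from_iqr(5, 5 * exp(-0.6), 5 * exp(0.6))
  expect_equal(s, 0.6 / qnorm(0.75), tolerance = 1e-12)
  # calibrated presets put the printed quartiles within a few percent
  for (id in c("xray-control", "cisplatin-uniform")) {
    p <- speed_preset(id)
    q <- qlnorm(c(0.25, 0.75), log(p$speed_median), p$speed_log_sigma)
    expect_equal(q[1], p$speed_q1, tolerance = 0.05)
    expect_equal(q[2], p$speed_q3, tolerance = 0.05)
  }
})

test_that("persistence-free Gaussian walks obey the diffusive MSD law", {
  # generator cohort: per-axis step SD sigma = 2 um  =>  MSD(k) = 8k um^2
  sigma <- 2
  speed <- sigma * sqrt(pi / 2) / 0.25      # mean step L = sigma*sqrt(pi/2)
  cfg <- one_group_config(speed_median = speed, speed_log_sigma = 0,
                          n_cells = 5000, n_frames = 25,
                          step_law = "gaussian", seed = 5)
  msd <- ensemble_msd(simulate_trajectories(cfg, "Control"))
  k <- seq_along(msd$msd_um2)
  # independent Monte-Carlo oracle: 1e5 plain cumulative-sum Gaussian walks
  set.seed(6)
  n_o <- 1e5
  ox <- apply(matrix(rnorm(24 * n_o, 0, sigma), 24), 2, cumsum)
  oy <- apply(matrix(rnorm(24 * n_o, 0, sigma), 24), 2, cumsum)
  oracle <- rowMeans(ox^2 + oy^2)
  expect_equal(oracle, 8 * k, tolerance = 0.02)
  expect_equal(msd$msd_um2, oracle, tolerance = 0.05)
})

test_that("net displacement grows with directional persistence", {
  meds <- sapply(c(0, 0.4, 0.8), function(p) {
    cfg <- one_group_config(speed_median = 6, speed_log_sigma = 0.3,
                            persistence = p, n_cells = 500, n_frames = 49,
                            seed = 21)
    m <- cell_metrics(simulate_trajectories(cfg, "Control"))
    median(m$net_displacement_um)
  })
  expect_true(all(diff(meds) > 0))
})

test_that("start positions respect the group's analyzable region", {
  cfg <- synthetic_config(
    n_cells_per_group = 200, n_replicates = 2, n_frames = 2, seed = 8,
    groups = list(
      "In-field" = list(speed_median = 5, speed_log_sigma = 0.3),
      "Out-of-field" = list(speed_median = 5, speed_log_sigma = 0.3),
      "Control" = list(speed_median = 5, speed_log_sigma = 0.3)))
  tr <- simulate_cohort(cfg)
  first <- tr[tr$frame == 1, ]
  expect_true(all(first$x_um[first$group == "In-field"] < -10000))
  expect_true(all(first$x_um[first$group == "Out-of-field"] > 10000))
  expect_true(all(sqrt(first$x_um^2 + first$y_um^2) <= 30000))
})

test_that("cell-cycle states sample the configured distribution", {
  st <- sample_cellcycle_states(50, c(0, 0, 1), seed = 2)
  expect_true(all(st == "green"))
  st <- sample_cellcycle_states(3e5, rep(1 / 3, 3), seed = 3)
  expect_true(all(abs(table(st) / 3e5 - 1 / 3) < 0.01))
  expect_identical(sample_cellcycle_states(100, c(0.2, 0.3, 0.5), seed = 4),
                   sample_cellcycle_states(100, c(0.2, 0.3, 0.5), seed = 4))
})

test_that("invalid generator inputs are rejected", {
  expect_error(one_group_config(persistence = 1.2), "persistence")
  expect_error(one_group_config(persistence = -0.1), "persistence")
  expect_error(one_group_config(speed_median = -2), "speed_median")
  cfg <- one_group_config()
  expect_error(simulate_trajectories(cfg, "Nope"), "unknown group")
  expect_error(sample_cellcycle_states(10, c(0.5, 0.4, 0.2)), "summing to 1")
  expect_error(synthetic_config(n_cells_per_group = 10, n_frames = 1,
                                groups = list(Control = list(speed_median = 5))),
               "n_frames")
})
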