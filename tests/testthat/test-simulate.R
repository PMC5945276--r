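geom <- cassette_geometry()

test_that("cut fraction extremes behave as forced", {
  cfg0 <- sim_config(n_cells = 40, cut_fraction = 0, seed = 1)
  ev0 <- simulate_events(cfg0, geom)
  expect_true(all(!ev0$is_cut))
  expect_true(all(is.na(ev0$true_rate_kb_per_hr)))

  cfg1 <- sim_config(n_cells = 20, cut_fraction = 1, seed = 1,
                     rate_model = rate_model(13.87, sdlog = 0),
                     cut_time_window_min = 1e-9,
                     rad52_delay_range_min = c(0, 0))
  ev1 <- simulate_events(cfg1, geom)
  expect_true(all(ev1$is_cut))
  expect_equal(ev1$gfp_loss_time_min, rep(60, 20), tolerance = 1e-6)
})

test_that("cut count is binomial around n * cut_fraction", {
  cfg <- sim_config(n_cells = 10000, cut_fraction = 0.15, seed = 42)
  ev <- simulate_events(cfg, geom)
  expected <- 1500
  sd3 <- 3 * sqrt(10000 * 0.15 * 0.85)
  expect_lt(abs(sum(ev$is_cut) - expected), sd3)
})

test_that("event truth obeys the constant-rate timing relations", {
  cfg <- sim_config(n_cells = 200, cut_fraction = 1, seed = 3)
  ev <- simulate_events(cfg, geom)
  expect_true(all(ev$rad52_visible_time_min >= ev$cut_time_min))
  d <- ev$rad52_visible_time_min - ev$cut_time_min
  expect_true(all(d >= 30 & d <= 60))
  expect_equal(ev$gfp_loss_time_min,
               ev$rad52_visible_time_min +
                 60 * total_distance(geom) / ev$true_rate_kb_per_hr)
  expect_equal(ev$completes_in_window, ev$gfp_loss_time_min <= 300)
})

test_that("identical seeds reproduce identical truth tables and stacks", {
  cfg <- sim_config(n_cells = 4, cut_fraction = 0.5, seed = 11, roi_px = 12,
                    z_slices = 9)
  ev1 <- simulate_events(cfg, geom); ev2 <- simulate_events(cfg, geom)
  expect_identical(ev1, ev2)
  r1 <- render_stack(ev1, cfg, geom); r2 <- render_stack(ev2, cfg, geom)
  expect_identical(r1$stack$data, r2$stack$data)
  expect_identical(r1$truth, r2$truth)
})

test_that("pre-noise GFP intensity is constant for an unbleached uncut cell
          and declines only after the front reaches the array", {
  cfg <- noiseless_config(n_cells = 1, cut_fraction = 0, seed = 5,
                          bleach_rate_per_frame = 0, roi_px = 16,
                          z_slices = 11)
  ev <- simulate_events(cfg, geom)
  rend <- render_stack(ev, cfg, geom, jitter_centers = FALSE)
  per_frame <- apply(rend$stack$data[, 1, , , ], 1, sum)
  expect_equal(per_frame, rep(per_frame[1], cfg$n_frames), tolerance = 1e-9)

  # cut cell: first pre-noise decline at onset + 60 * spacer / rate
  cfg2 <- noiseless_config(n_cells = 1, cut_fraction = 1, seed = 5,
                           bleach_rate_per_frame = 0, roi_px = 16,
                           z_slices = 11,
                           cut_time_window_min = 1e-9,
                           rad52_delay_range_min = c(40, 40),
                           rate_model = rate_model(7.6, sdlog = 0))
  ev2 <- simulate_events(cfg2, geom)
  rend2 <- render_stack(ev2, cfg2, geom, jitter_centers = FALSE)
  gfp <- apply(rend2$stack$data[, 1, , , ], 1, sum)
  t_decline <- 40 + 60 * 3.57 / 7.6          # 68.2 min
  frames <- (seq_len(cfg2$n_frames) - 1) * 10
  flat <- frames <= t_decline
  expect_equal(gfp[flat], rep(gfp[1], sum(flat)), tolerance = 1e-9)
  expect_true(all(diff(gfp[!flat][1:5]) < 0))
})

test_that("with the PSF collapsed the rendered focus carries the configured
          integrated intensity exactly", {
  cfg <- noiseless_config(n_cells = 1, cut_fraction = 0, seed = 2,
                          bleach_rate_per_frame = 0, roi_px = 12,
                          z_slices = 9, psf_sigma_xy_px = 1e-9,
                          psf_sigma_z_slices = 1e-9, n_frames = 2)
  ev <- simulate_events(cfg, geom)
  rend <- render_stack(ev, cfg, geom, jitter_centers = FALSE)
  vol <- rend$stack$data[1, 1, , , ]
  expect_equal(sum(vol), cfg$gfp_intensity)
  expect_equal(max(vol), cfg$gfp_intensity)   # a single voxel
})

test_that("mitosis-free bleaching is multiplicative per exposure", {
  cfg <- noiseless_config(n_cells = 1, cut_fraction = 0, seed = 2,
                          bleach_rate_per_frame = 0.05, roi_px = 12,
                          z_slices = 9, n_frames = 10)
  ev <- simulate_events(cfg, geom)
  rend <- render_stack(ev, cfg, geom, jitter_centers = FALSE)
  gfp <- apply(rend$stack$data[, 1, , , ], 1, sum)
  expect_equal(gfp / gfp[1], 0.95^(0:9), tolerance = 1e-9)
})

test_that("simulated qPCR plates respect front monotonicity and limits", {
  cfg <- sim_config(n_cells = 3000, cut_fraction = 0.15, seed = 9,
                    rate_model = rate_model(7.6))
  plate <- simulate_qpcr_plate(cfg, site_distances_kb = c(3, 13),
                               timepoints_min = c(0, 120, 240))
  truth <- attr(plate, "truth")
  expect_true(all(truth$true_protected_fraction[truth$time_min == 0] == 0))
  # nearer site is always at least as protected
  for (t in unique(truth$time_min)) {
    p3 <- truth$true_protected_fraction[truth$time_min == t &
                                          truth$site_kb == 3]
    p13 <- truth$true_protected_fraction[truth$time_min == t &
                                           truth$site_kb == 13]
    expect_gte(p3, p13)
  }
  # fast-rate, fully cut, late-time limit: everything protected
  cfg2 <- sim_config(n_cells = 2000, cut_fraction = 1, seed = 9,
                     rate_model = rate_model(1000, sdlog = 0))
  plate2 <- simulate_qpcr_plate(cfg2, site_distances_kb = c(3, 13),
                                timepoints_min = 1000)
  truth2 <- attr(plate2, "truth")
  expect_true(all(truth2$true_protected_fraction == 1))
})
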