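test_that("cylinder/shell photometry matches brute-force voxel enumeration", {
  set.seed(101)
  for (i in 1:30) {
    d <- c(sample(5:9, 1), sample(9:14, 1), sample(9:14, 1))
    vol <- array(runif(prod(d), 0, 1000), dim = d)
    params <- cylinder_params(radius_px = runif(1, 1, 2.5),
                              half_height_slices = sample(1:2, 1),
                              shell_gap_px = runif(1, 0, 1),
                              shell_width_px = runif(1, 1, 2))
    center <- c(runif(1, d[1] / 2 - 0.5, d[1] / 2 + 0.5),
                runif(1, d[2] / 2 - 0.5, d[2] / 2 + 0.5),
                runif(1, d[3] / 2 - 0.5, d[3] / 2 + 0.5))
    st <- vol_stack(vol)
    m <- measure_focus_intensity(st, "GFP", 1, center, params)
    if (!m$valid) next
    expect_equal(m$integrated_intensity,
                 brute_force_cylinder(vol, center, params))
  }
})

test_that("photometry is linear in gain, exactly background-invariant, and
          translation-invariant", {
  set.seed(7)
  vol <- gauss_spot_vol(c(9, 15, 15), c(5, 8, 8), 5000, 1.5, 1.3,
                        background = 50) + array(runif(9 * 15 * 15, 0, 5),
                                                 dim = c(9, 15, 15))
  params <- cylinder_params(radius_px = 2.5, half_height_slices = 2)
  base <- measure_focus_intensity(vol_stack(vol), "GFP", 1, c(5, 8, 8),
                                  params)
  scaled <- measure_focus_intensity(vol_stack(3 * vol), "GFP", 1, c(5, 8, 8),
                                    params)
  offset <- measure_focus_intensity(vol_stack(vol + 123), "GFP", 1,
                                    c(5, 8, 8), params)
  expect_equal(scaled$integrated_intensity, 3 * base$integrated_intensity)
  expect_equal(offset$integrated_intensity, base$integrated_intensity)
  # whole-voxel translation away from borders
  big <- array(0, dim = c(9, 21, 21))
  big[, 1:15, 1:15] <- vol
  shifted <- array(0, dim = c(9, 21, 21))
  shifted[, 4:18, 5:19] <- vol
  m1 <- measure_focus_intensity(vol_stack(big), "GFP", 1, c(5, 8, 8), params)
  m2 <- measure_focus_intensity(vol_stack(shifted), "GFP", 1, c(5, 11, 12),
                                params)
  expect_equal(m2$integrated_intensity, m1$integrated_intensity)
})

test_that("a uniform image measures zero and a border cylinder is invalid", {
  vol <- array(77, dim = c(9, 15, 15))
  st <- vol_stack(vol)
  m <- measure_focus_intensity(st, "GFP", 1, c(5, 8, 8), cylinder_params())
  expect_true(m$valid)
  expect_equal(m$integrated_intensity, 0)
  edge <- measure_focus_intensity(st, "GFP", 1, c(5, 2, 8), cylinder_params())
  expect_false(edge$valid)
  expect_true(is.na(edge$integrated_intensity))
})

test_that("a wide cylinder recovers a rendered focus intensity within 5%", {
  vol <- gauss_spot_vol(c(15, 25, 25), c(8, 13, 13), 10000, 1.5, 1.3,
                        background = 100)
  params <- cylinder_params(radius_px = 4, half_height_slices = 5,
                            shell_gap_px = 2, shell_width_px = 2)
  m <- measure_focus_intensity(vol_stack(vol), "GFP", 1, c(8, 13, 13),
                               params)
  expect_true(m$valid)
  expect_equal(m$integrated_intensity, 10000, tolerance = 0.05)
})

test_that("detection finds nothing on flat frames and exactly the rendered
          foci otherwise", {
  st0 <- vol_stack(array(0, dim = c(9, 20, 20)))
  expect_equal(nrow(detect_foci(st0, "GFP", 1)), 0L)
  stc <- vol_stack(array(55, dim = c(9, 20, 20)))
  expect_equal(nrow(detect_foci(stc, "GFP", 1)), 0L)

  one <- gauss_spot_vol(c(11, 24, 24), c(6, 12, 12), 8000, 1.5, 1.3,
                        background = 10)
  cand <- detect_foci(vol_stack(one), "GFP", 1)
  expect_equal(nrow(cand), 1L)
  expect_true(max(abs(c(cand$z, cand$y, cand$x) - c(6, 12, 12))) <= 1)

  two <- gauss_spot_vol(c(11, 30, 30), c(6, 10, 10), 8000, 1.5, 1.3) +
         gauss_spot_vol(c(11, 30, 30), c(6, 21, 21), 8000, 1.5, 1.3) + 10
  cand2 <- detect_foci(vol_stack(two), "GFP", 1)
  expect_equal(nrow(cand2), 2L)
})

test_that("detection is deterministic for fixed input", {
  set.seed(12)
  vol <- gauss_spot_vol(c(11, 24, 24), c(6, 12, 12), 6000, 1.5, 1.3, 100) +
    array(rnorm(11 * 24 * 24, 0, 5), dim = c(11, 24, 24))
  vol <- pmax(vol, 0)
  st <- vol_stack(vol)
  expect_identical(detect_foci(st, "GFP", 1), detect_foci(st, "GFP", 1))
})

test_that("subpixel localization recovers voxel-centered and fractional
          offsets", {
  on_voxel <- gauss_spot_vol(c(11, 21, 21), c(6, 11, 11), 8000, 1.5, 1.3, 20)
  loc <- localize_subpixel(vol_stack(on_voxel), "GFP", 1, c(6, 11, 11))
  expect_false(loc$low_confidence)
  expect_lt(max(abs(loc$center_zyx - c(6, 11, 11))), 0.05)

  off <- gauss_spot_vol(c(11, 21, 21), c(6, 11.3, 10.8), 8000, 1.5, 1.3, 20)
  loc2 <- localize_subpixel(vol_stack(off), "GFP", 1, c(6, 11, 11))
  expect_lt(abs(loc2$center_zyx[2] - 11.3), 0.15)
  expect_lt(abs(loc2$center_zyx[3] - 10.8), 0.15)

  flat <- vol_stack(array(40, dim = c(11, 21, 21)))
  loc3 <- localize_subpixel(flat, "GFP", 1, c(6, 11, 11))
  expect_true(loc3$low_confidence)
  expect_equal(loc3$center_zyx, c(6, 11, 11))
  expect_error(localize_subpixel(flat, "GFP", 1, c(50, 11, 11)), "outside")
})

test_that("traces quantify disappearance at the last known center and mark
          never-detected channels undetected throughout", {
  geom <- cassette_geometry()
  cfg <- sim_config(n_cells = 1, cut_fraction = 1, seed = 21, roi_px = 20,
                    z_slices = 15, n_frames = 25,
                    cut_time_window_min = 1e-9,
                    rad52_delay_range_min = c(30, 30),
                    rate_model = rate_model(10, sdlog = 0))
  ev <- simulate_events(cfg, geom)
  rend <- render_stack(ev, cfg, geom)
  roi <- list(y = c(rend$truth$y0, rend$truth$y1),
              x = c(rend$truth$x0, rend$truth$x1))
  gfp <- build_trace(rend$stack, "GFP", roi)
  expect_equal(nrow(gfp), 25)
  # GFP focus present early, gone late; intensity is still measured there
  expect_true(all(gfp$detected[1:5]))
  expect_false(any(gfp$detected[20:25]))
  expect_true(all(is.finite(gfp$intensity)))

  # an uncut cell has no mCherry focus in any frame
  cfg0 <- sim_config(n_cells = 1, cut_fraction = 0, seed = 22, roi_px = 20,
                     z_slices = 15, n_frames = 10)
  ev0 <- simulate_events(cfg0, geom)
  rend0 <- render_stack(ev0, cfg0, geom)
  roi0 <- list(y = c(rend0$truth$y0, rend0$truth$y1),
               x = c(rend0$truth$x0, rend0$truth$x1))
  mch <- build_trace(rend0$stack, "mCherry", roi0)
  expect_false(any(mch$detected))
  expect_error(build_trace(rend0$stack, "GFP", list(y = c(5, 2), x = c(1, 5))),
               "ROI")
})
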