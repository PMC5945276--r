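#' Per-genotype model of true long-range resection rates
#'
#' Single-cell rates are modelled as log-normal: rates are strictly
#' positive and right-skewed, which matches the visual spread of
#' single-cell measurements. The model is parameterized by its median (the
#' statistic the assay reports) and the log-scale SD.
#'
#' @param median_kb_hr Median rate in kb/hr.
#' @param sdlog SD of log-rate (dimensionless). Default 0.25.
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(median_kb_hr, sdlog = 0.25) {
  stopifnot(is.numeric(median_kb_hr), median_kb_hr > 0, sdlog >= 0)
  structure(list(median_kb_hr = median_kb_hr, sdlog = sdlog),
            class = "rate_model")
}

draw_rates <- function(model, n) {
  if (model$sdlog == 0) return(rep(model$median_kb_hr, n))
  stats::rlnorm(n, meanlog = log(model$median_kb_hr), sdlog = model$sdlog)
}

#' Default genotype rate models
#'
#' Medians: 7.6 kb/hr for wild type, 13.9 for a crb2-delete-like
#' fast-resecting genotype, 10.4 for a rev7-delete-like genotype, and
#' 1.4 kb/hr for an exo1-delete-like genotype whose resection is too slow
#' to traverse the reporter within a 5 hr acquisition (all its events
#' censor). Dispersion (sdlog 0.25) is a free simulator parameter.
#'
#' @return Named list of [rate_model()] objects.
#' @export
rate_models <- function() {
  list(WT      = rate_model(7.6),
       crb2d   = rate_model(13.9),
       rev7d   = rate_model(10.4),
       exo1d   = rate_model(1.4))
}

#' Simulation configuration
#'
#' Defaults reproduce the acquisition and induction conditions of the
#' assay: 10 min frame interval for 5 hr (31 frames), 25 Z-sections at
#' 0.26 um, ~15% of cells acquiring an on-target DSB within a 2 hr
#' induction window, and a 30-60 min delay between resection initiation at
#' the cut and a visible Rad52 focus.
#'
#' @param n_cells Number of cells to simulate.
#' @param frame_interval_min Minutes between frames. Default 10.
#' @param n_frames Number of frames. Default 31 (5 hr).
#' @param z_slices Z-sections per volume. Default 25.
#' @param z_spacing_um Z step in um. Default 0.26.
#' @param pixel_size_xy_um Lateral pixel size in um. Default 0.16
#'   (EMCCD 16 um pixels behind a 100x objective).
#' @param cut_fraction Probability a cell acquires an on-target DSB.
#'   Default 0.15.
#' @param cut_time_window_min Cut times are uniform on
#'   `[0, cut_time_window_min]`. Default 120.
#' @param rad52_delay_range_min `(min, max)` minutes from the cut (and
#'   resection initiation) to a visible Rad52 focus; long-range resection
#'   through the reporter is clocked from Rad52 visibility (initiation
#'   resects <0.3 kb). Default `c(30, 60)`.
#' @param rate_model A [rate_model()] for this genotype's true rates.
#' @param bleach_rate_per_frame Fractional GFP intensity loss per exposure
#'   (multiplicative, identical in cut and uncut cells). Default 0.012.
#' @param gfp_intensity Pre-noise integrated counts of an intact GFP focus
#'   at frame 0. Default 300 * psf mass = configured per focus; see details.
#' @param mcherry_intensity Pre-noise integrated counts of a saturated
#'   Rad52 focus. Default 4000.
#' @param mcherry_floor Fraction of `mcherry_intensity` present as soon as
#'   Rad52 loads (the just-visible ~30-molecule nucleus). Default 0.4.
#' @param mcherry_plateau_kb Resected tract length (kb) at which the Rad52
#'   focus intensity saturates. Default 6.
#' @param cell_background Per-voxel mean cellular background counts,
#'   per channel, `c(gfp, mcherry)`. Default `c(20, 10)`.
#' @param camera_offset Additive camera bias in counts. Default 100.
#' @param camera_sd Gaussian read-noise SD in counts. Default 5.
#' @param shot_noise Apply Poisson shot noise? Default TRUE.
#' @param psf_sigma_xy_px,psf_sigma_z_slices Gaussian PSF widths, lateral
#'   in pixels and axial in z-slices. Defaults 1.3 and 1.5.
#' @param roi_px Side of the square region rendered per cell, in pixels.
#'   Default 24.
#' @param seed Random seed for event simulation and rendering, or NULL.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 50,
                       frame_interval_min = 10,
                       n_frames = 31,
                       z_slices = 25,
                       z_spacing_um = 0.26,
                       pixel_size_xy_um = 0.16,
                       cut_fraction = 0.15,
                       cut_time_window_min = 120,
                       rad52_delay_range_min = c(30, 60),
                       rate_model = rate_models()$WT,
                       bleach_rate_per_frame = 0.012,
                       gfp_intensity = 12000,
                       mcherry_intensity = 4000,
                       mcherry_floor = 0.4,
                       mcherry_plateau_kb = 6,
                       cell_background = c(20, 10),
                       camera_offset = 100,
                       camera_sd = 5,
                       shot_noise = TRUE,
                       psf_sigma_xy_px = 1.3,
                       psf_sigma_z_slices = 1.5,
                       roi_px = 24,
                       seed = NULL) {
  stopifnot(n_cells >= 1, frame_interval_min > 0, n_frames >= 2,
            z_slices >= 1, z_spacing_um > 0, pixel_size_xy_um > 0,
            cut_fraction >= 0, cut_fraction <= 1,
            cut_time_window_min > 0,
            length(rad52_delay_range_min) == 2,
            rad52_delay_range_min[1] >= 0,
            rad52_delay_range_min[1] <= rad52_delay_range_min[2],
            inherits(rate_model, "rate_model"),
            bleach_rate_per_frame >= 0, bleach_rate_per_frame < 1,
            gfp_intensity > 0, mcherry_intensity > 0,
            mcherry_floor > 0, mcherry_floor <= 1, mcherry_plateau_kb > 0,
            length(cell_background) == 2, all(cell_background >= 0),
            camera_offset >= 0, camera_sd >= 0,
            psf_sigma_xy_px > 0, psf_sigma_z_slices > 0, roi_px >= 9)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

acquisition_end_min <- function(config)
  (config$n_frames - 1) * config$frame_interval_min

#' Simulate ground-truth resection events
#'
#' Draws, per cell: whether it acquires an on-target DSB (binomial with
#' `cut_fraction`), the cut time (uniform on the induction window), the
#' delay until the Rad52 focus is visible (uniform on the delay range),
#' and a true long-range rate from the genotype model. The long-range
#' resection clock starts when Rad52 becomes visible (resection initiation
#' covers only a few hundred nt during the delay), so the GFP focus is
#' fully lost at `rad52_visible + 60 * total_distance / rate` minutes.
#'
#' @param config A [sim_config()].
#' @param geometry A [cassette_geometry()].
#' @param genotype Genotype label attached to every event.
#' @return Data frame of class `truth_events`: `cell_id`, `genotype`,
#'   `is_cut`, `cut_time_min`, `rad52_visible_time_min`,
#'   `true_rate_kb_per_hr`, `gfp_loss_time_min`, `completes_in_window`.
#'   Uncut cells carry `NA` for the event fields.
#' @export
simulate_events <- function(config, geometry = cassette_geometry(),
                            genotype = "WT") {
  stopifnot(inherits(config, "sim_config"))
  geometry <- as_geometry(geometry)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_cells
  is_cut <- stats::runif(n) < config$cut_fraction
  cut_time <- ifelse(is_cut, stats::runif(n, 0, config$cut_time_window_min),
                     NA_real_)
  delay <- stats::runif(n, config$rad52_delay_range_min[1],
                        config$rad52_delay_range_min[2])
  rad52_t <- ifelse(is_cut, cut_time + delay, NA_real_)
  rate <- ifelse(is_cut, draw_rates(config$rate_model, n), NA_real_)
  loss_t <- rad52_t + 60 * geometry$total_distance_kb / rate
  out <- data.frame(
    cell_id = sprintf("%s_c%04d", genotype, seq_len(n)),
    genotype = genotype,
    is_cut = is_cut,
    cut_time_min = cut_time,
    rad52_visible_time_min = rad52_t,
    true_rate_kb_per_hr = rate,
    gfp_loss_time_min = loss_t,
    completes_in_window = !is.na(loss_t) & loss_t <= acquisition_end_min(config),
    stringsAsFactors = FALSE)
  class(out) <- c("truth_events", class(out))
  out
}

# position of the long-range resection front (kb from the cut site) at
# absolute time t; 0 until the Rad52 focus is visible
front_kb <- function(t, event) {
  if (!isTRUE(event$is_cut) || t < event$rad52_visible_time_min) return(0)
  event$true_rate_kb_per_hr * (t - event$rad52_visible_time_min) / 60
}

# double-stranded fraction of the LacO array remaining at time t
ds_fraction <- function(t, event, geometry) {
  f <- front_kb(t, event)
  if (f <= geometry$hocs_to_array_kb) return(1)
  max(0, (geometry$total_distance_kb - f) / geometry$array_length_kb)
}

# pre-noise integrated focus intensities at frame index (0-based)
underlying_intensities <- function(frame0, event, config, geometry) {
  t <- frame0 * config$frame_interval_min
  bleach <- (1 - config$bleach_rate_per_frame)^frame0
  gfp <- config$gfp_intensity * bleach *
    (if (isTRUE(event$is_cut)) ds_fraction(t, event, geometry) else 1)
  mch <- 0
  if (isTRUE(event$is_cut) && t >= event$rad52_visible_time_min) {
    grow <- min(1, front_kb(t, event) / config$mcherry_plateau_kb)
    mch <- config$mcherry_intensity *
      (config$mcherry_floor + (1 - config$mcherry_floor) * grow)
  }
  c(gfp = gfp, mcherry = mch)
}

# discrete, sum-normalized 1-D Gaussian sampled at integer offsets from a
# (possibly fractional) center; sigma -> 0 degenerates to a delta
sampled_gauss <- function(n, center, sigma) {
  x <- seq_len(n)
  if (sigma < 1e-6) {
    k <- numeric(n); k[round(center)] <- 1; return(k)
  }
  k <- exp(-(x - center)^2 / (2 * sigma^2))
  k / sum(k)
}

# render one cell's (t, c, z, y, x) pre-noise block and its truth center
render_cell <- function(event, config, geometry, center_offset = c(0, 0, 0)) {
  nz <- config$z_slices; ny <- config$roi_px; nx <- config$roi_px
  nt <- config$n_frames
  cz <- (nz + 1) / 2 + center_offset[1]
  cy <- (ny + 1) / 2 + center_offset[2]
  cx <- (nx + 1) / 2 + center_offset[3]
  kz <- sampled_gauss(nz, cz, config$psf_sigma_z_slices)
  ky <- sampled_gauss(ny, cy, config$psf_sigma_xy_px)
  kx <- sampled_gauss(nx, cx, config$psf_sigma_xy_px)
  spot <- outer(kz, outer(ky, kx))           # sums to 1
  dim(spot) <- c(nz, ny, nx)
  block <- array(0, dim = c(nt, 2, nz, ny, nx))
  for (f in seq_len(nt)) {
    ints <- underlying_intensities(f - 1L, event, config, geometry)
    block[f, 1, , , ] <- config$cell_background[1] + ints[["gfp"]] * spot
    block[f, 2, , , ] <- config$cell_background[2] + ints[["mcherry"]] * spot
  }
  list(block = block, center_zyx = c(cz, cy, cx))
}

apply_camera <- function(block, config) {
  v <- as.numeric(block)
  if (config$shot_noise) v <- stats::rpois(length(v), v)
  if (config$camera_sd > 0) v <- v + stats::rnorm(length(v), 0, config$camera_sd)
  v <- pmax(0, v + config$camera_offset)
  array(v, dim = dim(block))
}

#' Render a two-channel time-lapse stack from simulated events
#'
#' Cells are placed on a square grid, one `roi_px` x `roi_px` tile each,
#' and rendered as static diffraction-limited foci: the GFP focus carries
#' the double-stranded fraction of the array times the photobleaching
#' decay; the Rad52-mCherry focus appears at its visibility time and grows
#' with the resected tract up to a plateau. Both are Gaussian-PSF spots on
#' a cellular background, then Poisson shot noise, Gaussian read noise and
#' the camera offset are applied.
#'
#' @param events A `truth_events` data frame from [simulate_events()].
#' @param config A [sim_config()].
#' @param geometry A [cassette_geometry()].
#' @param jitter_centers Place each focus at a random subpixel offset
#'   (up to +-0.5 px/slice)? Default TRUE.
#' @return A list: `stack` (an [image_stack()] with channels GFP,
#'   mCherry) and `truth` (the events plus each cell's tile bounds and
#'   true focus center, 1-based voxel coordinates).
#' @export
render_stack <- function(events, config, geometry = cassette_geometry(),
                         jitter_centers = TRUE) {
  stopifnot(inherits(config, "sim_config"), nrow(events) >= 1)
  geometry <- as_geometry(geometry)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- nrow(events)
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  ny <- nrow_grid * config$roi_px
  nx <- ncol_grid * config$roi_px
  data <- array(0, dim = c(config$n_frames, 2, config$z_slices, ny, nx))
  truth <- events
  truth$y0 <- truth$y1 <- truth$x0 <- truth$x1 <- NA_integer_
  truth$center_z <- truth$center_y <- truth$center_x <- NA_real_
  for (i in seq_len(n)) {
    off <- if (jitter_centers) stats::runif(3, -0.5, 0.5) else c(0, 0, 0)
    rc <- render_cell(events[i, ], config, geometry, off)
    gy <- (ceiling(i / ncol_grid) - 1L) * config$roi_px
    gx <- ((i - 1L) %% ncol_grid) * config$roi_px
    ys <- gy + seq_len(config$roi_px); xs <- gx + seq_len(config$roi_px)
    data[, , , ys, xs] <- rc$block
    truth$y0[i] <- ys[1]; truth$y1[i] <- ys[length(ys)]
    truth$x0[i] <- xs[1]; truth$x1[i] <- xs[length(xs)]
    truth$center_z[i] <- rc$center_zyx[1]
    truth$center_y[i] <- gy + rc$center_zyx[2]
    truth$center_x[i] <- gx + rc$center_zyx[3]
  }
  data <- apply_camera(data, config)
  stack <- image_stack(data,
                       pixel_size_xy_um = config$pixel_size_xy_um,
                       z_spacing_um = config$z_spacing_um,
                       frame_interval_min = config$frame_interval_min,
                       channel_names = c("GFP", "mCherry"))
  list(stack = stack, truth = truth)
}

# time at which the resection front passes a site `d` kb from the cut.
# Initiation creeps to the first ApoI site (0.168 kb) during the
# Rad52-visibility delay; beyond it the long-range front applies.
site_arrival_min <- function(d, cut_time, delay, rate, init_kb = 0.168) {
  if (d <= init_kb) cut_time + delay * d / init_kb
  else cut_time + delay + 60 * (d - init_kb) / rate
}

#' Simulate an ApoI-protection qPCR plate
#'
#' Draws a virtual cell population under `config` (cut fraction, cut
#' times, Rad52 delays, genotype rates), computes for each site/timepoint
#' the fraction of chromosomes whose resection front has passed the site,
#' and inverts the delta-delta-Cq protection model to generate Cq
#' quadruplets (ApoI/mock x target/control) with Gaussian Cq noise and a
#' random per-sample plate offset shared by the four wells' baselines.
#' Records for an amplicon spanning the HO cut site (locus `"hocs"`) track
#' cutting: its template is destroyed in cut cells.
#'
#' @param config A [sim_config()]; `n_cells` is the virtual population
#'   size (use thousands for smooth fractions).
#' @param site_distances_kb ApoI site distances from the HO cut site, kb.
#' @param timepoints_min Sampling times after induction, minutes.
#' @param geometry A [cassette_geometry()].
#' @param genotype Genotype label.
#' @param n_replicates Technical replicates per condition. Default 3.
#' @param efficiency Amplification efficiency (fold per cycle). Default 2.
#' @param cq_noise_sd SD of Gaussian Cq noise per well. Default 0.1.
#' @param background_protection Apparent protection in unresected samples
#'   (incomplete ApoI digestion). Default 0.03.
#' @return Long-format data frame: `genotype`, `time_min`, `site_kb`,
#'   `condition` ("ApoI"/"mock"), `locus` ("target"/"control"/"hocs"),
#'   `Cq`, `replicate`, with the true protected/cut fractions attached as
#'   attribute `"truth"`.
#' @export
simulate_qpcr_plate <- function(config,
                                site_distances_kb = c(0.168, 3, 13),
                                timepoints_min = seq(0, 300, by = 30),
                                geometry = cassette_geometry(),
                                genotype = "WT",
                                n_replicates = 3,
                                efficiency = 2,
                                cq_noise_sd = 0.1,
                                background_protection = 0.03) {
  stopifnot(length(site_distances_kb) >= 1, length(timepoints_min) >= 1,
            all(site_distances_kb > 0), efficiency > 1)
  geometry <- as_geometry(geometry)
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  n <- config$n_cells
  is_cut <- stats::runif(n) < config$cut_fraction
  cut_time <- stats::runif(n, 0, config$cut_time_window_min)
  delay <- stats::runif(n, config$rad52_delay_range_min[1],
                        config$rad52_delay_range_min[2])
  rate <- draw_rates(config$rate_model, n)
  base_cq_target <- 20; base_cq_control <- 18; base_cq_hocs <- 20
  rows <- list(); truth <- list()
  logE <- log(efficiency)
  noise <- function(k) if (cq_noise_sd > 0) stats::rnorm(k, 0, cq_noise_sd) else numeric(k)
  for (t in timepoints_min) {
    cut_now <- is_cut & cut_time <= t
    for (d in site_distances_kb) {
      passed <- cut_now & site_arrival_min(d, cut_time, delay, rate) <= t
      p_prot <- mean(passed)
      survive <- background_protection + (1 - background_protection) * p_prot
      for (r in seq_len(n_replicates)) {
        off <- stats::rnorm(1, 0, 0.3)   # shared plate/sample offset
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = genotype, time_min = t, site_kb = d,
          condition = c("ApoI", "mock", "ApoI", "mock"),
          locus = c("target", "target", "control", "control"),
          Cq = c(base_cq_target + off - log(survive) / logE + noise(1),
                 base_cq_target + off + noise(1),
                 base_cq_control + off + noise(1),
                 base_cq_control + off + noise(1)),
          replicate = r, stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        genotype = genotype, time_min = t, site_kb = d,
        true_protected_fraction = p_prot, true_cut_fraction = mean(cut_now))
    }
    # HOcs-spanning amplicon: cut chromosomes do not amplify
    frac_cut <- mean(cut_now)
    for (r in seq_len(n_replicates)) {
      off <- stats::rnorm(1, 0, 0.3)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = genotype, time_min = t, site_kb = NA_real_,
        condition = "mock",
        locus = c("hocs", "control"),
        Cq = c(base_cq_hocs + off - log(max(1 - frac_cut, 1e-6)) / logE + noise(1),
               base_cq_control + off + noise(1)),
        replicate = r, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}
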