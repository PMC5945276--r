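# shared fixture builders; everything is generated in code

# a stack holding one (z, y, x) volume in one channel
vol_stack <- function(vol, frame_interval_min = 10, channels = "GFP") {
  d <- dim(vol)
  data <- array(vol, dim = c(1, 1, d))
  image_stack(data, pixel_size_xy_um = 0.16, z_spacing_um = 0.26,
              frame_interval_min = frame_interval_min,
              channel_names = channels)
}

# render a Gaussian spot of integrated intensity I at a subpixel center
# onto a constant background
gauss_spot_vol <- function(dim_zyx, center_zyx, I, sigma_z, sigma_xy,
                           background = 0) {
  g1 <- function(n, c0, s) {
    k <- exp(-((seq_len(n) - c0)^2) / (2 * s^2))
    k / sum(k)
  }
  kz <- g1(dim_zyx[1], center_zyx[1], sigma_z)
  ky <- g1(dim_zyx[2], center_zyx[2], sigma_xy)
  kx <- g1(dim_zyx[3], center_zyx[3], sigma_xy)
  spot <- outer(kz, outer(ky, kx))
  dim(spot) <- dim_zyx
  background + I * spot
}

# independent brute-force cylinder/shell photometry: explicit loop over
# every voxel, membership by center-of-voxel distance
brute_force_cylinder <- function(vol, center_zyx, params) {
  d <- dim(vol)
  cyl <- c(); shell <- c()
  r_in <- params$radius_px
  r_lo <- params$radius_px + params$shell_gap_px
  r_hi <- r_lo + params$shell_width_px
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (abs(z - center_zyx[1]) > params$half_height_slices) next
    r <- sqrt((y - center_zyx[2])^2 + (x - center_zyx[3])^2)
    if (r <= r_in) cyl <- c(cyl, vol[z, y, x])
    else if (r > r_lo && r <= r_hi) shell <- c(shell, vol[z, y, x])
  }
  sum(cyl) - length(cyl) * median(shell)
}

# a focus_trace scaffold with prescribed detection/intensity patterns
toy_trace <- function(detected, intensity = NULL, y = 10, x = 10,
                      frame_interval_min = 10, shell_mad = 1,
                      n_voxels = 100) {
  n <- length(detected)
  if (is.null(intensity)) intensity <- ifelse(detected, 1000, 0)
  data.frame(frame = seq_len(n) - 1L,
             time_min = (seq_len(n) - 1L) * frame_interval_min,
             channel = "GFP", z = 13, y = rep_len(y, n), x = rep_len(x, n),
             intensity = intensity, background = 0,
             shell_mad = shell_mad, n_voxels = n_voxels,
             detected = detected, stringsAsFactors = FALSE)
}

# noiseless, deterministic simulator settings for closed-form checks
noiseless_config <- function(...) {
  sim_config(shot_noise = FALSE, camera_sd = 0, camera_offset = 0,
             cell_background = c(0, 0), ...)
}
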