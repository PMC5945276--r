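#' On-target co-localization test
#'
#' Many Rad52 foci arise from spontaneous damage elsewhere in the genome,
#' so only Rad52 foci that co-localize with the LacO/LacI-GFP focus in at
#' least `min_frames` frames (default 2) count as the induced break.
#'
#' @param gfp_trace,rad52_trace `focus_trace` data frames sharing a frame
#'   grid.
#' @param max_dist_px Maximum xy center distance counted as co-localized.
#'   Default 3.
#' @param min_frames Minimum number of co-localized frames (with both foci
#'   detected). Default 2.
#' @return Logical flag.
#' @export
call_on_target <- function(gfp_trace, rad52_trace, max_dist_px = 3,
                           min_frames = 2) {
  if (nrow(gfp_trace) != nrow(rad52_trace) ||
      any(gfp_trace$frame != rad52_trace$frame))
    stop("traces must share the same frame grid", call. = FALSE)
  both <- gfp_trace$detected & rad52_trace$detected
  d <- sqrt((gfp_trace$y - rad52_trace$y)^2 +
            (gfp_trace$x - rad52_trace$x)^2)
  sum(both & d <= max_dist_px) >= min_frames
}

# first index starting a run of >= k TRUEs, or NA
first_sustained <- function(flags, k) {
  n <- length(flags)
  if (k <= 1L) return(if (any(flags)) which(flags)[1] else NA_integer_)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (flags[i]) run + 1L else 0L
    if (run >= k) return(i - k + 1L)
  }
  NA_integer_
}

#' Rad52 focus onset frame
#'
#' The resection start point: the first frame with a detected Rad52 focus,
#' where detection is sustained for at least `persistence_frames`
#' consecutive frames to suppress single-frame noise.
#'
#' @param rad52_trace A `focus_trace` data frame.
#' @param persistence_frames Consecutive detections required. Default 2.
#' @return 0-based frame index, or `NA` when no sustained focus appears.
#' @export
call_rad52_onset <- function(rad52_trace, persistence_frames = 2) {
  if (nrow(rad52_trace) == 0L) stop("empty trace", call. = FALSE)
  i <- first_sustained(rad52_trace$detected, persistence_frames)
  if (is.na(i)) NA_integer_ else rad52_trace$frame[i]
}

#' GFP focus loss frame (with censoring)
#'
#' The resection end point: the first frame at which the
#' background-subtracted GFP intensity falls below a noise-floor
#' threshold and is never again contradicted by a *detected* focus at or
#' above the threshold. The irreversibility guard absorbs single-frame
#' dropouts and transient mitotic dips, in which a detectable focus
#' recovers; a later above-threshold photometric reading without a
#' detected focus is a noise excursion and does not revoke the loss
#' (with ~30 frames, even a 3-sigma threshold is crossed by noise in a
#' few percent of cells). The threshold is `k` times
#' the noise floor of the integrated measurement at an empty location,
#' derived from the robust per-voxel shell SD: the cylinder sum
#' contributes `sqrt(n_cyl) * sd` and the subtracted background
#' (`n_cyl` times the shell median, whose SE is `sqrt(pi/2) *
#' sd / sqrt(n_shell)`) contributes `n_cyl * sqrt(pi/2 / n_shell) * sd`,
#' added in quadrature.
#'
#' @param gfp_trace A `focus_trace` data frame.
#' @param k Threshold multiplier. Default 3.
#' @return List: `loss_frame` (0-based, `NA` when censored), `censored`,
#'   `threshold`.
#' @export
call_gfp_loss <- function(gfp_trace, k = 3) {
  if (nrow(gfp_trace) == 0L) stop("empty trace", call. = FALSE)
  ok <- is.finite(gfp_trace$shell_mad) & is.finite(gfp_trace$n_voxels)
  n_cyl <- stats::median(gfp_trace$n_voxels[ok])
  n_shell <- if ("n_shell" %in% names(gfp_trace))
    stats::median(gfp_trace$n_shell[ok]) else Inf
  thr <- k * stats::median(gfp_trace$shell_mad[ok]) *
    sqrt(n_cyl + n_cyl^2 * (pi / 2) / n_shell)
  below <- !is.na(gfp_trace$intensity) & gfp_trace$intensity < thr
  # a loss call is contradicted only by later evidence of a real focus: a
  # frame that is both detected and at/above the threshold; an undetected
  # above-threshold photometric excursion is noise, not recovery
  contradicts <- !below & gfp_trace$detected
  idx <- NA_integer_
  for (i in rev(seq_len(nrow(gfp_trace)))) {
    if (contradicts[i]) break
    idx <- i
  }
  if (!is.na(idx)) {
    cand <- which(below & seq_along(below) >= idx)
    idx <- if (length(cand)) cand[1] else NA_integer_
  }
  if (is.na(idx))
    list(loss_frame = NA_integer_, censored = TRUE, threshold = thr)
  else
    list(loss_frame = gfp_trace$frame[idx], censored = FALSE, threshold = thr)
}

#' Assemble a resection event from a cell's trace pair
#'
#' Applies the on-target filter, onset and loss calls, and computes the
#' duration (loss frame minus onset frame, times the frame interval) or
#' the censored observation window.
#'
#' @param gfp_trace,rad52_trace `focus_trace` data frames for one cell.
#' @param cell_id,genotype Labels carried into the event record.
#' @param frame_interval_min Minutes per frame.
#' @param max_dist_px,min_frames On-target co-localization parameters.
#' @param persistence_frames Rad52 onset persistence.
#' @param k GFP-loss threshold multiplier.
#' @return One-row data frame (`cell_id`, `genotype`, `on_target`,
#'   `rad52_onset_frame`, `gfp_loss_frame`, `duration_min`, `censored`,
#'   `observed_window_min`), or a row with `on_target = FALSE` and `NA`
#'   event fields when no on-target event exists.
#' @export
call_event <- function(gfp_trace, rad52_trace, cell_id, genotype,
                       frame_interval_min, max_dist_px = 3, min_frames = 2,
                       persistence_frames = 2, k = 3) {
  empty <- data.frame(cell_id = cell_id, genotype = genotype,
                      on_target = FALSE,
                      rad52_onset_frame = NA_integer_,
                      gfp_loss_frame = NA_integer_,
                      duration_min = NA_real_, censored = NA,
                      observed_window_min = NA_real_,
                      stringsAsFactors = FALSE)
  onset <- call_rad52_onset(rad52_trace, persistence_frames)
  if (is.na(onset)) return(empty)
  if (!call_on_target(gfp_trace, rad52_trace, max_dist_px, min_frames))
    return(empty)
  loss <- call_gfp_loss(gfp_trace, k)
  last_frame <- max(gfp_trace$frame)
  window <- (last_frame - onset) * frame_interval_min
  if (loss$censored || loss$loss_frame <= onset) {
    data.frame(cell_id = cell_id, genotype = genotype, on_target = TRUE,
               rad52_onset_frame = onset, gfp_loss_frame = NA_integer_,
               duration_min = NA_real_, censored = TRUE,
               observed_window_min = window, stringsAsFactors = FALSE)
  } else {
    data.frame(cell_id = cell_id, genotype = genotype, on_target = TRUE,
               rad52_onset_frame = onset, gfp_loss_frame = loss$loss_frame,
               duration_min = (loss$loss_frame - onset) * frame_interval_min,
               censored = FALSE, observed_window_min = window,
               stringsAsFactors = FALSE)
  }
}

#' Photobleaching control on uncut cells
#'
#' GFP focus disappearance must reflect resection, not photobleaching.
#' Cells without an induced DSB (the large majority under a ~15% cut
#' fraction) keep their LacO/LacI-GFP focus; this control applies the
#' GFP-loss criterion to uncut traces and flags the dataset when the
#' false-loss fraction exceeds a tolerance.
#'
#' @param uncut_traces List of `focus_trace` data frames (GFP channel)
#'   from cells without induced DSBs.
#' @param k GFP-loss threshold multiplier. Default 3.
#' @param tolerance Maximum acceptable false-loss fraction. Default 0.05.
#' @return Object of class `photobleach_control`: `n`, `n_lost`,
#'   `fraction_lost`, `flagged`. With no uncut traces the control is
#'   skipped with a warning (`n = 0`, `flagged = NA`).
#' @export
photobleach_control <- function(uncut_traces, k = 3, tolerance = 0.05) {
  if (length(uncut_traces) == 0L) {
    warning("no uncut cells available; photobleach control skipped")
    return(structure(list(n = 0L, n_lost = NA_integer_,
                          fraction_lost = NA_real_, flagged = NA,
                          tolerance = tolerance),
                     class = "photobleach_control"))
  }
  lost <- vapply(uncut_traces, function(tr) !call_gfp_loss(tr, k)$censored,
                 logical(1))
  frac <- mean(lost)
  flagged <- frac > tolerance
  if (flagged)
    warning(sprintf(paste0("photobleaching control failed: %.1f%% of uncut ",
                           "cells lost their GFP focus (tolerance %.1f%%)"),
                    100 * frac, 100 * tolerance))
  structure(list(n = length(lost), n_lost = sum(lost), fraction_lost = frac,
                 flagged = flagged, tolerance = tolerance),
            class = "photobleach_control")
}

#' @export
print.photobleach_control <- function(x, ...) {
  cat("Photobleaching control (uncut cells)\n")
  if (x$n == 0L) {
    cat("  skipped: no uncut cells\n")
  } else {
    cat(sprintf("  %d / %d uncut cells lost the GFP focus (%.1f%%)\n",
                x$n_lost, x$n, 100 * x$fraction_lost))
    cat(sprintf("  dataset %s (tolerance %.1f%%)\n",
                if (x$flagged) "FLAGGED" else "passes",
                100 * x$tolerance))
  }
  invisible(x)
}

#' Blind and randomize a field manifest for scoring
#'
#' Shuffles the order of imaging fields across genotypes and replaces
#' identifying names with opaque IDs, so manual or semi-manual scoring is
#' blinded; a key file maps back. Deterministic for a fixed seed, and
#' contrast metadata is fixed identically for every image.
#'
#' @param manifest Data frame with at least `field_id` (unique) and
#'   `genotype`.
#' @param seed Integer seed for the permutation.
#' @return List: `blinded` (data frame `blind_id`, `contrast`, plus any
#'   non-identifying columns) and `key` (data frame `blind_id`,
#'   `field_id`, `genotype`, in original order).
#' @export
blind_and_randomize <- function(manifest, seed) {
  stopifnot(is.data.frame(manifest),
            all(c("field_id", "genotype") %in% names(manifest)))
  if (anyDuplicated(manifest$field_id))
    stop("duplicate field_id in manifest", call. = FALSE)
  n <- nrow(manifest)
  set.seed(seed)
  perm <- sample.int(n)
  blind_id <- sprintf("B%04d", seq_len(n))
  key <- data.frame(blind_id = blind_id,
                    field_id = manifest$field_id[perm],
                    genotype = manifest$genotype[perm],
                    stringsAsFactors = FALSE)
  blinded <- data.frame(blind_id = blind_id,
                        contrast = "fixed",
                        stringsAsFactors = FALSE)
  list(blinded = blinded, key = key)
}

#' Reverse a blinding
#'
#' @param blinded The blinded manifest from [blind_and_randomize()].
#' @param key The corresponding key.
#' @return Data frame `field_id`, `genotype` restored, sorted by
#'   `field_id`.
#' @export
unblind <- function(blinded, key) {
  m <- merge(blinded, key, by = "blind_id")
  out <- m[order(m$field_id), c("field_id", "genotype")]
  rownames(out) <- NULL
  out
}

#' Write called events to CSV
#'
#' @param events Event data frame (rows from [call_event()]).
#' @param path Output CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
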