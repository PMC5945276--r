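#' Five-dimensional image stack container
#'
#' A time-lapse fluorescence acquisition: a numeric array ordered
#' (time, channel, z, y, x) plus the calibration needed downstream
#' (xy pixel size, z spacing, frame interval, channel names). All focus
#' quantification operates on these full Z-stacks, never on projections.
#'
#' @param data 5-dimensional numeric array, axes (t, c, z, y, x),
#'   intensities in counts (all >= 0).
#' @param pixel_size_xy_um Lateral pixel size in micrometres.
#' @param z_spacing_um Axial step between Z-sections in micrometres.
#' @param frame_interval_min Time between frames in minutes.
#' @param channel_names Character vector, one label per channel
#'   (e.g. `c("GFP", "mCherry")`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_xy_um, z_spacing_um,
                        frame_interval_min, channel_names) {
  if (!is.array(data) || length(dim(data)) != 5L)
    stop("'data' must be a 5-dimensional array (t, c, z, y, x)",
         call. = FALSE)
  if (any(dim(data) < 1L)) stop("all axes must have size >= 1", call. = FALSE)
  if (any(data < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (length(channel_names) != dim(data)[2])
    stop("need one channel name per channel axis entry", call. = FALSE)
  for (v in c(pixel_size_xy_um = pixel_size_xy_um,
              z_spacing_um = z_spacing_um,
              frame_interval_min = frame_interval_min))
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("calibration fields must be single positive numbers",
           call. = FALSE)
  structure(
    list(data = data,
         pixel_size_xy_um = pixel_size_xy_um,
         z_spacing_um = z_spacing_um,
         frame_interval_min = frame_interval_min,
         channel_names = as.character(channel_names)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_stack: %d frames x %d channels (%s) x %d z x %d y x %d x\n",
    d[1], d[2], paste(x$channel_names, collapse = ", "), d[3], d[4], d[5]))
  cat(sprintf("  pixel %g um, z step %g um, frame interval %g min\n",
              x$pixel_size_xy_um, x$z_spacing_um, x$frame_interval_min))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
  } else {
    ch <- match(channel, stack$channel_names)
  }
  if (is.na(ch) || ch < 1L || ch > dim(stack$data)[2])
    stop("unknown channel: ", channel, call. = FALSE)
  ch
}

# one (z, y, x) volume
frame_volume <- function(stack, channel, frame) {
  d <- dim(stack$data)
  if (frame < 1L || frame > d[1]) stop("frame out of range", call. = FALSE)
  ch <- channel_index(stack, channel)
  vol <- stack$data[frame, ch, , , , drop = FALSE]
  dim(vol) <- d[3:5]
  vol
}

#' Write / read an image stack as multi-page TIFF with a sidecar
#'
#' Pages are written in t-major, then channel, then z order; the sidecar
#' YAML (`<path>.meta.yaml`) records the axis order, dimensions,
#' calibration, channel names and the count scale used for the 16-bit
#' encoding, so `read_stack()` restores the stack exactly (intensities are
#' rounded to integer counts on write).
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  counts <- round(stack$data)
  scale <- max(counts, 1)
  pages <- vector("list", d[1] * d[2] * d[3])
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- matrix(counts[t, ch, z, , ] / scale, d[4], d[5])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(axes = "TCZYX",
               shape = as.integer(d),
               pixel_size_xy_um = stack$pixel_size_xy_um,
               z_spacing_um = stack$z_spacing_um,
               frame_interval_min = stack$frame_interval_min,
               channel_names = as.list(stack$channel_names),
               count_scale = scale)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  d <- as.integer(unlist(meta$shape))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != d[1] * d[2] * d[3])
    stop("TIFF page count does not match sidecar shape", call. = FALSE)
  data <- array(0, dim = d)
  i <- 0L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    i <- i + 1L
    # writeTIFF quantizes [0,1] to 16-bit; undo the count scale exactly
    data[t, ch, z, , ] <- round(pages[[i]] * meta$count_scale)
  }
  image_stack(data,
              pixel_size_xy_um = meta$pixel_size_xy_um,
              z_spacing_um = meta$z_spacing_um,
              frame_interval_min = meta$frame_interval_min,
              channel_names = unlist(meta$channel_names))
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")
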