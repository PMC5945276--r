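#' Fluorescence-to-molecule-count calibration
#'
#' A reference focus of known stoichiometry - the spindle-pole-body
#' protein Sad1, whose single focus contains between 450 and 1030
#' molecules - anchors the conversion from background-subtracted focus
#' intensity to an approximate molecule count, provided the reference was
#' imaged with identical parameters. Because the reference copy number is
#' only known as a range, conversions are intervals, not point estimates.
#' A molecule count converts onward to a minimum resected ssDNA tract:
#' each loaded molecule covers `nt_per_molecule` nt and in G2 the
#' molecules are shared between `n_sisters` sister chromatids.
#'
#' @param reference_intensity Background-subtracted integrated intensity
#'   of the reference focus, in counts.
#' @param reference_molecule_range `(low, high)` molecule copies at the
#'   reference focus. Default `c(450, 1030)`.
#' @param nt_per_molecule nt of ssDNA covered per loaded molecule.
#'   Default 6 (the footprint is contested, so this is configuration, not
#'   a constant).
#' @param n_sisters Sister chromatids sharing the loaded molecules in G2.
#'   Default 2.
#' @param imaging_meta Optional named list of imaging parameters recorded
#'   with the reference (exposure, power, ...); conversions assert that
#'   the sample was imaged identically.
#' @return Object of class `intensity_calibration` with the derived
#'   `intensity_per_molecule_range`.
#' @export
intensity_calibration <- function(reference_intensity,
                                  reference_molecule_range = c(450, 1030),
                                  nt_per_molecule = 6,
                                  n_sisters = 2,
                                  imaging_meta = NULL) {
  stopifnot(is.numeric(reference_intensity), reference_intensity > 0,
            length(reference_molecule_range) == 2,
            all(reference_molecule_range > 0),
            reference_molecule_range[1] <= reference_molecule_range[2],
            nt_per_molecule > 0, n_sisters >= 1)
  structure(list(
    reference_intensity = reference_intensity,
    reference_molecule_range = reference_molecule_range,
    intensity_per_molecule_range =
      c(reference_intensity / reference_molecule_range[2],
        reference_intensity / reference_molecule_range[1]),
    nt_per_molecule = nt_per_molecule,
    n_sisters = n_sisters,
    imaging_meta = imaging_meta),
    class = "intensity_calibration")
}

#' @export
print.intensity_calibration <- function(x, ...) {
  cat("Intensity calibration\n")
  cat(sprintf("  reference: %g counts for %g-%g molecules\n",
              x$reference_intensity, x$reference_molecule_range[1],
              x$reference_molecule_range[2]))
  cat(sprintf("  counts per molecule: %.3g-%.3g\n",
              x$intensity_per_molecule_range[1],
              x$intensity_per_molecule_range[2]))
  cat(sprintf("  %g nt ssDNA per molecule, %d sister(s)\n",
              x$nt_per_molecule, x$n_sisters))
  invisible(x)
}

assert_imaging_match <- function(cal, imaging_meta) {
  if (is.null(cal$imaging_meta) || is.null(imaging_meta)) return(invisible())
  common <- intersect(names(cal$imaging_meta), names(imaging_meta))
  for (k in common)
    if (!identical(cal$imaging_meta[[k]], imaging_meta[[k]]))
      stop("imaging parameter '", k, "' differs from the calibration ",
           "reference; molecule counts require identical imaging",
           call. = FALSE)
  invisible()
}

#' Molecule-count interval from a focus intensity
#'
#' @param intensity Background-subtracted integrated intensity (counts).
#' @param cal An [intensity_calibration()].
#' @param imaging_meta Optional imaging parameters of the measured sample;
#'   any mismatch with the calibration reference is a hard error.
#' @return Numeric `(low, high)` molecule estimate; `intensity <= 0`
#'   returns `c(NA, NA)` with a warning.
#' @export
molecules_from_intensity <- function(intensity, cal, imaging_meta = NULL) {
  stopifnot(inherits(cal, "intensity_calibration"))
  assert_imaging_match(cal, imaging_meta)
  if (!is.finite(intensity) || intensity <= 0) {
    warning("non-positive intensity: molecule count undefined")
    return(c(low = NA_real_, high = NA_real_))
  }
  c(low = intensity / cal$intensity_per_molecule_range[2],
    high = intensity / cal$intensity_per_molecule_range[1])
}

#' Minimum resected ssDNA per sister from a molecule count
#'
#' @param molecules Loaded molecule count (e.g. the ~30 copies at the
#'   focus-visibility threshold).
#' @param cal An [intensity_calibration()].
#' @return Lower bound on the resected tract per sister chromatid, nt.
#' @export
min_resected_nt <- function(molecules, cal) {
  stopifnot(inherits(cal, "intensity_calibration"))
  if (!is.numeric(molecules) || any(!is.finite(molecules)) ||
      any(molecules <= 0))
    stop("'molecules' must be positive", call. = FALSE)
  (molecules / cal$n_sisters) * cal$nt_per_molecule
}

#' Read / write a calibration as a plain key-value file
#'
#' @param path File path.
#' @return `read_calibration` returns an [intensity_calibration()];
#'   `write_calibration` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  kv <- read_keyvalue(path)
  need <- c("reference_intensity", "reference_molecules_low",
            "reference_molecules_high", "nt_per_molecule", "n_sisters")
  if (!all(need %in% names(kv)))
    stop("calibration file must define: ", paste(need, collapse = ", "),
         call. = FALSE)
  intensity_calibration(
    reference_intensity = as.numeric(kv[["reference_intensity"]]),
    reference_molecule_range = c(as.numeric(kv[["reference_molecules_low"]]),
                                 as.numeric(kv[["reference_molecules_high"]])),
    nt_per_molecule = as.numeric(kv[["nt_per_molecule"]]),
    n_sisters = as.numeric(kv[["n_sisters"]]))
}

#' @rdname read_calibration
#' @param cal An [intensity_calibration()] to serialize.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "intensity_calibration"))
  writeLines(c(
    "# focus intensity -> molecule count calibration",
    sprintf("reference_intensity = %.10g", cal$reference_intensity),
    sprintf("reference_molecules_low = %.10g", cal$reference_molecule_range[1]),
    sprintf("reference_molecules_high = %.10g", cal$reference_molecule_range[2]),
    sprintf("nt_per_molecule = %.10g", cal$nt_per_molecule),
    sprintf("n_sisters = %.10g", cal$n_sisters)), path)
  invisible(path)
}
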