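#' Reporter-cassette geometry
#'
#' The assay converts resection durations into rates through the genomic
#' layout of the reporter: an HO endonuclease cut site (HOcs) separated by a
#' spacer from a LacO repeat array bound by LacI-GFP. Complete loss of the
#' GFP focus means the resection front has traversed the spacer plus the
#' full array, so the relevant distance is the sum of the two. The default
#' layout is a 3.57 kb spacer followed by a 10.3 kb array: 13.87 kb from
#' cut site to the distal array end.
#'
#' @param hocs_to_array_kb Distance in kb from the HO cut site to the
#'   proximal edge of the LacO array. Default 3.57.
#' @param array_length_kb Length of the LacO array in kb. Default 10.3.
#' @return An object of class `cassette_geometry` with fields
#'   `hocs_to_array_kb`, `array_length_kb` and the derived
#'   `total_distance_kb`.
#' @examples
#' geom <- cassette_geometry()
#' total_distance(geom)            # 13.87
#' duration_to_rate(150, geom)     # 5.548 kb/hr
#' @export
cassette_geometry <- function(hocs_to_array_kb = 3.57, array_length_kb = 10.3) {
  for (v in c(hocs_to_array_kb = hocs_to_array_kb,
              array_length_kb = array_length_kb)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("cassette geometry distances must be single positive numbers",
           call. = FALSE)
  }
  structure(
    list(hocs_to_array_kb = hocs_to_array_kb,
         array_length_kb = array_length_kb,
         total_distance_kb = hocs_to_array_kb + array_length_kb),
    class = "cassette_geometry")
}

#' @export
print.cassette_geometry <- function(x, ...) {
  cat("Reporter cassette geometry\n")
  cat(sprintf("  HOcs -> array edge : %g kb\n", x$hocs_to_array_kb))
  cat(sprintf("  LacO array length  : %g kb\n", x$array_length_kb))
  cat(sprintf("  total distance     : %g kb\n", x$total_distance_kb))
  invisible(x)
}

as_geometry <- function(geometry) {
  if (inherits(geometry, "cassette_geometry")) return(geometry)
  if (is.list(geometry) &&
      all(c("hocs_to_array_kb", "array_length_kb") %in% names(geometry)))
    return(cassette_geometry(geometry$hocs_to_array_kb,
                             geometry$array_length_kb))
  stop("'geometry' must be a cassette_geometry object", call. = FALSE)
}

#' Total cut-site-to-distal-array distance
#'
#' @param geometry A [cassette_geometry()] object.
#' @return Distance in kb from the HO cut site to the distal end of the
#'   LacO array.
#' @export
total_distance <- function(geometry = cassette_geometry()) {
  as_geometry(geometry)$total_distance_kb
}

#' Convert a resection duration into a rate
#'
#' The per-cell statistic of the assay: the time from the first frame with
#' an on-target Rad52 focus to the first frame with total loss of the
#' LacO/LacI-GFP focus spans resection of the full cut-site-to-distal-array
#' distance, so rate = distance / duration.
#'
#' Rates are returned at full precision; round only for display (the
#' conventional report format is 2 decimals).
#'
#' @param duration_min Duration(s) in minutes; must be > 0.
#' @param geometry A [cassette_geometry()] object.
#' @return Resection rate(s) in kb/hr.
#' @examples
#' round(duration_to_rate(c(150, 140)), 2)  # 5.55, 5.94
#' @export
duration_to_rate <- function(duration_min, geometry = cassette_geometry()) {
  geometry <- as_geometry(geometry)
  if (!is.numeric(duration_min) || any(!is.finite(duration_min)) ||
      any(duration_min <= 0))
    stop("'duration_min' must be positive and finite", call. = FALSE)
  geometry$total_distance_kb / (duration_min / 60)
}

#' Rate upper bound for a censored event
#'
#' An event whose GFP focus persists to the end of acquisition did not
#' finish resecting the reporter within the observed window, so its true
#' rate is at most distance / window. With the default geometry and a 5 hr
#' window this bound is ~2.8 kb/hr.
#'
#' @param acquisition_window_min Observed window in minutes (onset to last
#'   acquired frame); must be > 0.
#' @param geometry A [cassette_geometry()] object.
#' @return Upper bound(s) on the rate in kb/hr.
#' @export
censored_upper_bound <- function(acquisition_window_min,
                                 geometry = cassette_geometry()) {
  geometry <- as_geometry(geometry)
  if (!is.numeric(acquisition_window_min) ||
      any(!is.finite(acquisition_window_min)) ||
      any(acquisition_window_min <= 0))
    stop("'acquisition_window_min' must be positive and finite",
         call. = FALSE)
  geometry$total_distance_kb / (acquisition_window_min / 60)
}

#' Read / write a cassette geometry as a plain key-value file
#'
#' Format: one `key = value` pair per line; `#` starts a comment.
#' Recognized keys: `hocs_to_array_kb`, `array_length_kb`.
#'
#' @param path File path.
#' @return `read_geometry_config` returns a [cassette_geometry()];
#'   `write_geometry_config` returns `path` invisibly.
#' @export
read_geometry_config <- function(path) {
  kv <- read_keyvalue(path)
  need <- c("hocs_to_array_kb", "array_length_kb")
  if (!all(need %in% names(kv)))
    stop("geometry config must define: ", paste(need, collapse = ", "),
         call. = FALSE)
  cassette_geometry(as.numeric(kv[["hocs_to_array_kb"]]),
                    as.numeric(kv[["array_length_kb"]]))
}

#' @rdname read_geometry_config
#' @param geometry A [cassette_geometry()] object to serialize.
#' @export
write_geometry_config <- function(geometry, path) {
  geometry <- as_geometry(geometry)
  writeLines(c("# reporter cassette geometry (kb)",
               sprintf("hocs_to_array_kb = %.10g", geometry$hocs_to_array_kb),
               sprintf("array_length_kb = %.10g", geometry$array_length_kb)),
             path)
  invisible(path)
}

# parse "key = value" lines, ignoring blanks and comments
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("malformed key-value line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  vals <- vapply(parts, function(p) trimws(p[2]), "")
  names(vals) <- vapply(parts, function(p) trimws(p[1]), "")
  vals
}
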