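#' Quantify and call events for a rendered field
#'
#' Runs the focus-photometry and event-calling stages over every cell of
#' a rendered stack: builds GFP and mCherry traces inside each cell's
#' tile, then calls on-target status, Rad52 onset, GFP loss and
#' censoring.
#'
#' @param stack An [image_stack()] from [render_stack()].
#' @param truth The matching truth table (only the tile bounds and labels
#'   are used, never the event truth).
#' @param params A [cylinder_params()].
#' @param threshold_sd Detection threshold. Default 5.
#' @param k GFP-loss threshold multiplier. Default 3.
#' @param sigma_xy,sigma_z Detection band-pass scales.
#' @return List: `events` (one row per cell from [call_event()]) and
#'   `traces` (named list of per-cell `list(gfp, rad52)` traces).
#' @export
quantify_field <- function(stack, truth, params = cylinder_params(),
                           threshold_sd = 5, k = 3,
                           sigma_xy = 1.3, sigma_z = 1.5) {
  rows <- vector("list", nrow(truth))
  traces <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    roi <- list(y = c(truth$y0[i], truth$y1[i]),
                x = c(truth$x0[i], truth$x1[i]))
    gfp <- build_trace(stack, "GFP", roi, params, sigma_xy, sigma_z,
                       threshold_sd)
    mch <- build_trace(stack, "mCherry", roi, params, sigma_xy, sigma_z,
                       threshold_sd)
    rows[[i]] <- call_event(gfp, mch, truth$cell_id[i], truth$genotype[i],
                            stack$frame_interval_min, k = k)
    traces[[i]] <- list(gfp = gfp, rad52 = mch)
  }
  names(traces) <- truth$cell_id
  list(events = do.call(rbind, rows), traces = traces)
}

#' Simulate, render and analyze cells one at a time
#'
#' Memory-friendly end-to-end driver: renders each simulated cell as its
#' own single-tile stack and runs [quantify_field()] on it, so arbitrarily
#' many cells can be processed without holding a full field in memory.
#'
#' @param events A `truth_events` data frame from [simulate_events()].
#' @param config The [sim_config()] used to simulate them.
#' @param geometry A [cassette_geometry()].
#' @param params,threshold_sd,k Passed to [quantify_field()].
#' @return Data frame of called events (one row per cell).
#' @export
analyze_simulated_cells <- function(events, config,
                                    geometry = cassette_geometry(),
                                    params = cylinder_params(),
                                    threshold_sd = 5, k = 3) {
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    one <- events[i, , drop = FALSE]
    cfg1 <- config
    cfg1$seed <- if (is.null(config$seed)) NULL else config$seed + i
    rend <- render_stack(one, cfg1, geometry)
    q <- quantify_field(rend$stack, rend$truth, params, threshold_sd, k,
                        sigma_xy = config$psf_sigma_xy_px,
                        sigma_z = config$psf_sigma_z_slices)
    rows[[i]] <- q$events
  }
  do.call(rbind, rows)
}

#' Default run configuration
#'
#' A serializable nested list tying all stage parameters together;
#' defaults equal the assay's acquisition settings (10 min frames, 25 z
#' at 0.26 um, 5 hr window) and the package's stage defaults.
#'
#' @param seed Integer seed.
#' @param genotypes Character vector of genotype names; each must match a
#'   model in [rate_models()].
#' @param n_cells Cells per genotype.
#' @return Nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L, genotypes = c("WT", "crb2d", "rev7d"),
                       n_cells = 10L) {
  structure(list(
    seed = as.integer(seed),
    geometry = list(hocs_to_array_kb = 3.57, array_length_kb = 10.3),
    simulation = list(n_cells = as.integer(n_cells),
                      genotypes = genotypes,
                      frame_interval_min = 10, n_frames = 31,
                      z_slices = 25, z_spacing_um = 0.26,
                      cut_fraction = 0.15),
    imaging = list(cylinder = list(radius_px = 2.5, half_height_slices = 3,
                                   shell_gap_px = 1, shell_width_px = 2),
                   detection_threshold_sd = 5,
                   sigma_xy = 1.3, sigma_z = 1.5),
    event_calling = list(max_dist_px = 3, min_frames = 2,
                         persistence_frames = 2, loss_k = 3),
    stats = list(var_equal = FALSE, alpha = 0.05)),
    class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path File path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(run_config())
  merge_cfg <- function(base, upd) {
    for (k in names(upd))
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
        merge_cfg(base[[k]], upd[[k]]) else upd[[k]]
    base
  }
  structure(merge_cfg(base, cfg), class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config` to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' End-to-end simulated run
#'
#' Simulates each configured genotype, renders and analyzes every cell,
#' fits the genotype rate table, and writes the per-cell event table, the
#' fit tables, a rate strip plot and a run log under `out_dir`.
#'
#' @param config A `run_config` (see [run_config()], [read_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @return The `resection_fit`, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geometry <- cassette_geometry(config$geometry$hocs_to_array_kb,
                                config$geometry$array_length_kb)
  models <- rate_models()
  params <- do.call(cylinder_params, config$imaging$cylinder)
  all_events <- list()
  for (gi in seq_along(config$simulation$genotypes)) {
    g <- config$simulation$genotypes[gi]
    if (!g %in% names(models))
      stop("no rate model for genotype: ", g, call. = FALSE)
    sc <- sim_config(n_cells = config$simulation$n_cells,
                     frame_interval_min = config$simulation$frame_interval_min,
                     n_frames = config$simulation$n_frames,
                     z_slices = config$simulation$z_slices,
                     z_spacing_um = config$simulation$z_spacing_um,
                     cut_fraction = config$simulation$cut_fraction,
                     rate_model = models[[g]],
                     seed = config$seed + 1000L * gi)
    truth <- simulate_events(sc, geometry, genotype = g)
    all_events[[g]] <- analyze_simulated_cells(
      truth, sc, geometry, params,
      threshold_sd = config$imaging$detection_threshold_sd,
      k = config$event_calling$loss_k)
  }
  events <- do.call(rbind, all_events)
  write_events(events, file.path(out_dir, "events.csv"))
  fit <- resection_fit(events, geometry,
                       var_equal = config$stats$var_equal,
                       alpha = config$stats$alpha)
  write_fit(fit, file.path(out_dir, "rates"))
  grDevices::png(file.path(out_dir, "rates.png"), width = 640, height = 480)
  ok <- try(plot(fit), silent = TRUE)
  grDevices::dev.off()
  write_run_config(config, file.path(out_dir, "config.yaml"))
  writeLines(c(sprintf("resectr %s", as.character(utils::packageVersion("resectr"))),
               sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("seed: %d", config$seed),
               sprintf("cells: %d x %d genotypes",
                       config$simulation$n_cells,
                       length(config$simulation$genotypes))),
             file.path(out_dir, "run.log"))
  invisible(fit)
}
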