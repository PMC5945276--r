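#' Fit per-cell resection rates by genotype
#'
#' The central estimator of the assay. Uncensored events (Rad52 onset to
#' complete GFP focus loss observed) are converted to rates through
#' [duration_to_rate()]; censored events (focus persists to the end of
#' acquisition) are converted to rate upper bounds through
#' [censored_upper_bound()] and never enter medians or tests - they are
#' reported descriptively, and a genotype with a majority of censored
#' events is reported as not determinable ("N.D."). Genotypes are compared
#' with pairwise two-tailed t-tests with Bonferroni correction, the family
#' being the set of pairs actually tested in the call.
#'
#' @param events Data frame of called events with columns `cell_id`,
#'   `genotype`, `duration_min`, `censored`, `observed_window_min`
#'   (rows from [call_event()]; rows with `on_target == FALSE` or missing
#'   event fields are dropped).
#' @param geometry A [cassette_geometry()].
#' @param pairs List of length-2 character vectors naming genotype pairs
#'   to test; `NULL` (default) tests all pairs of genotypes with at least
#'   2 uncensored rates.
#' @param var_equal Use Student's pooled-variance t-test instead of the
#'   default Welch test.
#' @param alpha Significance level on the adjusted p. Default 0.05.
#' @return Object of class `resection_fit`: `rates` (per-cell table with
#'   `genotype`, `cell_id`, `rate_kb_hr`, `upper_bound_kb_hr`,
#'   `censored`), `summary` (per genotype: `n`, `n_censored`, `median`,
#'   `nd`), `comparisons` (per pair: `t`, `df`, `p_raw`, `p_adj`, `m`,
#'   `significant`), `geometry`.
#' @examples
#' ev <- data.frame(cell_id = c("a", "b"), genotype = "WT",
#'                  on_target = TRUE, duration_min = c(150, 140),
#'                  censored = FALSE, observed_window_min = 300)
#' fit <- resection_fit(ev)
#' coef(fit)  # median rate
#' @export
resection_fit <- function(events, geometry = cassette_geometry(),
                          pairs = NULL, var_equal = FALSE, alpha = 0.05) {
  geometry <- as_geometry(geometry)
  stopifnot(is.data.frame(events))
  need <- c("cell_id", "genotype", "duration_min", "censored",
            "observed_window_min")
  if (nrow(events) > 0 && !all(need %in% names(events)))
    stop("events must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if ("on_target" %in% names(events))
    events <- events[!is.na(events$on_target) & events$on_target, ,
                     drop = FALSE]
  if (nrow(events) > 0)
    events <- events[!is.na(events$censored), , drop = FALSE]
  if (nrow(events) == 0L) {
    fit <- list(rates = data.frame(genotype = character(),
                                   cell_id = character(),
                                   rate_kb_hr = numeric(),
                                   upper_bound_kb_hr = numeric(),
                                   censored = logical()),
                summary = data.frame(genotype = character(), n = integer(),
                                     n_censored = integer(),
                                     median = numeric(), nd = logical()),
                comparisons = empty_comparisons(),
                geometry = geometry, alpha = alpha)
    class(fit) <- "resection_fit"
    return(fit)
  }
  rates <- data.frame(
    genotype = events$genotype,
    cell_id = events$cell_id,
    rate_kb_hr = ifelse(events$censored, NA_real_,
                        duration_to_rate_safe(events$duration_min, geometry)),
    upper_bound_kb_hr = ifelse(
      events$censored,
      censored_upper_bound_safe(events$observed_window_min, geometry),
      NA_real_),
    censored = events$censored,
    stringsAsFactors = FALSE)
  gsplit <- split(rates, rates$genotype)
  summ <- do.call(rbind, lapply(names(gsplit), function(g) {
    r <- gsplit[[g]]
    unc <- r$rate_kb_hr[!r$censored]
    nd <- sum(r$censored) > length(unc)    # majority censored
    data.frame(genotype = g,
               n = length(unc),
               n_censored = sum(r$censored),
               median = if (nd || length(unc) == 0L) NA_real_
                        else stats::median(unc),
               nd = nd, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  fit <- list(rates = rates, summary = summ,
              comparisons = empty_comparisons(), geometry = geometry,
              alpha = alpha)
  class(fit) <- "resection_fit"
  fit$comparisons <- pairwise_tests(fit, pairs = pairs,
                                    var_equal = var_equal, alpha = alpha)
  fit
}

duration_to_rate_safe <- function(d, geometry) {
  out <- rep(NA_real_, length(d))
  ok <- !is.na(d) & d > 0
  out[ok] <- duration_to_rate(d[ok], geometry)
  out
}

censored_upper_bound_safe <- function(w, geometry) {
  out <- rep(NA_real_, length(w))
  ok <- !is.na(w) & w > 0
  out[ok] <- censored_upper_bound(w[ok], geometry)
  out
}

empty_comparisons <- function() {
  data.frame(genotype_a = character(), genotype_b = character(),
             t = numeric(), df = numeric(), p_raw = numeric(),
             p_adj = numeric(), m = integer(), significant = logical(),
             stringsAsFactors = FALSE)
}

#' Pairwise genotype t-tests with Bonferroni correction
#'
#' Two-sample two-tailed t-tests on uncensored rates, with the adjusted
#' p-value `min(1, p * m)`, `m` being the number of pairs actually tested
#' in this call. Pairs with fewer than 2 uncensored rates on either side
#' are skipped with a notice (and do not count toward `m`).
#'
#' @param fit A `resection_fit` object.
#' @param pairs List of length-2 character vectors; `NULL` tests all
#'   eligible pairs.
#' @param var_equal Student's pooled-variance test instead of Welch.
#' @param alpha Significance level on the adjusted p.
#' @return Data frame of comparison records (one per tested pair).
#' @export
pairwise_tests <- function(fit, pairs = NULL, var_equal = FALSE,
                           alpha = 0.05) {
  stopifnot(inherits(fit, "resection_fit"))
  rates <- fit$rates[!fit$rates$censored, , drop = FALSE]
  by_g <- split(rates$rate_kb_hr, rates$genotype)
  eligible <- names(by_g)[vapply(by_g, length, 1L) >= 2L]
  if (is.null(pairs)) {
    if (length(eligible) < 2L) return(empty_comparisons())
    pairs <- utils::combn(sort(eligible), 2, simplify = FALSE)
  }
  usable <- Filter(function(p) {
    ok <- all(p %in% eligible)
    if (!ok) message("skipping pair ", paste(p, collapse = " vs "),
                     ": fewer than 2 uncensored rates")
    ok
  }, pairs)
  m <- length(usable)
  if (m == 0L) return(empty_comparisons())
  rows <- lapply(usable, function(p) {
    tt <- stats::t.test(by_g[[p[1]]], by_g[[p[2]]],
                        alternative = "two.sided", var.equal = var_equal)
    data.frame(genotype_a = p[1], genotype_b = p[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adj = min(1, tt$p.value * m),
               m = m, significant = min(1, tt$p.value * m) < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.resection_fit <- function(x, ...) {
  cat("Single-cell long-range resection rates",
      sprintf("(reporter distance %.2f kb)\n", x$geometry$total_distance_kb))
  if (nrow(x$summary) == 0L) {
    cat("  <no events>\n")
    return(invisible(x))
  }
  s <- x$summary
  med <- ifelse(s$nd, "N.D.",
                ifelse(is.na(s$median), "-", sprintf("%.2f", s$median)))
  cat(sprintf("  %-10s n=%-4d censored=%-4d median=%s kb/hr\n",
              s$genotype, s$n, s$n_censored, med), sep = "")
  if (nrow(x$comparisons) > 0L) {
    cat(sprintf("Pairwise two-tailed t-tests, Bonferroni m = %d:\n",
                x$comparisons$m[1]))
    with(x$comparisons,
         cat(sprintf("  %s vs %s: t = %.3f, p = %.3g, adj p = %.3g%s\n",
                     genotype_a, genotype_b, t, p_raw, p_adj,
                     ifelse(significant, " *", "")), sep = ""))
  }
  invisible(x)
}

#' @export
summary.resection_fit <- function(object, ...) {
  structure(list(summary = object$summary,
                 comparisons = object$comparisons,
                 geometry = object$geometry),
            class = "summary.resection_fit")
}

#' @export
print.summary.resection_fit <- function(x, ...) {
  print(structure(list(summary = x$summary, comparisons = x$comparisons,
                       geometry = x$geometry),
                  class = "resection_fit"))
  invisible(x)
}

#' @export
coef.resection_fit <- function(object, ...) {
  stats::setNames(object$summary$median, object$summary$genotype)
}

#' Strip plot of single-cell rates with median bars
#'
#' One jittered column of points per genotype, a horizontal bar at each
#' determinable median, and censored events shown as open triangles at
#' their rate upper bounds.
#'
#' @param x A `resection_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.resection_fit <- function(x, ...) {
  r <- x$rates
  if (nrow(r) == 0L) stop("nothing to plot", call. = FALSE)
  gs <- x$summary$genotype
  gi <- match(r$genotype, gs)
  set.seed(1L)  # reproducible jitter only
  jx <- gi + stats::runif(nrow(r), -0.15, 0.15)
  yv <- ifelse(r$censored, r$upper_bound_kb_hr, r$rate_kb_hr)
  graphics::plot(jx, yv, xlim = c(0.5, length(gs) + 0.5),
                 ylim = c(0, max(yv, na.rm = TRUE) * 1.1),
                 xaxt = "n", xlab = "", ylab = "resection rate (kb/hr)",
                 pch = ifelse(r$censored, 2, 16),
                 col = ifelse(r$censored, "grey40", "black"), ...)
  graphics::axis(1, at = seq_along(gs), labels = gs)
  for (i in seq_along(gs)) {
    m <- x$summary$median[i]
    if (!is.na(m))
      graphics::segments(i - 0.25, m, i + 0.25, m, col = "red", lwd = 3)
    else
      graphics::text(i, 0, "N.D.", pos = 3, col = "red")
  }
  invisible(x)
}

#' Write fit tables to CSV
#'
#' Writes `<prefix>_rates.csv` (per-cell), `<prefix>_summary.csv`
#' (per-genotype; majority-censored genotypes carry median "N.D.") and
#' `<prefix>_comparisons.csv`.
#'
#' @param fit A `resection_fit`.
#' @param prefix Output path prefix.
#' @return Invisibly, the three paths.
#' @export
write_fit <- function(fit, prefix) {
  stopifnot(inherits(fit, "resection_fit"))
  p1 <- paste0(prefix, "_rates.csv")
  p2 <- paste0(prefix, "_summary.csv")
  p3 <- paste0(prefix, "_comparisons.csv")
  utils::write.csv(fit$rates, p1, row.names = FALSE)
  s <- fit$summary
  s$median <- ifelse(s$nd, "N.D.", format(s$median))
  utils::write.csv(s, p2, row.names = FALSE)
  utils::write.csv(fit$comparisons, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
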