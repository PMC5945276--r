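#' Read a long-format qPCR table
#'
#' Expected columns: `genotype`, `time_min`, `site_kb`, `condition`
#' ("ApoI" or "mock"), `locus` ("target", "control", or "hocs"), `Cq`,
#' `replicate`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "time_min", "site_kb", "condition", "locus", "Cq",
            "replicate")
  if (!all(need %in% names(df)))
    stop("qPCR table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' ApoI-protection fraction from Cq quadruplets
#'
#' ssDNA produced by resection is refractory to ApoI digestion, so the
#' surviving (amplifiable) fraction of target molecules after digestion
#' measures protection. Per sample the four wells are combined as
#' `dCq_target = Cq(ApoI, target) - Cq(mock, target)`, the same for the
#' control locus (no ApoI site; it normalizes digestion efficiency and
#' plate offsets), and `protection = efficiency^-(dCq_target -
#' dCq_control)`, clipped to `[0, 1]` with a flag when clipping occurred.
#'
#' @param records Long-format data frame as from [read_qpcr()] /
#'   [simulate_qpcr_plate()].
#' @param efficiency Amplification efficiency (fold per cycle). Default 2.
#' @return Data frame, one row per (genotype, time_min, site_kb,
#'   replicate): `ddCq`, `protection`, `clipped`. Samples with any of the
#'   four Cq values missing are skipped with a notice.
#' @export
protection_fraction <- function(records, efficiency = 2) {
  stopifnot(efficiency > 1)
  rec <- records[records$locus %in% c("target", "control") &
                   !is.na(records$site_kb), , drop = FALSE]
  keys <- unique(rec[, c("genotype", "time_min", "site_kb", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- rec[rec$genotype == k$genotype & rec$time_min == k$time_min &
                 rec$site_kb == k$site_kb & rec$replicate == k$replicate, ]
    cq <- function(cond, loc) {
      v <- sub$Cq[sub$condition == cond & sub$locus == loc]
      if (length(v) == 1L && is.finite(v)) v else NA_real_
    }
    quad <- c(cq("ApoI", "target"), cq("mock", "target"),
              cq("ApoI", "control"), cq("mock", "control"))
    if (anyNA(quad)) {
      message("skipping sample with incomplete Cq quadruplet: ",
              paste(unlist(k), collapse = "/"))
      return(NULL)
    }
    ddcq <- (quad[1] - quad[2]) - (quad[3] - quad[4])
    p <- efficiency^(-ddcq)
    clipped <- p < 0 || p > 1
    data.frame(genotype = k$genotype, time_min = k$time_min,
               site_kb = k$site_kb, replicate = k$replicate,
               ddCq = ddcq, protection = min(max(p, 0), 1),
               clipped = clipped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(genotype = character(), time_min = numeric(),
                      site_kb = numeric(), replicate = integer(),
                      ddCq = numeric(), protection = numeric(),
                      clipped = logical())
  out
}

#' Cut fraction over time from HOcs-spanning primers
#'
#' An amplicon spanning the HO cut site loses its template when the site
#' is cut, so the Cq shift relative to the first timepoint, normalized to
#' the control locus, measures the cut fraction:
#' `cut(t) = 1 - efficiency^-((Cq_t - Cq_t0) - (Cqc_t - Cqc_t0))`,
#' averaged over replicates.
#'
#' @param records Long-format data frame containing locus `"hocs"` rows
#'   and matching `"control"` rows (same `condition`/`replicate`).
#' @param efficiency Amplification efficiency. Default 2.
#' @return Data frame per (genotype, time_min): `cut_fraction` (clipped to
#'   `[0, 1]`). Errors if the first timepoint is absent.
#' @export
cut_fraction <- function(records, efficiency = 2) {
  rec <- records[records$locus %in% c("hocs", "control") &
                   is.na(records$site_kb), , drop = FALSE]
  if (!any(rec$locus == "hocs"))
    stop("no HOcs-spanning records found", call. = FALSE)
  rows <- list()
  for (g in unique(rec$genotype)) {
    sub <- rec[rec$genotype == g, ]
    t0 <- min(sub$time_min)
    mean_cq <- function(t, loc) mean(sub$Cq[sub$time_min == t &
                                              sub$locus == loc])
    h0 <- mean_cq(t0, "hocs"); c0 <- mean_cq(t0, "control")
    if (!is.finite(h0) || !is.finite(c0))
      stop("reference (earliest) timepoint missing for genotype ", g,
           call. = FALSE)
    for (t in sort(unique(sub$time_min))) {
      dd <- (mean_cq(t, "hocs") - h0) - (mean_cq(t, "control") - c0)
      fc <- 1 - efficiency^(-dd)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, time_min = t,
        cut_fraction = min(max(fc, 0), 1), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Resected fraction among cut chromosomes
#'
#' Protection mixes three populations: background (incomplete digestion),
#' uncut chromosomes, and cut chromosomes resected past the site. Given
#' the background protection (from uninduced or t0 samples) and the cut
#' fraction, the resected fraction among cut chromosomes is
#' `(protection - background) / cut`, clipped to `[0, 1]`.
#'
#' @param protection Protection fraction(s).
#' @param background Background protection estimate.
#' @param cut Cut fraction(s); zero is undefined and returns `NA` with a
#'   warning.
#' @return Fraction(s) in `[0, 1]`.
#' @export
resected_fraction_among_cut <- function(protection, background, cut) {
  out <- rep(NA_real_, length(protection))
  bad <- !is.na(cut) & cut <= 0
  if (any(bad)) warning("cut fraction of 0: resected fraction undefined")
  ok <- !is.na(cut) & cut > 0 & !is.na(protection)
  out[ok] <- pmin(pmax((protection[ok] - background) / cut[ok], 0), 1)
  out
}

# first upward crossing of `level`, linearly interpolated; NA if never
t_half <- function(time, frac, level) {
  ord <- order(time)
  time <- time[ord]; frac <- frac[ord]
  for (i in seq_along(frac)[-1]) {
    if (frac[i - 1] < level && frac[i] >= level) {
      return(time[i - 1] + (level - frac[i - 1]) /
               (frac[i] - frac[i - 1]) * (time[i] - time[i - 1]))
    }
  }
  NA_real_
}

#' Population resection rate from multi-site kinetics
#'
#' The time of half-maximal resected fraction (t50, linear interpolation
#' between bracketing timepoints) is found per ApoI site; between two
#' sites the resection front travels their distance difference in the t50
#' difference, so `rate = d(distance) / d(t50)`. All site pairs are
#' reported plus a pooled estimate (least-squares slope of distance on
#' t50); with >= 2 replicates a 95% t-interval over per-replicate pooled
#' rates is attached.
#'
#' @param curves Data frame: `site_kb`, `time_min`, `fraction` (resected
#'   fraction among cut chromosomes), optional `replicate`.
#' @param half_level `NULL` (default) uses half of each site's maximum;
#'   a number fixes the crossing level for all sites.
#' @return Object of class `population_rate`: `per_pair` (site pair,
#'   `t50_a`, `t50_b`, `rate_kb_hr`; an identical-t50 pair yields `Inf`
#'   and an out-of-model flag), `pooled_rate_kb_hr`, `ci95` (or `NA`),
#'   `t50` per site. Sites never crossing half-max are excluded with a
#'   notice; fewer than 2 usable sites is an error.
#' @export
population_rate <- function(curves, half_level = NULL) {
  stopifnot(all(c("site_kb", "time_min", "fraction") %in% names(curves)))
  agg <- stats::aggregate(fraction ~ site_kb + time_min, data = curves,
                          FUN = mean)
  sites <- sort(unique(agg$site_kb))
  t50 <- vapply(sites, function(d) {
    cur <- agg[agg$site_kb == d, ]
    lev <- if (is.null(half_level)) max(cur$fraction) / 2 else half_level
    if (lev <= 0) return(NA_real_)
    t_half(cur$time_min, cur$fraction, lev)
  }, numeric(1))
  usable <- !is.na(t50)
  if (any(!usable))
    message("excluding site(s) never reaching half-max: ",
            paste(sites[!usable], collapse = ", "), " kb")
  sites <- sites[usable]; t50 <- t50[usable]
  if (length(sites) < 2L)
    stop("need >= 2 sites whose curves cross half-max", call. = FALSE)
  pr <- utils::combn(seq_along(sites), 2, simplify = FALSE)
  per_pair <- do.call(rbind, lapply(pr, function(ij) {
    dt <- (t50[ij[2]] - t50[ij[1]]) / 60
    dd <- sites[ij[2]] - sites[ij[1]]
    data.frame(site_a_kb = sites[ij[1]], site_b_kb = sites[ij[2]],
               t50_a_min = t50[ij[1]], t50_b_min = t50[ij[2]],
               rate_kb_hr = if (dt == 0) Inf else dd / dt,
               out_of_model = dt == 0, stringsAsFactors = FALSE)
  }))
  pooled <- if (stats::sd(t50) == 0) Inf
            else unname(stats::coef(stats::lm(sites ~ t50))[2]) * 60
  ci <- c(NA_real_, NA_real_)
  if ("replicate" %in% names(curves) &&
      length(unique(curves$replicate)) >= 2L) {
    reps <- unique(curves$replicate)
    rr <- vapply(reps, function(r) {
      cur <- curves[curves$replicate == r, ]
      tr <- vapply(sites, function(d) {
        cc <- cur[cur$site_kb == d, ]
        lev <- if (is.null(half_level)) max(cc$fraction) / 2 else half_level
        t_half(cc$time_min, cc$fraction, lev)
      }, numeric(1))
      if (anyNA(tr) || stats::sd(tr) == 0) return(NA_real_)
      unname(stats::coef(stats::lm(sites ~ tr))[2]) * 60
    }, numeric(1))
    rr <- rr[is.finite(rr)]
    if (length(rr) >= 2L) {
      se <- stats::sd(rr) / sqrt(length(rr))
      q <- stats::qt(0.975, df = length(rr) - 1)
      ci <- mean(rr) + c(-1, 1) * q * se
    }
  }
  structure(list(per_pair = per_pair,
                 pooled_rate_kb_hr = pooled,
                 ci95 = ci,
                 t50 = stats::setNames(t50, paste0(sites, "kb"))),
            class = "population_rate")
}

#' @export
print.population_rate <- function(x, ...) {
  cat("Population resection rate (ApoI-protection qPCR)\n")
  cat("  t50 (min):", paste(sprintf("%s = %.1f", names(x$t50), x$t50),
                            collapse = ", "), "\n")
  for (i in seq_len(nrow(x$per_pair)))
    cat(sprintf("  %g -> %g kb: %.2f kb/hr%s\n",
                x$per_pair$site_a_kb[i], x$per_pair$site_b_kb[i],
                x$per_pair$rate_kb_hr[i],
                if (x$per_pair$out_of_model[i]) "  [out of model]" else ""))
  cat(sprintf("  pooled: %.2f kb/hr", x$pooled_rate_kb_hr))
  if (all(is.finite(x$ci95)))
    cat(sprintf("  (95%% CI %.2f-%.2f)", x$ci95[1], x$ci95[2]))
  cat("\n")
  invisible(x)
}
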