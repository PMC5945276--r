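quad <- function(cq_ad, cq_am, cq_cd, cq_cm, time = 60, site = 3, rep = 1,
                 genotype = "WT") {
  data.frame(genotype = genotype, time_min = time, site_kb = site,
             condition = c("ApoI", "mock", "ApoI", "mock"),
             locus = c("target", "target", "control", "control"),
             Cq = c(cq_ad, cq_am, cq_cd, cq_cm), replicate = rep,
             stringsAsFactors = FALSE)
}

test_that("delta-delta-Cq maps to protection with factor-2 logic", {
  # ddCq = 0: fully protected relative to control
  expect_equal(protection_fraction(quad(20, 20, 18, 18))$protection, 1)
  # one extra cycle after digestion = half the template survives
  expect_equal(protection_fraction(quad(21, 20, 18, 18))$protection, 0.5)
  # digestion-efficiency shifts on the control cancel
  expect_equal(protection_fraction(quad(21.7, 20, 18.7, 18))$protection, 0.5)
  # clipping flags impossible values
  res <- protection_fraction(quad(19, 20, 18, 18))
  expect_true(res$clipped)
  expect_equal(res$protection, 1)
})

test_that("protection is invariant to a constant plate offset", {
  set.seed(31)
  base <- quad(runif(1, 20, 25), runif(1, 19, 21), runif(1, 17, 19),
               runif(1, 17, 19))
  shifted <- base; shifted$Cq <- shifted$Cq + 3.21
  expect_equal(protection_fraction(base)$protection,
               protection_fraction(shifted)$protection)
})

test_that("incomplete quadruplets are skipped with a notice", {
  rec <- quad(21, 20, 18, 18)[-1, ]
  expect_message(out <- protection_fraction(rec), "incomplete")
  expect_equal(nrow(out), 0L)
})

test_that("a simulated plate with known protection recovers it through
          the Cq model", {
  cfg <- sim_config(n_cells = 20000, cut_fraction = 0.4, seed = 17,
                    rate_model = rate_model(7.6))
  plate <- simulate_qpcr_plate(cfg, site_distances_kb = 3,
                               timepoints_min = c(0, 180),
                               n_replicates = 6, cq_noise_sd = 0.1,
                               background_protection = 0)
  truth <- attr(plate, "truth")
  p_true <- truth$true_protected_fraction[truth$time_min == 180]
  est <- protection_fraction(plate)
  est180 <- est$protection[est$time_min == 180]
  expect_lt(abs(mean(est180) - p_true), 0.03)
})

test_that("cut fraction recovers the simulated induction level", {
  cfg <- sim_config(n_cells = 20000, cut_fraction = 0.15, seed = 23,
                    rate_model = rate_model(7.6))
  plate <- simulate_qpcr_plate(cfg, timepoints_min = c(0, 120, 240),
                               n_replicates = 4)
  truth <- attr(plate, "truth")
  cf <- cut_fraction(plate)
  # by 120 min every cut has happened (2 hr induction window)
  true120 <- max(truth$true_cut_fraction[truth$time_min == 120])
  expect_lt(abs(cf$cut_fraction[cf$time_min == 120] - true120), 0.03)
  # unchanged Cq at the reference timepoint gives 0
  expect_lt(cf$cut_fraction[cf$time_min == 0], 0.02)
  expect_error(cut_fraction(quad(20, 20, 18, 18)), "HOcs")
})

test_that("resected fraction among cut chromosomes normalizes protection", {
  expect_equal(resected_fraction_among_cut(0.05, 0.05, 0.2), 0)
  expect_equal(resected_fraction_among_cut(0.25, 0.05, 0.2), 1)
  expect_equal(resected_fraction_among_cut(0.15, 0.05, 0.2), 0.5)
  expect_warning(bad <- resected_fraction_among_cut(0.3, 0.05, 0),
                 "undefined")
  expect_true(is.na(bad))
})

test_that("population rate from two-site kinetics matches the generator", {
  # noiseless curves from the front model at a fixed 7.6 kb/hr
  cfg <- noiseless_config(n_cells = 30000, cut_fraction = 1, seed = 29,
                          rate_model = rate_model(7.6, sdlog = 0))
  plate <- simulate_qpcr_plate(cfg, site_distances_kb = c(3, 13),
                               timepoints_min = seq(0, 300, 10),
                               n_replicates = 1, cq_noise_sd = 0,
                               background_protection = 0)
  est <- protection_fraction(plate)
  curves <- data.frame(site_kb = est$site_kb, time_min = est$time_min,
                       fraction = est$protection)
  pr <- population_rate(curves)
  expect_equal(pr$pooled_rate_kb_hr, 7.6, tolerance = 0.10)
  expect_equal(pr$per_pair$rate_kb_hr, 7.6, tolerance = 0.10)

  # identical t50s are out of model
  dup <- rbind(curves[curves$site_kb == 3, ],
               transform(curves[curves$site_kb == 3, ], site_kb = 5))
  pr2 <- population_rate(dup)
  expect_true(all(pr2$per_pair$out_of_model))
  expect_true(is.infinite(pr2$per_pair$rate_kb_hr))

  # a site that never crosses half-max is excluded; one site is an error
  flatline <- rbind(curves[curves$site_kb == 3, ],
                    data.frame(site_kb = 40,
                               time_min = seq(0, 300, 10), fraction = 0))
  expect_error(expect_message(population_rate(flatline), "excluding"),
               ">= 2 sites")
})

test_that("resected fraction is monotone non-increasing in site distance", {
  cfg <- sim_config(n_cells = 20000, cut_fraction = 0.3, seed = 37,
                    rate_model = rate_model(7.6))
  plate <- simulate_qpcr_plate(cfg, site_distances_kb = c(1, 5, 12),
                               timepoints_min = c(90, 180, 270),
                               n_replicates = 8)
  est <- protection_fraction(plate)
  agg <- aggregate(protection ~ site_kb + time_min, est, mean)
  for (t in unique(agg$time_min)) {
    cur <- agg[agg$time_min == t, ]
    cur <- cur[order(cur$site_kb), ]
    expect_true(all(diff(cur$protection) <= 0.05))  # Cq noise allowance
  }
})

test_that("qPCR tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  plate <- quad(21, 20, 18, 18)
  write.csv(plate, path, row.names = FALSE)
  back <- read_qpcr(path)
  expect_equal(back$Cq, plate$Cq)
  writeLines("a,b\n1,2", path)
  expect_error(read_qpcr(path), "columns")
})
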