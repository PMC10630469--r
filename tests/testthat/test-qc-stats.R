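test_that("rsd follows the sample-sd definition and NA rules", {
  expect_equal(rsd(c(5, 5, 5)), 0)
  expect_equal(rsd(c(90, 100, 110)), 10)   # sd 10, mean 100
  expect_true(is.na(rsd(7)))
  expect_true(is.na(rsd(c(3, NA))))
  expect_equal(rsd(c(90, 100, 110, NA)), 10)
})

test_that("pearson_r2 matches the textbook formula and flags degeneracy", {
  x <- 1:6
  expect_equal(pearson_r2(x, 2 * x), 1.0)
  expect_true(is.na(pearson_r2(x, rep(4, 6))))
  expect_true(is.na(pearson_r2(1:2, 2:3)))
  set.seed(77)
  a <- rnorm(50); b <- 0.6 * a + rnorm(50)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r2(a, b), (num / den)^2, tolerance = 1e-12)
})

test_that("qc_summary categories partition channels and medians track CVs", {
  catalog <- desk_catalog(80, seed = 51)
  sim <- simulate_quant_table(catalog, n_per_group = 3, n_qc = 6,
                              noise_cv = 0, ms1_cv = 0.08, ms2_cv = 0.18,
                              seed = 8)
  qc <- names(sim$groups)[sim$groups == "QC"]
  res <- qc_summary(sim$quant, qc)
  s <- res$summary
  expect_equal(s$n_total,
               s$n_rsd_lt20 + s$n_rsd_20_30 + s$n_rsd_gt30 +
                 s$n_non_quantifiable)
  ms1 <- s[s$level == "MS1", ]
  ms2 <- s[s$level == "MS2", ]
  expect_lt(abs(ms1$median_rsd_all - 8), 3)
  expect_lt(abs(ms2$median_rsd_all - 18), 3)
  # identical QC values: every channel "<20" with median 0
  q0 <- sim$quant
  q0$area <- ave(q0$area, lipidia:::chan_key(q0), FUN = function(v) v[1])
  q0$area_detected <- q0$area
  res0 <- qc_summary(q0, qc)
  expect_true(all(res0$channels$rsd_category == "<20"))
  expect_equal(res0$summary$median_rsd_all, c(0, 0))
})

test_that("a channel seen in one QC sample is non-quantifiable", {
  catalog <- desk_catalog(3, seed = 5)
  sim <- simulate_quant_table(catalog, n_per_group = 2, n_qc = 3, seed = 2)
  q <- sim$quant
  one <- q$entry_id == catalog$species_name[1] & q$channel == "MS1" &
    q$sample %in% c("QC_2", "QC_3")
  q$area[one] <- NA; q$area_detected[one] <- NA
  res <- qc_summary(q, c("QC_1", "QC_2", "QC_3"))
  ch <- res$channels
  bad <- ch$entry_id == catalog$species_name[1] & ch$channel == "MS1"
  expect_equal(ch$rsd_category[bad], "non_quantifiable")
})

test_that("best fragment is chosen by correlation, then RSD", {
  ch <- data.frame(entry_id = "X", adduct = "[M+H]+",
                   polarity = "positive", sum_composition = "X",
                   channel = c("MS1", "200.1", "300.2", "400.3"),
                   rsd_qc = c(5, 12, 8, 8),
                   rsd_category = "<20",
                   r2_vs_ms1 = c(NA, 0.99, 0.90, 0.99),
                   median_area = c(100, 10, 20, 5))
  best <- select_best_fragment(ch, "X")
  expect_equal(best$channel, "400.3")   # tie on R2 broken by lower RSD
  single <- ch[c(1, 3), ]
  expect_equal(select_best_fragment(single, "X")$channel, "300.2")
  none <- ch[1, ]
  expect_null(select_best_fragment(none, "X"))
})

test_that("linearity uses only volumes at or below the saturation cap", {
  # proportional up to 4 uL, hard plateau at 8 uL
  vols <- c(0.25, 0.5, 1, 2, 4, 8)
  area <- ifelse(vols <= 4, 1000 * vols, 4000)
  q <- data.frame(entry_id = "L", sum_composition = "L",
                  adduct = "[M+H]+", polarity = "positive",
                  channel = "MS1",
                  sample = sprintf("dil_%g", vols), area = area,
                  filled = FALSE, area_detected = area)
  man <- data.frame(sample_id = sprintf("dil_%g", vols), path = NA,
                    group = "dilution", injection_volume_uL = vols,
                    replicate = 1:6)
  lin <- linearity(q, man)
  expect_equal(lin$n_volumes, 5L)       # 5 of the 6 points used
  expect_equal(lin$r2_linearity, 1.0, tolerance = 1e-12)
  # with the cap lifted the plateau destroys the fit
  lin8 <- linearity(q, man, stat_params(linearity_max_volume = 8))
  expect_lt(lin8$r2_linearity, 0.95)
})

test_that("the retention filter applies both gates strictly", {
  catalog <- desk_catalog(200, seed = 5)
  noisy <- catalog$species_name[1:20]
  sim <- simulate_quant_table(
    catalog, n_per_group = 5, n_qc = 6, noise_cv = 0.10, seed = 3,
    ms2_cv_override = setNames(rep(0.6, 20), noisy))
  qc <- names(sim$groups)[sim$groups == "QC"]
  study <- names(sim$groups)[sim$groups != "QC"]
  flt <- filter_for_diff(sim$quant, qc, study)
  kept <- flt$entries$entry_id
  expect_lte(length(intersect(noisy, kept)), 2L)
  expect_gte(length(setdiff(catalog$species_name, noisy) |>
                      intersect(kept)), 170L)
  # monotonicity: loosening thresholds never shrinks the retained set
  tight <- filter_for_diff(sim$quant, qc, study,
                           stat_params(rsd_pass = 20, rsd_tight = 10,
                                       r2_ms1_min = 0.9))
  loose <- filter_for_diff(sim$quant, qc, study,
                           stat_params(rsd_pass = 40, r2_ms1_min = 0.5))
  expect_true(all(tight$entries$entry_id %in% flt$entries$entry_id |
                    length(tight$entries$entry_id) == 0))
  expect_true(all(flt$entries$entry_id %in% loose$entries$entry_id))
})

test_that("RSD boundary at the pass threshold is strict", {
  # MS1 RSD exactly 29.9 percent passes; exactly 30 fails
  mk <- function(r) {
    vals <- c(100 - r, 100, 100 + r)   # mean 100, sample sd r
    stopifnot(abs(rsd(vals) - r) < 1e-9)
    vals
  }
  q <- do.call(rbind, lapply(list(c("A", 29.9), c("B", 30)), function(z) {
    rbind(
      data.frame(entry_id = z[1], sum_composition = z[1],
                 adduct = "[M+H]+", polarity = "positive", channel = "MS1",
                 sample = c("QC_1", "QC_2", "QC_3"),
                 area = mk(as.numeric(z[2])), filled = FALSE),
      data.frame(entry_id = z[1], sum_composition = z[1],
                 adduct = "[M+H]+", polarity = "positive",
                 channel = "500.0",
                 sample = c("QC_1", "QC_2", "QC_3"),
                 area = mk(5), filled = FALSE))
  }))
  study <- do.call(rbind, lapply(c("A", "B"), function(e) {
    x <- c(50, 100, 200, 400, 800)
    rbind(data.frame(entry_id = e, sum_composition = e,
                     adduct = "[M+H]+", polarity = "positive",
                     channel = "MS1", sample = sprintf("s%d", 1:5),
                     area = x, filled = FALSE),
          data.frame(entry_id = e, sum_composition = e,
                     adduct = "[M+H]+", polarity = "positive",
                     channel = "500.0", sample = sprintf("s%d", 1:5),
                     area = 0.4 * x, filled = FALSE))
  }))
  qq <- rbind(q, study)
  qq$area_detected <- qq$area
  flt <- filter_for_diff(qq, c("QC_1", "QC_2", "QC_3"),
                         sprintf("s%d", 1:5))
  expect_equal(flt$entries$entry_id, "A")
})

test_that("the representative readout takes the lowest RSD across polarities", {
  flt <- list(
    entries = data.frame(entry_id = c("PC 34:1 pos", "PC 34:1 neg"),
                         adduct = c("[M+H]+", "[M+HCOO]-"),
                         polarity = c("positive", "negative"),
                         sum_composition = "PC 34:1"),
    channels = data.frame(
      entry_id = rep(c("PC 34:1 pos", "PC 34:1 neg"), each = 2),
      adduct = rep(c("[M+H]+", "[M+HCOO]-"), each = 2),
      polarity = rep(c("positive", "negative"), each = 2),
      sum_composition = "PC 34:1",
      channel = c("MS1", "184.07", "MS1", "168.04"),
      rsd_qc = c(9, 12, 11, 6),
      rsd_category = "<20", r2_vs_ms1 = c(NA, 0.95, NA, 0.97),
      median_area = 1, qualifying = c(FALSE, TRUE, FALSE, TRUE)))
  rep1 <- representative_readout(flt)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$polarity, "negative")   # negative fragment beats MS1
  expect_equal(rep1$channel, "168.04")
  # single channel: itself
  flt2 <- list(entries = flt$entries[1, ],
               channels = flt$channels[1, ])
  expect_equal(representative_readout(flt2)$channel, "MS1")
})

test_that("BH adjustment matches the reference step-up procedure", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(19)
  for (i in 1:1000) {
    p <- runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_reference(p),
                 tolerance = 1e-12)
  }
})

test_that("differential abundance calls programmed changes, not nulls", {
  catalog <- desk_catalog(60, seed = 13)
  changed <- catalog$species_name[1:12]
  sim <- simulate_quant_table(catalog,
                              setNames(rep(2.5, 12), changed),
                              n_per_group = 5, n_qc = 6,
                              noise_cv = 0.10, seed = 21)
  qc <- names(sim$groups)[sim$groups == "QC"]
  study <- names(sim$groups)[sim$groups != "QC"]
  flt <- filter_for_diff(sim$quant, qc, study)
  reps <- representative_readout(flt)
  grp <- sim$groups[sim$groups != "QC"]
  d <- differential(sim$quant, grp, reps, group_order = c("WT", "KO"))
  truth_changed <- sim$truth$sum_composition[sim$truth$fold != 1]
  hit <- d$significant & d$sum_composition %in% truth_changed
  expect_gte(sum(hit), 11L)
  expect_lte(sum(d$significant & !(d$sum_composition %in% truth_changed)),
             2L)
  # programmed fold change is recovered on the log2 scale
  expect_lt(abs(stats::median(d$log2_fc[d$sum_composition %in%
                                          truth_changed]) - log2(2.5)),
            0.1)
  # identical groups: no significance
  sim0 <- simulate_quant_table(catalog, NULL, n_per_group = 5, n_qc = 6,
                               noise_cv = 0.10, seed = 22)
  flt0 <- filter_for_diff(sim0$quant, qc, study)
  d0 <- differential(sim0$quant, sim0$groups[sim0$groups != "QC"],
                     representative_readout(flt0),
                     group_order = c("WT", "KO"))
  expect_equal(sum(d0$significant), 0L)
})

test_that("median centring zeroes every row median", {
  m <- matrix(c(3, 3, 3, 3, 10, 20, 40, 80), nrow = 2, byrow = TRUE)
  mc <- median_center(m)
  expect_equal(mc[1, ], rep(0, 4))
  expect_equal(apply(mc, 1, stats::median), c(0, 0))
  # doubling one sample adds exactly +1 in that cell
  m2 <- matrix(rep(100, 5), 1)
  m2[1, 3] <- 200
  expect_equal(median_center(m2)[1, 3], 1)
  set.seed(3)
  r <- matrix(rlnorm(60), 6)
  expect_equal(apply(median_center(r), 1, stats::median), rep(0, 6),
               tolerance = 1e-12)
})
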