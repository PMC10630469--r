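test_that("an absent entry yields all-null channels, filled on demand", {
  catalog <- desk_catalog(5, seed = 9, rt_range = c(0.5, 1.5))
  w <- desk_windows(catalog, n_windows = 3)
  run <- simulate_dia_run(catalog[0, ], w, gradient_length = 2, seed = 1)
  entry <- catalog_to_library(catalog)[[1]]
  rec <- quantify_entry(run, entry, w)
  expect_true(is.na(rec$ms1_area))
  expect_true(all(is.na(rec$fragments$area)))
  expect_false(rec$ms1_filled)
  filled <- fill_missing(run, entry, rec, w)
  expect_equal(filled$ms1_area, 0)
  expect_true(filled$ms1_filled)
  expect_true(all(filled$fragments$area == 0))
  expect_true(all(filled$fragments$filled))
})

test_that("simulated areas are recovered with correct fragment ratios", {
  catalog <- desk_catalog(50, seed = 7, rt_range = c(0.5, 3.5))
  w <- desk_windows(catalog)
  run <- simulate_dia_run(catalog, w, noise_cv = 0.05,
                          gradient_length = 4, seed = 11)
  lib <- catalog_to_library(catalog)
  q <- quantify_batch(run, lib, w, fill = FALSE)
  truth <- catalog$base_abundance * catalog$peak_sigma * sqrt(2 * pi)
  ms1 <- q[q$channel == "MS1", ]
  got <- ms1$area[match(catalog$species_name, ms1$entry_id)]
  rel <- abs(got - truth) / truth
  expect_gte(mean(rel < 0.05, na.rm = TRUE), 0.95)
  # fragment yield ratios for a handful of species
  for (i in c(1, 10, 25)) {
    fr <- catalog$fragments[[i]]
    sub <- q[q$entry_id == catalog$species_name[i] & q$channel != "MS1", ]
    exp_area <- truth[i] * fr$yield[match(as.numeric(sub$channel), fr$mz)]
    ratio <- (sub$area / sum(sub$area)) / (exp_area / sum(exp_area))
    expect_true(all(abs(ratio - 1) < 0.10, na.rm = TRUE))
  }
})

test_that("RT isomers are quantified from their own peaks", {
  base <- desk_catalog(1, seed = 14, rt_range = c(1, 1))
  iso <- base
  iso$rt <- base$rt + 0.4
  iso$species_name <- "isomer_late"
  iso$base_abundance <- base$base_abundance * 3
  two <- rbind(base, iso)
  class(two) <- c("lp_catalog", "data.frame")
  w <- desk_windows(two, n_windows = 2, min_width = 10, max_width = 690)
  run <- simulate_dia_run(two, w, noise_cv = 0, gradient_length = 2,
                          seed = 3)
  lib <- catalog_to_library(two)
  q <- quantify_batch(run, lib, w, fill = FALSE)
  truth <- two$base_abundance * two$peak_sigma * sqrt(2 * pi)
  for (i in 1:2) {
    got <- q$area[q$entry_id == two$species_name[i] & q$channel == "MS1"]
    expect_lt(abs(got - truth[i]) / truth[i], 0.05)
  }
})

test_that("extraction from the wrong window sees no signal", {
  catalog <- desk_catalog(30, seed = 25, rt_range = c(0.5, 2))
  w <- desk_windows(catalog, n_windows = 6)
  run <- simulate_dia_run(catalog, w, noise_cv = 0, gradient_length = 2.5,
                          seed = 2)
  # a species whose precursor is interior to its core window
  win <- assign_window(catalog$precursor_mz, w)
  interior <- which(catalog$precursor_mz > w$ext_low[win] + 1 &
                      catalog$precursor_mz < w$ext_high[win] - 1)
  i <- interior[1]
  fr <- catalog$fragments[[i]]
  right <- extract_xic(run, fr$mz[1], 0.01, ms_level = 2,
                       window_id = win[i])
  wrong_id <- if (win[i] == 1L) nrow(w) else win[i] - 1L
  wrong <- extract_xic(run, fr$mz[1], 0.01, ms_level = 2,
                       window_id = wrong_id)
  expect_gt(max(right$intensity), 0)
  expect_equal(max(wrong$intensity), 0)
  expect_error(extract_xic(run, fr$mz[1], 0.01, ms_level = 2,
                           window_id = 99), "not present")
})

test_that("a species in the overlap region appears in both windows", {
  catalog <- desk_catalog(40, seed = 33, rt_range = c(0.5, 1.5))
  w <- desk_windows(catalog, n_windows = 6)
  ov <- NULL
  for (i in seq_len(nrow(catalog))) {
    hits <- which(catalog$precursor_mz[i] >= w$ext_low &
                    catalog$precursor_mz[i] <= w$ext_high)
    if (length(hits) == 2L) { ov <- i; break }
  }
  if (is.null(ov)) {
    # force one: move a precursor into the first interior overlap
    catalog$precursor_mz[1] <- w$core_high[1]
    ov <- 1L
    hits <- c(1L, 2L)
  }
  run <- simulate_dia_run(catalog, w, noise_cv = 0, gradient_length = 2,
                          seed = 5)
  fr <- catalog$fragments[[ov]]
  for (h in hits) {
    tr <- extract_xic(run, fr$mz[1], 0.01, ms_level = 2, window_id = h)
    expect_gt(max(tr$intensity), 0)
  }
})

test_that("forced fill recovers a sub-threshold bump and is idempotent", {
  # a tiny 3-point bump is below what peak detection reports with
  # min_points and smoothing, but forced integration must capture it
  catalog <- desk_catalog(1, seed = 40, rt_range = c(1, 1))
  catalog$base_abundance <- 1e5
  w <- desk_windows(catalog, n_windows = 2, max_width = 690)
  run <- simulate_dia_run(catalog, w, noise_cv = 0, gradient_length = 2,
                          seed = 1)
  entry <- catalog_to_library(catalog)[[1]]
  rec <- quantify_entry(run, entry, w)
  analytic <- 1e5 * catalog$peak_sigma * sqrt(2 * pi)
  expect_lt(abs(rec$ms1_area - analytic) / analytic, 0.05)
  rec2 <- fill_missing(run, entry, rec, w)
  expect_equal(rec2$ms1_area, rec$ms1_area)   # untouched when detected
  expect_false(rec2$ms1_filled)
  # the full-window forced trapezoid also recovers the analytic area
  fa <- lipidia:::forced_area(extract_xic(run, entry$precursor_mz, 0.005),
                              entry$rt, 0.5)
  expect_lt(abs(fa - analytic) / analytic, 0.10)
})

test_that("batch output is rectangular and fill only adds cells", {
  catalog <- desk_catalog(10, seed = 21, rt_range = c(0.5, 1.5))
  w <- desk_windows(catalog, n_windows = 4)
  runs <- lapply(1:3, function(i)
    simulate_dia_run(catalog, w, noise_cv = 0.05, gradient_length = 2,
                     seed = 50 + i, sample_id = paste0("s", i)))
  lib <- catalog_to_library(catalog)
  q <- quantify_batch(runs, lib, w, fill = TRUE)
  nchan <- sum(vapply(lib, function(e) 1L + nrow(e$fragments), integer(1)))
  expect_equal(nrow(q), 3L * nchan)
  expect_false(any(is.na(q$area)))            # fill leaves no blank cells
  det <- !is.na(q$area_detected)
  expect_equal(q$area[det], q$area_detected[det])  # detected cells identical
  expect_true(all(q$filled[!det]))
  # written tables agree
  outdir <- tempfile()
  quantify_batch(runs, lib, w, fill = TRUE, outdir = outdir)
  qa <- read.delim(file.path(outdir, "quant_all.tsv"))
  qf <- read.delim(file.path(outdir, "quant_fill_all.tsv"))
  expect_equal(nrow(qa), nrow(qf))
  expect_false(any(is.na(qf$area)))
  ok <- !is.na(qa$area)
  expect_equal(qa$area[ok], qf$area[ok])
})

test_that("dilution series quantification is linear below saturation", {
  catalog <- desk_catalog(25, seed = 12, rt_range = c(0.5, 2))
  w <- desk_windows(catalog, n_windows = 5)
  sim <- simulate_dilution_series(catalog, w,
                                  volumes = c(0.25, 0.5, 1, 2, 4),
                                  noise_cv = 0.03, seed = 60,
                                  gradient_length = 2.5)
  lib <- catalog_to_library(catalog)
  q <- quantify_batch(sim$runs, lib, w, fill = TRUE)
  lin <- linearity(q, sim$manifest,
                   stat_params(linearity_max_volume = 4))
  expect_gte(stats::median(lin$r2_linearity, na.rm = TRUE), 0.99)
})

test_that("mixed-polarity pairing is rejected", {
  catalog <- desk_catalog(5, seed = 9, rt_range = c(0.5, 1))
  w <- desk_windows(catalog, n_windows = 3)
  run <- simulate_dia_run(catalog, w, gradient_length = 1.5, seed = 1)
  neg <- make_catalog(5, polarity = "negative", seed = 9,
                      rt_range = c(0.5, 1))
  expect_error(quantify_batch(run, catalog_to_library(neg), w),
               "polarity")
})
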