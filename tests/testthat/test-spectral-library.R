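test_that("lipid shorthand parses to structured chains", {
  p <- parse_lipid_name("SM 30:1;2O/2:0")
  expect_equal(p$class, "SM")
  expect_equal(p$chains$carbons, c(30L, 2L))
  expect_equal(p$chains$double_bonds, c(1L, 0L))
  expect_equal(p$chains$oxygens, c(2L, 0L))

  p <- parse_lipid_name("Cer d18:1/12:0")
  expect_equal(p$chains$carbons, c(18L, 12L))
  expect_equal(p$chains$oxygens, c(2L, 0L))

  p <- parse_lipid_name("PC 13:0/13:0")
  expect_equal(p$chains$carbons, c(13L, 13L))
  expect_equal(p$chains$oxygens, c(0L, 0L))

  p <- parse_lipid_name("PC-P 18:0/18:1")
  expect_true(p$ether)
  expect_equal(p$class, "PC-P")

  expect_error(parse_lipid_name("PC xx:0/18:1"), "cannot parse")
})

test_that("sum composition collapses chains and is idempotent", {
  expect_equal(to_sum_composition("SM 30:1;2O/2:0"), "SM 32:1")
  expect_equal(to_sum_composition("PC 13:0/13:0"), "PC 26:0")
  expect_equal(to_sum_composition("SM 32:1"), "SM 32:1")
  expect_equal(to_sum_composition(to_sum_composition("Cer d18:1/12:0")),
               to_sum_composition("Cer d18:1/12:0"))
})

test_that("every internal-standard shorthand name parses", {
  standards <- c(
    "Cer d18:1/12:0", "Cer m18:1/12:0", "COH-d7", "HexCer d18:1/12:0",
    "Hex2Cer d18:1/12:0", "LPC 13:0", "LPE 14:0", "PC 13:0/13:0",
    "PE 17:0/17:0", "PG 17:0/17:0", "PI 12:0/13:0", "PS 17:0/17:0",
    "PC-P 18:0/18:1-d9", "PE-P 18:0/18:1-d9", "SM d18:1/12:0",
    "CAR 16:0-d3", "TG 12:0/12:0/12:0", "TG 17:0/17:0/17:0",
    "GM3 d18:0/18:1-d3", "Hex3Cer d18:0/18:1-d3", "CE 18:0-d6",
    "DG 15:0/15:0")
  for (s in standards)
    expect_no_error(to_sum_composition(s))
  expect_equal(to_sum_composition("TG 17:0/17:0/17:0"), "TG 51:0")
  expect_equal(to_sum_composition("PI 12:0/13:0"), "PI 25:0")
})

test_that("match_score follows the cosine-on-root-intensity contract", {
  a <- data.frame(mz = c(100, 200, 300), intensity = c(50, 80, 20))
  s <- match_score(a, a)
  expect_equal(s$score, 1.0, tolerance = 1e-12)
  expect_equal(s$n_matched, 3L)

  b <- data.frame(mz = c(150, 250), intensity = c(10, 10))
  s2 <- match_score(a, b)
  expect_equal(s2$score, 0.0)
  expect_equal(s2$n_matched, 0L)

  # headgroup/formate-loss example: both query peaks pair within 0.01 Da
  q <- data.frame(mz = c(659.515, 168.042), intensity = c(100, 40))
  r <- data.frame(mz = c(659.5148, 168.0416, 97.02),
                  intensity = c(100, 50, 10))
  s3 <- match_score(q, r)
  expect_equal(s3$n_matched, 2L)
  hand <- (sqrt(100 * 100) + sqrt(40 * 50)) / (sqrt(140) * sqrt(160))
  expect_equal(s3$score, hand, tolerance = 1e-12)
  expect_equal(s3$score, 0.9669602571, tolerance = 1e-9)

  # symmetry
  set.seed(2)
  x <- data.frame(mz = sort(runif(8, 100, 900)), intensity = runif(8, 1, 100))
  y <- data.frame(mz = x$mz + rnorm(8, 0, 0.004), intensity = runif(8, 1, 100))
  expect_equal(match_score(x, y)$score, match_score(y, x)$score,
               tolerance = 1e-9)
  expect_error(match_score(x[0, ], y), "non-empty")
})

test_that("consensus merges iterative injections per precursor and RT", {
  mk_run <- function(id, prec, rt, frag_int) {
    lp_run(list(
      lp_spectrum(1, 1, rt - 0.01, prec, 1000),
      lp_spectrum(2, 2, rt, c(200.05, 500.10), frag_int,
                  precursor_window = prec + c(-0.65, 0.65))),
      mode = "DDA", sample_id = id)
  }
  one <- build_consensus(mk_run("a", 700.4, 5, c(10, 90)))
  expect_length(one, 1L)
  expect_equal(one[[1]]$peaks$intensity, c(10, 90))

  runs <- list(mk_run("a", 700.4, 5.00, c(10, 90)),
               mk_run("b", 700.4005, 5.05, c(14, 70)),
               mk_run("c", 700.3995, 4.95, c(12, 80)))
  cs <- build_consensus(runs)
  expect_length(cs, 1L)
  expect_equal(cs[[1]]$n_scans, 3L)
  expect_equal(cs[[1]]$peaks$intensity, c(12, 80))  # median across runs
  expect_lt(abs(cs[[1]]$precursor_mz - 700.4), 0.001)

  # two species 0.02 Th apart at the same RT stay separate at ms1to1=0.005
  runs2 <- list(mk_run("a", 700.40, 5, c(10, 90)),
                mk_run("b", 700.42, 5, c(50, 50)))
  expect_length(build_consensus(runs2), 2L)

  dia <- lp_run(list(lp_spectrum(1, 1, 0.1, 500, 10)), mode = "DIA")
  expect_error(build_consensus(dia), "DDA")
})

test_that("library search recovers a noisy self-match and gates scores", {
  catalog <- desk_catalog(100, seed = 19)
  refs <- catalog_to_library(catalog)
  set.seed(42)
  consensus <- lapply(seq_along(refs), function(i) {
    e <- refs[[i]]
    list(id = i, precursor_mz = e$precursor_mz, rt = e$rt,
         n_scans = 1L,
         peaks = data.frame(mz = e$fragments$mz,
                            intensity = e$fragments$intensity *
                              rlnorm(nrow(e$fragments), 0, 0.05)))
  })
  cands <- search_library(consensus, refs, match_params(rt_shift = 10))
  resolved <- vapply(seq_along(refs), function(i) {
    sub <- cands[cands$spectrum_id == i, , drop = FALSE]
    win <- resolve_annotation(sub)
    !is.null(win) && win$species_name == refs[[i]]$species_name
  }, logical(1))
  expect_gte(sum(resolved), 95L)

  # zero noise: every entry self-matches with score 1
  clean <- lapply(seq_along(refs), function(i)
    list(id = i, precursor_mz = refs[[i]]$precursor_mz, rt = refs[[i]]$rt,
         n_scans = 1L, peaks = refs[[i]]$fragments))
  cands0 <- search_library(clean, refs, match_params(rt_shift = 10))
  self <- cands0[mapply(function(s, j) s == j, cands0$spectrum_id,
                        cands0$ref_index), ]
  expect_equal(nrow(self), length(refs))
  expect_true(all(abs(self$score - 1) < 1e-9))
  expect_true(all(self$passed))
})

test_that("score threshold is a strict gate but candidates are retained", {
  ref <- list(library_entry("PC 16:0/18:1", "[M+H]+", 760.585, rt = 5,
                            fragments = data.frame(mz = c(184.073, 500.3),
                                                   intensity = c(100, 60))))
  cs <- list(list(id = 1, precursor_mz = 760.585, rt = 5, n_scans = 1,
                  peaks = data.frame(mz = c(184.073, 620.9),
                                     intensity = c(100, 130))))
  p49 <- search_library(cs, ref, match_params(ms2_score_min = 0.90))
  expect_equal(nrow(p49), 1L)
  expect_false(p49$passed)
  expect_null(resolve_annotation(p49))
  # monotonicity: raising the threshold never grows the passed set
  ths <- c(0.2, 0.5, 0.8, 0.95)
  passed <- vapply(ths, function(t)
    sum(search_library(cs, ref, match_params(ms2_score_min = t))$passed),
    numeric(1))
  expect_true(all(diff(passed) <= 0))
})

test_that("annotation ties resolve to the last library entry", {
  cand <- data.frame(spectrum_id = 1, ref_index = c(3L, 7L),
                     species_name = c("SM d16:1/16:0", "SM 30:1;2O/2:0"),
                     sum_composition = "SM 32:1", adduct = "[M+HCOO]-",
                     polarity = "negative", score = c(0.9, 0.9),
                     n_matched = 2L, passed = TRUE)
  expect_equal(resolve_annotation(cand)$ref_index, 7L)
  expect_equal(resolve_annotation(cand, tie = "first")$ref_index, 3L)
  cand$score <- c(0.9, 0.8)
  expect_equal(resolve_annotation(cand)$ref_index, 3L)
})

test_that("adduct filtering enforces the polarity-specific sets", {
  mk <- function(ad, pol) library_entry("PC 16:0/18:1", ad, 760.5,
                                        fragments = data.frame(mz = 184,
                                                               intensity = 1),
                                        polarity = pol)
  pos <- list(mk("[M+H]+", "positive"), mk("[M+Na]+", "positive"),
              mk("[M+NH4]+", "positive"))
  expect_length(filter_adducts(pos, "positive"), 2L)
  neg <- list(mk("[M+HCOO]-", "negative"), mk("[M-H]-", "negative"),
              mk("[M+Cl]-", "negative"))
  expect_length(filter_adducts(neg, "negative"), 2L)
  expect_length(filter_adducts(list(), "positive"), 0L)
})

test_that("deduplication keeps the best-scoring entry per readout", {
  mk <- function(name, score, rt) library_entry(
    name, "[M+H]+", 703.57, rt = rt,
    fragments = data.frame(mz = 184.073, intensity = 100),
    match_score = score, sum_composition = "SM 34:1")
  two <- list(mk("SM d18:1/16:0", 0.9, 6.1), mk("SM d16:1/18:0", 0.7, 6.3))
  kept <- dedupe_entries(two)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$match_score, 0.9)
  # distinct adducts both survive
  other <- library_entry("SM d18:1/16:0", "[M+NH4]+", 720.6,
                         fragments = data.frame(mz = 184.073,
                                                intensity = 100),
                         match_score = 0.5, sum_composition = "SM 34:1")
  expect_length(dedupe_entries(c(two, list(other))), 2L)
  # three-way score tie resolves by earliest RT
  tie <- list(mk("a", 0.8, 6.5), mk("b", 0.8, 6.2), mk("c", 0.8, 6.9))
  expect_equal(dedupe_entries(tie)[[1]]$species_name, "b")
})

test_that("libraries round-trip through MSP and TSV", {
  catalog <- desk_catalog(15, seed = 8)
  lib <- catalog_to_library(catalog)
  for (fmt in c("msp", "tsv")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_library(lib, f, fmt)
    lib2 <- read_library(f, fmt)
    expect_length(lib2, length(lib))
    for (i in seq_along(lib)) {
      expect_equal(lib2[[i]]$species_name, lib[[i]]$species_name)
      expect_equal(lib2[[i]]$sum_composition, lib[[i]]$sum_composition)
      expect_equal(lib2[[i]]$adduct, lib[[i]]$adduct)
      expect_equal(lib2[[i]]$precursor_mz, lib[[i]]$precursor_mz,
                   tolerance = 1e-9)
      expect_equal(lib2[[i]]$rt, lib[[i]]$rt, tolerance = 1e-9)
      expect_equal(lib2[[i]]$fragments$mz, lib[[i]]$fragments$mz,
                   tolerance = 1e-9)
    }
  }
  # empty library and missing retention time
  f <- tempfile(fileext = ".msp")
  write_library(list(), f, "msp")
  expect_length(read_library(f, "msp"), 0L)
  writeLines(c("Name: PC 16:0/18:1", "PRECURSORMZ: 760.585",
               "PRECURSORTYPE: [M+H]+", "IONMODE: positive",
               "Num Peaks: 1", "184.0733 100", ""), f)
  e <- read_library(f, "msp")[[1]]
  expect_true(is.na(e$rt))
})
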