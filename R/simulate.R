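# ---- synthetic lipidomics runs ------------------------------------------
#
# The simulator emulates a reversed-phase lipidomics gradient on a Q-TOF:
# lipid species with class-dependent precursor m/z (so precursor density
# is non-uniform across the mass range), Gaussian elution peaks,
# log-normal abundance spread, 1-10 product ions per species, DDA top-N
# scheduling with active and iterative exclusion, and DIA cycles over an
# isolation-window scheme.  It is the ground-truth source for validating
# window design, extraction and statistics.

CLASS_MIX_DEFAULT <- c(TG = 0.30, PC = 0.22, SM = 0.15, LPC = 0.10,
                       Cer = 0.08, PE = 0.08, DG = 0.04, PI = 0.03)

# class-dependent precursor m/z distributions (mean, sd) and chain grids
CLASS_MZ <- list(TG = c(880, 40), PC = c(766, 35), SM = c(745, 40),
                 LPC = c(520, 30), Cer = c(590, 45), PE = c(730, 30),
                 DG = c(610, 30), PI = c(850, 25))
CLASS_CHAINS <- list(TG = 3L, PC = 2L, SM = 2L, LPC = 1L, Cer = 2L,
                     PE = 2L, DG = 2L, PI = 2L)

lognorm_sd <- function(cv) sqrt(log(1 + cv^2))

# multiplicative mean-1 log-normal noise
mnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- lognorm_sd(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate a synthetic lipid catalog
#'
#' Species are drawn from a class mixture (triacylglycerols most
#' represented, then PCs, SMs and LPCs); each class places its precursors
#' in a characteristic m/z region, so the catalog's precursor density is
#' non-uniform — the regime variable isolation windows are designed for.
#' Species names are molecular-species-level shorthand (unique within the
#' catalog); each species carries 1-10 product ions in 50-1000 m/z with
#' fragment yields summing to at most 1.
#'
#' @param n_species number of species.
#' @param polarity `"positive"` or `"negative"`.
#' @param class_mix named numeric vector of class weights.
#' @param seed RNG seed; fixed seed gives an identical catalog.
#' @param rt_range elution-time range (minutes) on the gradient.
#' @param mz_range precursor acquisition range (Th).
#' @param peak_sigma Gaussian peak sigma (minutes); 0.04 gives a base
#'   width of about 0.16 min.
#' @param abund_meanlog,abund_sdlog log-normal abundance spread.
#' @param max_fragments at most this many product ions per species.
#' @return data frame of class `"lp_catalog"` with a `fragments` list
#'   column (`mz`, `yield` per species).
#' @export
make_catalog <- function(n_species, polarity = "positive",
                         class_mix = CLASS_MIX_DEFAULT, seed = 1,
                         rt_range = c(0.5, 14), mz_range = c(300, 1000),
                         peak_sigma = 0.04, abund_meanlog = log(5e4),
                         abund_sdlog = 1, max_fragments = 10L) {
  set.seed(seed)
  if (n_species == 0L) {
    out <- data.frame(species_name = character(0),
                      sum_composition = character(0),
                      lipid_class = character(0), polarity = character(0),
                      adduct = character(0), precursor_mz = numeric(0),
                      rt = numeric(0), peak_sigma = numeric(0),
                      base_abundance = numeric(0),
                      group_fold_change = numeric(0))
    out$fragments <- list()
    class(out) <- c("lp_catalog", "data.frame")
    return(out)
  }
  cls <- sample(names(class_mix), n_species, replace = TRUE,
                prob = class_mix)
  name_of <- function(cl) {
    nch <- CLASS_CHAINS[[cl]]
    ch <- vapply(seq_len(nch), function(i) {
      c0 <- sample(seq(12L, 22L, 2L), 1)
      d0 <- sample(0:6, 1, prob = c(4, 4, 3, 2, 1, 1, 1))
      if (cl %in% c("SM", "Cer") && i == 1L)
        sprintf("d%d:%d", c0 + 6L, d0) else sprintf("%d:%d", c0, d0)
    }, character(1))
    paste(cl, paste(ch, collapse = "/"))
  }
  nm <- vapply(cls, name_of, character(1))
  # the catalog stands for distinct quantifiable lipids: readouts are at
  # sum-composition level, so species are redrawn until no two collapse
  # to the same sum composition
  sumc <- function(x) vapply(x, function(v)
    tryCatch(to_sum_composition(v), error = function(e) v), character(1))
  sc <- sumc(nm)
  stall <- 0L; prev <- Inf
  for (tries in 1:500) {
    dup <- which(duplicated(sc))
    if (!length(dup)) break
    stall <- if (length(dup) >= prev) stall + 1L else 0L
    if (stall > 25L) break     # composition space exhausted for a class
    prev <- length(dup)
    nm[dup] <- vapply(cls[dup], name_of, character(1))
    sc[dup] <- sumc(nm[dup])
  }
  if (anyDuplicated(sc)) {
    keepu <- !duplicated(sc)
    nm <- nm[keepu]; cls <- cls[keepu]; sc <- sc[keepu]
    n_species <- length(nm)
  }
  mzp <- t(vapply(cls, function(cl) CLASS_MZ[[cl]], numeric(2)))
  prec <- stats::rnorm(n_species, mzp[, 1], mzp[, 2])
  # reflect strays back into the acquisition range
  for (tries in 1:50) {
    bad <- prec < mz_range[1] | prec > mz_range[2]
    if (!any(bad)) break
    prec[bad] <- stats::rnorm(sum(bad), mzp[bad, 1], mzp[bad, 2])
  }
  prec <- pmin(pmax(prec, mz_range[1]), mz_range[2])
  rt <- stats::runif(n_species, rt_range[1], rt_range[2])
  abund <- stats::rlnorm(n_species, abund_meanlog, abund_sdlog)
  adduct <- if (polarity == "positive") {
    ifelse(cls == "TG", "[M+NH4]+", "[M+H]+")
  } else ifelse(cls %in% c("PC", "SM", "LPC"), "[M+HCOO]-", "[M-H]-")
  frags <- lapply(seq_len(n_species), function(i) {
    nf <- sample(seq_len(max_fragments), 1)
    fmz <- sort(stats::runif(nf, 50, min(999, prec[i] - 1)))
    total <- stats::runif(1, 0.2, 0.8)
    yl <- stats::rgamma(nf, 1.5)
    data.frame(mz = fmz, yield = total * yl / sum(yl))
  })
  out <- data.frame(species_name = nm, sum_composition = sc,
                    lipid_class = cls, polarity = polarity,
                    adduct = adduct, precursor_mz = prec, rt = rt,
                    peak_sigma = peak_sigma, base_abundance = abund,
                    group_fold_change = 1, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$fragments <- frags
  class(out) <- c("lp_catalog", "data.frame")
  out
}

#' Turn a catalog into a targeted spectral library
#'
#' Each species becomes a library entry whose fragment intensities are the
#' relative yields — the ground-truth library for targeted extraction.
#'
#' @param catalog an `lp_catalog`.
#' @return list of [library_entry()] objects.
#' @export
catalog_to_library <- function(catalog) {
  lapply(seq_len(nrow(catalog)), function(i)
    library_entry(
      species_name = catalog$species_name[i],
      adduct = catalog$adduct[i],
      precursor_mz = catalog$precursor_mz[i], rt = catalog$rt[i],
      fragments = data.frame(mz = catalog$fragments[[i]]$mz,
                             intensity = catalog$fragments[[i]]$yield),
      polarity = catalog$polarity[i], source = "simulated",
      sum_composition = catalog$sum_composition[i],
      lipid_class = catalog$lipid_class[i]))
}

soft_clamp <- function(x, ceiling) {
  if (!is.finite(ceiling)) return(x)
  ceiling * tanh(x / ceiling)
}

# Gaussian elution profile of species i at time t (minutes)
elution <- function(t, rt, sigma) exp(-(t - rt)^2 / (2 * sigma^2))

#' Simulate a DIA run over a window scheme
#'
#' Cycles of one MS1 scan followed by one MS2 scan per isolation window.
#' Every species contributes a Gaussian-in-time precursor signal to MS1
#' and, in each window whose *extended* bounds contain its precursor,
#' product-ion peaks scaled by the fragment yields (a species in the
#' overlap region therefore appears in both adjacent windows' scans).
#' Noise is multiplicative mean-one log-normal with the given CV, drawn
#' per species and scan; intensities are scaled by
#' `volume_scale * group_fold_change` and optionally soft-clamped at
#' `sat_ceiling` (a smooth tanh ceiling emulating detector saturation).
#'
#' @param catalog an `lp_catalog`.
#' @param windows an `lp_windows` scheme.
#' @param noise_cv technical noise CV (fraction).
#' @param volume_scale multiplicative intensity scale (e.g. injection
#'   volume relative to the reference).
#' @param ms1_rate,ms2_rate acquisition rates (spectra/s); 20 and 40 by
#'   default.
#' @param gradient_length run length (minutes).
#' @param seed RNG seed; a fixed seed and design give byte-identical
#'   output.
#' @param sat_ceiling saturation ceiling (intensity units); `Inf`
#'   disables.
#' @param sample_id run identifier.
#' @return a DIA [lp_run()].
#' @export
simulate_dia_run <- function(catalog, windows, noise_cv = 0.05,
                             volume_scale = 1, ms1_rate = 20,
                             ms2_rate = 40, gradient_length = 15.8,
                             seed = 1, sat_ceiling = Inf,
                             sample_id = "sim_dia") {
  set.seed(seed)
  nw <- nrow(windows)
  cycle_s <- 1 / ms1_rate + nw / ms2_rate
  starts <- seq(0, gradient_length * 60 - cycle_s, by = cycle_s) / 60
  members <- lapply(seq_len(nw), function(w)
    which(catalog$precursor_mz >= windows$ext_low[w] &
            catalog$precursor_mz <= windows$ext_high[w]))
  amp <- catalog$base_abundance * volume_scale * catalog$group_fold_change
  sig <- catalog$peak_sigma
  rts <- catalog$rt
  spectra <- vector("list", length(starts) * (nw + 1L))
  k <- 0L
  for (t0 in starts) {
    # MS1 scan
    act <- which(abs(rts - t0) <= 5 * sig)
    k <- k + 1L
    if (length(act)) {
      inten <- amp[act] * elution(t0, rts[act], sig[act]) *
        mnoise(length(act), noise_cv)
      inten <- soft_clamp(inten, sat_ceiling)
      agg <- rowsum(inten, catalog$precursor_mz[act])
      spectra[[k]] <- lp_spectrum(k, 1L, t0,
                                  as.numeric(rownames(agg)), agg[, 1],
                                  polarity = catalog$polarity[1])
    } else {
      spectra[[k]] <- lp_spectrum(k, 1L, t0, numeric(0), numeric(0),
                                  polarity = catalog$polarity[1])
    }
    for (w in seq_len(nw)) {
      tw <- t0 + (1 / ms1_rate + (w - 1L) / ms2_rate) / 60
      mem <- members[[w]]
      actw <- mem[abs(rts[mem] - tw) <= 5 * sig[mem]]
      k <- k + 1L
      pw <- c(windows$ext_low[w], windows$ext_high[w])
      if (length(actw)) {
        mzs <- unlist(lapply(catalog$fragments[actw], `[[`, "mz"),
                      use.names = FALSE)
        nfr <- vapply(catalog$fragments[actw], nrow, integer(1))
        yld <- unlist(lapply(catalog$fragments[actw], `[[`, "yield"),
                      use.names = FALSE)
        base <- rep.int(amp[actw] * elution(tw, rts[actw], sig[actw]), nfr)
        inten <- soft_clamp(base * yld * mnoise(length(yld), noise_cv),
                            sat_ceiling)
        agg <- rowsum(inten, mzs)
        spectra[[k]] <- lp_spectrum(k, 2L, tw, as.numeric(rownames(agg)),
                                    agg[, 1],
                                    polarity = catalog$polarity[1],
                                    precursor_window = pw)
      } else {
        spectra[[k]] <- lp_spectrum(k, 2L, tw, numeric(0), numeric(0),
                                    polarity = catalog$polarity[1],
                                    precursor_window = pw)
      }
    }
  }
  lp_run(spectra, mode = "DIA", windows = windows, sample_id = sample_id)
}

#' Simulate a DDA run with top-N scheduling and active exclusion
#'
#' Each cycle records one MS1 scan and triggers MS2 scans on the most
#' intense eligible precursors: at most `max_precursors` per cycle, only
#' above `trigger_threshold` counts, and a precursor already selected
#' `1 + exclusion_repeats` times within the last `exclusion_window`
#' minutes is actively excluded. When an exclusion list from prior
#' injections is supplied (iterative mode), precursors within `ppm_tol`
#' and `rt_excl_tol` minutes of a prior selection are skipped, so repeat
#' injections dig deeper into the abundance range.
#'
#' @param catalog an `lp_catalog`.
#' @param noise_cv technical noise CV.
#' @param scan_rate acquisition rate (spectra/s) for both levels; 4 by
#'   default (auto-MS/MS cycle pacing).
#' @param gradient_length run length (minutes).
#' @param seed RNG seed.
#' @param max_precursors top-N cap per cycle (5).
#' @param trigger_threshold minimum MS1 intensity to trigger (200 counts).
#' @param exclusion_window active-exclusion span (minutes; 0.08).
#' @param exclusion_repeats repeats allowed before exclusion (1).
#' @param exclusion_state data frame (`mz`, `rt`) of precursors selected
#'   in prior injections, or `NULL`.
#' @param ppm_tol,rt_excl_tol iterative-exclusion tolerances (20 ppm,
#'   0.2 min).
#' @param isolation_width DDA quadrupole isolation width (Th).
#' @param volume_scale intensity scale.
#' @param sample_id run identifier.
#' @return list with `run` (a DDA [lp_run()]), `exclusion_state` (the
#'   input state plus this run's selections) and `fragmented` (indices of
#'   catalog species fragmented at least once).
#' @export
simulate_dda_run <- function(catalog, noise_cv = 0.05, scan_rate = 4,
                             gradient_length = 15.8, seed = 1,
                             max_precursors = 5L, trigger_threshold = 200,
                             exclusion_window = 0.08,
                             exclusion_repeats = 1L,
                             exclusion_state = NULL, ppm_tol = 20,
                             rt_excl_tol = 0.2, isolation_width = 1.3,
                             volume_scale = 1, sample_id = "sim_dda") {
  set.seed(seed)
  amp <- catalog$base_abundance * volume_scale * catalog$group_fold_change
  sig <- catalog$peak_sigma
  rts <- catalog$rt
  n <- nrow(catalog)
  iter_excluded <- rep(FALSE, n)
  if (!is.null(exclusion_state) && nrow(exclusion_state)) {
    for (i in seq_len(n)) {
      dmz <- abs(exclusion_state$mz - catalog$precursor_mz[i]) /
        catalog$precursor_mz[i] * 1e6
      iter_excluded[i] <- any(dmz <= ppm_tol &
                                abs(exclusion_state$rt - rts[i]) <=
                                rt_excl_tol)
    }
  }
  trigger_times <- vector("list", n)   # per-species selection times
  sel_mz <- numeric(0); sel_rt <- numeric(0)
  spectra <- list(); k <- 0L
  t0 <- 0
  end <- gradient_length
  fragmented <- logical(n)
  while (t0 < end) {
    act <- which(abs(rts - t0) <= 5 * sig)
    k <- k + 1L
    if (length(act)) {
      inten <- amp[act] * elution(t0, rts[act], sig[act]) *
        mnoise(length(act), noise_cv)
      agg <- rowsum(inten, catalog$precursor_mz[act])
      spectra[[k]] <- lp_spectrum(k, 1L, t0, as.numeric(rownames(agg)),
                                  agg[, 1],
                                  polarity = catalog$polarity[1])
      # eligibility per species (not per aggregated peak): use each
      # species' own contribution against the trigger threshold
      elig <- act[inten >= trigger_threshold & !iter_excluded[act]]
      if (length(elig)) {
        n_recent <- vapply(elig, function(i) {
          tt <- trigger_times[[i]]
          sum(tt > t0 - exclusion_window)
        }, numeric(1))
        elig <- elig[n_recent < 1 + exclusion_repeats]
      }
      if (length(elig)) {
        o <- order(-inten[match(elig, act)])
        sel <- elig[o][seq_len(min(max_precursors, length(elig)))]
      } else sel <- integer(0)
    } else {
      spectra[[k]] <- lp_spectrum(k, 1L, t0, numeric(0), numeric(0),
                                  polarity = catalog$polarity[1])
      sel <- integer(0)
    }
    dt <- 1 / scan_rate / 60
    tt <- t0 + dt
    for (i in sel) {
      trigger_times[[i]] <- c(trigger_times[[i]], t0)
      sel_mz <- c(sel_mz, catalog$precursor_mz[i])
      sel_rt <- c(sel_rt, t0)
      fragmented[i] <- TRUE
      fr <- catalog$fragments[[i]]
      inten <- amp[i] * elution(tt, rts[i], sig[i]) * fr$yield *
        mnoise(nrow(fr), noise_cv)
      k <- k + 1L
      spectra[[k]] <- lp_spectrum(
        k, 2L, tt, fr$mz, inten, polarity = catalog$polarity[1],
        precursor_window = catalog$precursor_mz[i] +
          c(-1, 1) * isolation_width / 2)
      tt <- tt + dt
    }
    t0 <- t0 + dt * (1 + length(sel))
  }
  run <- lp_run(spectra, mode = "DDA", sample_id = sample_id)
  state <- rbind(exclusion_state, data.frame(mz = sel_mz, rt = sel_rt))
  list(run = run, exclusion_state = state,
       fragmented = which(fragmented))
}

#' Simulate a dilution series
#'
#' One DIA run per injection volume, with intensities scaled by the
#' volume; an optional saturation ceiling makes the largest volumes fall
#' below proportionality, as real detectors do.
#'
#' @param catalog an `lp_catalog`.
#' @param windows an `lp_windows` scheme.
#' @param volumes injection volumes (uL); the classic series is 0.25,
#'   0.5, 1, 2, 4, 8.
#' @param noise_cv technical noise CV (3% by default, replicate-injection
#'   regime).
#' @param seed RNG seed.
#' @param sat_ceiling saturation ceiling; `Inf` disables.
#' @param ... passed to [simulate_dia_run()].
#' @return list with `runs` and a `manifest` data frame.
#' @export
simulate_dilution_series <- function(catalog, windows,
                                     volumes = c(0.25, 0.5, 1, 2, 4, 8),
                                     noise_cv = 0.03, seed = 1,
                                     sat_ceiling = Inf, ...) {
  runs <- lapply(seq_along(volumes), function(i)
    simulate_dia_run(catalog, windows, noise_cv = noise_cv,
                     volume_scale = volumes[i], seed = seed + i,
                     sat_ceiling = sat_ceiling,
                     sample_id = sprintf("dil_%g", volumes[i]), ...))
  manifest <- data.frame(
    sample_id = vapply(runs, `[[`, character(1), "sample_id"),
    path = NA_character_, group = "dilution",
    injection_volume_uL = volumes,
    replicate = seq_along(volumes))
  list(runs = runs, manifest = manifest)
}

#' Simulate a two-group study with QC injections
#'
#' `n_per_group` DIA runs per group; the second group applies the
#' per-species fold changes. QC runs are pooled extracts at the mean of
#' the two group abundances, interleaved as technical controls.
#'
#' @param catalog an `lp_catalog`.
#' @param windows an `lp_windows` scheme.
#' @param true_changes named numeric vector (species name to fold change)
#'   applied to group 2; unnamed species stay at 1.
#' @param n_per_group biological replicates per group (5).
#' @param n_qc pooled QC injections (6).
#' @param noise_cv technical noise CV.
#' @param seed RNG seed.
#' @param groups length-2 group labels.
#' @param ... passed to [simulate_dia_run()].
#' @return list with `runs`, `manifest` and `truth` (species, fold).
#' @export
simulate_two_group <- function(catalog, windows, true_changes = NULL,
                               n_per_group = 5L, n_qc = 6L,
                               noise_cv = 0.10, seed = 1,
                               groups = c("WT", "KO"), ...) {
  fold <- rep(1, nrow(catalog))
  names(fold) <- catalog$species_name
  if (!is.null(true_changes))
    fold[names(true_changes)] <- true_changes
  cat1 <- catalog; cat1$group_fold_change <- 1
  cat2 <- catalog; cat2$group_fold_change <- fold
  catq <- catalog; catq$group_fold_change <- (1 + fold) / 2
  runs <- list(); man <- list(); s <- seed
  for (r in seq_len(n_per_group)) {
    s <- s + 1L
    runs[[length(runs) + 1L]] <- simulate_dia_run(
      cat1, windows, noise_cv = noise_cv, seed = s,
      sample_id = sprintf("%s_%d", groups[1], r), ...)
    man[[length(man) + 1L]] <- data.frame(
      sample_id = sprintf("%s_%d", groups[1], r), path = NA_character_,
      group = groups[1], injection_volume_uL = NA_real_, replicate = r)
  }
  for (r in seq_len(n_per_group)) {
    s <- s + 1L
    runs[[length(runs) + 1L]] <- simulate_dia_run(
      cat2, windows, noise_cv = noise_cv, seed = s,
      sample_id = sprintf("%s_%d", groups[2], r), ...)
    man[[length(man) + 1L]] <- data.frame(
      sample_id = sprintf("%s_%d", groups[2], r), path = NA_character_,
      group = groups[2], injection_volume_uL = NA_real_, replicate = r)
  }
  for (r in seq_len(n_qc)) {
    s <- s + 1L
    runs[[length(runs) + 1L]] <- simulate_dia_run(
      catq, windows, noise_cv = noise_cv, seed = s,
      sample_id = sprintf("QC_%d", r), ...)
    man[[length(man) + 1L]] <- data.frame(
      sample_id = sprintf("QC_%d", r), path = NA_character_,
      group = "QC", injection_volume_uL = NA_real_, replicate = r)
  }
  list(runs = runs, manifest = do.call(rbind, man),
       truth = data.frame(species_name = catalog$species_name,
                          sum_composition = catalog$sum_composition,
                          fold = as.numeric(fold)))
}

#' Simulate a two-group quantification table at the area level
#'
#' The desk-scale counterpart of [simulate_two_group()]: instead of
#' rendering raw scans, each sample draws a realized per-species ion load
#' (shared between the MS1 channel and all fragments of the species, with
#' CV `noise_cv`) and each channel adds small independent detector noise
#' (`ms1_cv` / `ms2_cv`). QC samples are pooled at the mean of the two
#' group abundances. The output has exactly the long format of
#' [quantify_batch()], so the statistics chain runs on it unchanged.
#'
#' @param catalog an `lp_catalog`.
#' @param true_changes named fold-change vector for group 2.
#' @param n_per_group,n_qc design sizes (5 and 6).
#' @param noise_cv shared per-sample, per-species technical CV (0.10).
#' @param ms1_cv,ms2_cv independent per-channel detector CVs.
#' @param seed RNG seed.
#' @param groups length-2 group labels.
#' @param ms2_cv_override optional named vector (species name to CV)
#'   replacing `ms2_cv` for selected species, e.g. to plant noisy
#'   fragment channels.
#' @return list with `quant` (long `lp_quant` table), `manifest`,
#'   `groups` (named vector) and `truth`.
#' @export
simulate_quant_table <- function(catalog, true_changes = NULL,
                                 n_per_group = 5L, n_qc = 6L,
                                 noise_cv = 0.10, ms1_cv = 0.02,
                                 ms2_cv = 0.02, seed = 1,
                                 groups = c("WT", "KO"),
                                 ms2_cv_override = NULL) {
  set.seed(seed)
  fold <- rep(1, nrow(catalog))
  names(fold) <- catalog$species_name
  if (!is.null(true_changes)) fold[names(true_changes)] <- true_changes
  samples <- c(sprintf("%s_%d", groups[1], seq_len(n_per_group)),
               sprintf("%s_%d", groups[2], seq_len(n_per_group)),
               if (n_qc > 0) sprintf("QC_%d", seq_len(n_qc)))
  grp <- c(rep(groups, each = n_per_group), rep("QC", n_qc))
  names(grp) <- samples
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    base <- catalog$base_abundance[i]
    f <- fold[i]
    mean_by_sample <- ifelse(grp == groups[2], base * f,
                             ifelse(grp == "QC", base * (1 + f) / 2, base))
    shared <- mean_by_sample * mnoise(length(samples), noise_cv)
    cv2 <- if (!is.null(ms2_cv_override) &&
               catalog$species_name[i] %in% names(ms2_cv_override))
      ms2_cv_override[[catalog$species_name[i]]] else ms2_cv
    fr <- catalog$fragments[[i]]
    ms1 <- shared * mnoise(length(samples), ms1_cv)
    rows[[length(rows) + 1L]] <- data.frame(
      entry_id = catalog$species_name[i],
      sum_composition = catalog$sum_composition[i],
      adduct = catalog$adduct[i], polarity = catalog$polarity[i],
      channel = "MS1", sample = samples, area = ms1, filled = FALSE,
      area_detected = ms1)
    for (j in seq_len(nrow(fr))) {
      aj <- shared * fr$yield[j] * mnoise(length(samples), cv2)
      rows[[length(rows) + 1L]] <- data.frame(
        entry_id = catalog$species_name[i],
        sum_composition = catalog$sum_composition[i],
        adduct = catalog$adduct[i], polarity = catalog$polarity[i],
        channel = sprintf("%.4f", fr$mz[j]), sample = samples,
        area = aj, filled = FALSE, area_detected = aj)
    }
  }
  quant <- do.call(rbind, rows)
  class(quant) <- c("lp_quant", "data.frame")
  manifest <- data.frame(sample_id = samples, path = NA_character_,
                         group = grp, injection_volume_uL = NA_real_,
                         replicate = c(seq_len(n_per_group),
                                       seq_len(n_per_group),
                                       seq_len(n_qc)))
  list(quant = quant, manifest = manifest, groups = grp,
       truth = data.frame(species_name = catalog$species_name,
                          sum_composition = catalog$sum_composition,
                          fold = as.numeric(fold)))
}
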