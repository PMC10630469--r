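# ---- targeted DIA quantification ----------------------------------------
#
# DIA severs the precursor-product link, so quantification is targeted:
# each library entry names its precursor, its fragments and a retention
# time, and extraction reads the MS1 trace plus per-fragment MS2 traces
# from the single isolation window whose core contains the precursor.
# Fragment peaks must co-elute with the chosen MS1 apex, which restores
# the precursor-product link through the library RT.

# Choose the detected peak nearest `rt` within +/- gate; NULL when none.
pick_peak <- function(peaks, rt, gate) {
  if (!nrow(peaks)) return(NULL)
  d <- abs(peaks$rt_apex - rt)
  ok <- which(d <= gate)
  if (!length(ok)) return(NULL)
  peaks[ok[which.min(d[ok])], , drop = FALSE]
}

# Forced trapezoid over [rt - w, rt + w] on a trace; 0 on a blank region.
forced_area <- function(trace, rt, w) {
  seg <- which(trace$rt >= rt - w & trace$rt <= rt + w)
  if (length(seg) < 2L) return(0)
  x <- trace$rt[seg]; y <- trace$intensity[seg]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Quantify one library entry in one DIA run
#'
#' The MS1 XIC is extracted at `precursor_mz +/- ms1to1`; the precursor is
#' assigned to its core window and per-fragment MS2 XICs are extracted
#' from that window at `fragment mz +/- ms2to1`. Candidate peaks come from
#' [detect_chrom_peaks()]; the MS1 peak nearest the library RT within
#' `+/- rt_shift` is chosen first, and fragment peaks must then co-elute
#' with the chosen MS1 apex within `+/- rt_shift / 2`. Channels with no
#' qualifying peak are `NA` with `filled = FALSE`.
#'
#' @param run a DIA [lp_run()].
#' @param entry an [library_entry()].
#' @param windows an `lp_windows` scheme (defaults to `run$windows`).
#' @param params an [match_params()] object.
#' @param .index precomputed [run_index()] (internal fast path).
#' @return a quant record: list with `entry_id`, `sample_id`, `ms1_area`,
#'   `ms1_filled`, `rt_observed`, `n_points_ms1`, `fragments` (data frame
#'   `mz`, `area`, `filled`, `n_points`).
#' @export
quantify_entry <- function(run, entry, windows = run$windows,
                           params = match_params(rt_shift = 20),
                           .index = NULL) {
  if (run$mode != "DIA") stop("quantify_entry needs a DIA run")
  if (is.null(windows) || !nrow(windows))
    stop("no isolation-window scheme available")
  if (entry$precursor_mz < windows$core_low[1] ||
      entry$precursor_mz > windows$core_high[nrow(windows)])
    stop("precursor ", entry$precursor_mz, " of ", entry$species_name,
         " lies outside the window scheme")
  gate <- rt_shift_min(params)
  if (is.null(.index)) .index <- run_index(run)
  ms1_trace <- xic_from_table(.index$ms1, entry$precursor_mz, params$ms1to1)
  win <- assign_window(entry$precursor_mz, windows)
  ms1_pks <- detect_chrom_peaks(ms1_trace)
  ms1_pick <- pick_peak(ms1_pks, entry$rt, gate)
  ms1_area <- NA_real_; rt_obs <- NA_real_; np1 <- 0L
  anchor_rt <- entry$rt
  if (!is.null(ms1_pick)) {
    ms1_area <- ms1_pick$area; rt_obs <- ms1_pick$rt_apex
    np1 <- ms1_pick$n_points
    anchor_rt <- ms1_pick$rt_apex
  }
  frag <- entry$fragments
  f_area <- rep(NA_real_, nrow(frag))
  f_np <- integer(nrow(frag))
  for (j in seq_len(nrow(frag))) {
    tr <- xic_from_table(.index$ms2[[win]], frag$mz[j], params$ms2to1)
    pks <- detect_chrom_peaks(tr)
    # co-elution with the MS1 apex (or the library RT when MS1 is absent)
    pick <- pick_peak(pks, anchor_rt,
                      if (is.null(ms1_pick)) gate else gate / 2)
    if (!is.null(pick)) {
      f_area[j] <- pick$area
      f_np[j] <- pick$n_points
    }
  }
  list(entry_id = entry$species_name, sample_id = run$sample_id,
       ms1_area = ms1_area, ms1_filled = FALSE, rt_observed = rt_obs,
       n_points_ms1 = np1,
       fragments = data.frame(mz = frag$mz, area = f_area, filled = FALSE,
                              n_points = f_np),
       window = win)
}

#' Fill missing channels by forced integration
#'
#' Channels that [quantify_entry()] left `NA` are re-integrated by a
#' forced trapezoid over `[rt - w, rt + w]` with `w = rt_shift`, anchored
#' at the observed MS1 apex when available and at the library RT
#' otherwise. A blank region yields area 0. Channels already quantified
#' are untouched; filled channels are flagged.
#'
#' @param run,entry,windows,params,.index as in [quantify_entry()].
#' @param record a quant record from [quantify_entry()].
#' @return the record with `NA` channels filled and flagged.
#' @export
fill_missing <- function(run, entry, record, windows = run$windows,
                         params = match_params(rt_shift = 20),
                         .index = NULL) {
  w <- rt_shift_min(params)
  if (is.null(.index)) .index <- run_index(run)
  anchor <- if (!is.na(record$rt_observed)) record$rt_observed else entry$rt
  if (is.na(record$ms1_area)) {
    tr <- xic_from_table(.index$ms1, entry$precursor_mz, params$ms1to1)
    record$ms1_area <- forced_area(tr, anchor, w)
    record$ms1_filled <- TRUE
  }
  need <- which(is.na(record$fragments$area))
  if (length(need)) {
    win <- record$window
    for (j in need) {
      tr <- xic_from_table(.index$ms2[[win]], record$fragments$mz[j],
                           params$ms2to1)
      record$fragments$area[j] <- forced_area(tr, anchor, w)
      record$fragments$filled[j] <- TRUE
    }
  }
  record
}

#' Quantify a library across a batch of DIA runs
#'
#' Produces the long-format quantification matrix over all
#' `entries x samples x channels` (the MS1 channel plus one channel per
#' library fragment). When `outdir` is given, two tables are written:
#' `quant_all.tsv` with detected-peak areas only (missing cells blank) and
#' `quant_fill_all.tsv` where missing cells are additionally filled by
#' forced integration. Detected cells are identical between the two.
#'
#' @param runs list of DIA [lp_run()] objects.
#' @param library list of [library_entry()] objects.
#' @param windows an `lp_windows` scheme.
#' @param params an [match_params()] object.
#' @param fill logical; also compute filled values.
#' @param outdir optional output directory for the two TSVs.
#' @return data frame of class `"lp_quant"`: `entry_id`,
#'   `sum_composition`, `adduct`, `polarity`, `channel`, `sample`, `area`,
#'   `filled` (plus `area_detected` preserving the unfilled value).
#' @export
quantify_batch <- function(runs, library, windows,
                           params = match_params(rt_shift = 20),
                           fill = TRUE, outdir = NULL) {
  if (inherits(runs, "lp_run")) runs <- list(runs)
  pol_runs <- vapply(runs, run_polarity, character(1))
  pol_lib <- unique(vapply(library, `[[`, character(1), "polarity"))
  if (length(pol_lib) > 1L)
    stop("library mixes polarities; split by polarity before quantifying")
  if (any(!is.na(pol_runs) & pol_runs != pol_lib))
    stop("run polarity does not match library polarity")
  rows <- list()
  for (run in runs) {
    idx <- run_index(run)
    for (entry in library) {
      rec <- quantify_entry(run, entry, windows, params, .index = idx)
      det_ms1 <- rec$ms1_area
      det_frag <- rec$fragments$area
      if (fill)
        rec <- fill_missing(run, entry, rec, windows, params, .index = idx)
      rows[[length(rows) + 1L]] <- data.frame(
        entry_id = entry$species_name,
        sum_composition = entry$sum_composition,
        adduct = entry$adduct, polarity = entry$polarity,
        channel = c("MS1", sprintf("%.4f", entry$fragments$mz)),
        sample = run$sample_id,
        area = c(rec$ms1_area, rec$fragments$area),
        filled = c(rec$ms1_filled, rec$fragments$filled),
        area_detected = c(det_ms1, det_frag))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lp_quant", "data.frame")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    qa <- out[, c("entry_id", "sum_composition", "adduct", "polarity",
                  "channel", "sample", "area_detected")]
    names(qa)[names(qa) == "area_detected"] <- "area"
    utils::write.table(qa, file.path(outdir, "quant_all.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    qf <- out[, c("entry_id", "sum_composition", "adduct", "polarity",
                  "channel", "sample", "area", "filled")]
    utils::write.table(qf, file.path(outdir, "quant_fill_all.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  }
  out
}
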