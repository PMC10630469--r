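# ---- peak tables: fast indexed access to a run's peaks ------------------

# Flatten the peaks of a set of scans into one table sorted by m/z, keeping
# the scan each peak came from.  XIC extraction is then a binary search on
# the m/z column instead of a sweep over every spectrum.
build_peak_table <- function(spectra, scan_idx) {
  rts <- vapply(spectra[scan_idx], `[[`, numeric(1), "rt")
  nmz <- vapply(spectra[scan_idx], function(s) length(s$mz), integer(1))
  mz <- unlist(lapply(spectra[scan_idx], `[[`, "mz"), use.names = FALSE)
  it <- unlist(lapply(spectra[scan_idx], `[[`, "intensity"), use.names = FALSE)
  scan <- rep.int(seq_along(scan_idx), nmz)
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; it <- it[o]; scan <- scan[o]
  }
  list(mz = mz, intensity = it, scan = scan, rt = rts,
       n_scans = length(scan_idx))
}

# One table per extraction channel: MS1, and each DIA isolation window.
# Window membership of an MS2 scan is decided by its extended bounds.
run_index <- function(run) {
  lv <- vapply(run$spectra, `[[`, integer(1), "ms_level")
  idx <- list(ms1 = build_peak_table(run$spectra, which(lv == 1L)))
  if (!is.null(run$windows) && nrow(run$windows)) {
    ms2 <- which(lv == 2L)
    if (length(ms2)) {
      lows <- vapply(run$spectra[ms2], function(s)
        s$precursor_window[1], numeric(1))
      highs <- vapply(run$spectra[ms2], function(s)
        s$precursor_window[2], numeric(1))
      idx$ms2 <- lapply(seq_len(nrow(run$windows)), function(w) {
        hit <- abs(lows - run$windows$ext_low[w]) < 1e-6 &
          abs(highs - run$windows$ext_high[w]) < 1e-6
        build_peak_table(run$spectra, ms2[hit])
      })
    } else idx$ms2 <- rep(list(build_peak_table(run$spectra, integer(0))),
                          nrow(run$windows))
  }
  idx
}

xic_from_table <- function(tbl, target_mz, tol) {
  intensity <- numeric(tbl$n_scans)
  if (length(tbl$mz)) {
    i1 <- findInterval(target_mz - tol, tbl$mz, left.open = TRUE) + 1L
    i2 <- findInterval(target_mz + tol, tbl$mz)
    if (i2 >= i1) {
      sel <- i1:i2
      agg <- rowsum(tbl$intensity[sel], tbl$scan[sel])
      intensity[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  structure(data.frame(rt = tbl$rt, intensity = intensity),
            target_mz = target_mz, tol = tol, class = c("lp_xic", "data.frame"))
}

#' Extract an ion chromatogram
#'
#' For every qualifying scan the trace records the summed intensity of all
#' peaks within `target_mz +/- tol`; scans with no peak in range contribute
#' an explicit zero, so the trace has exactly one point per source scan.
#'
#' @param run an [lp_run()].
#' @param target_mz target m/z (Th).
#' @param tol absolute extraction tolerance (Th), e.g. 0.005 for MS1 and
#'   0.01 for MS2.
#' @param ms_level 1 or 2.
#' @param window_id for MS2 extraction from a DIA run, the index of the
#'   isolation window whose scans should be used.
#' @return a data frame (class `"lp_xic"`) with columns `rt`, `intensity`.
#' @export
extract_xic <- function(run, target_mz, tol, ms_level = 1L,
                        window_id = NULL) {
  stopifnot(tol > 0)
  if (ms_level == 1L) {
    lv <- vapply(run$spectra, `[[`, integer(1), "ms_level")
    tbl <- build_peak_table(run$spectra, which(lv == 1L))
  } else {
    if (run$mode == "DIA") {
      if (is.null(window_id))
        stop("MS2 extraction from a DIA run needs window_id")
      if (is.null(run$windows) || window_id < 1 ||
          window_id > nrow(run$windows))
        stop("window_id ", window_id, " not present in run")
      lv <- vapply(run$spectra, `[[`, integer(1), "ms_level")
      ms2 <- which(lv == 2L)
      hit <- vapply(run$spectra[ms2], function(s)
        abs(s$precursor_window[1] - run$windows$ext_low[window_id]) < 1e-6 &&
        abs(s$precursor_window[2] - run$windows$ext_high[window_id]) < 1e-6,
        logical(1))
      tbl <- build_peak_table(run$spectra, ms2[hit])
    } else {
      lv <- vapply(run$spectra, `[[`, integer(1), "ms_level")
      tbl <- build_peak_table(run$spectra, which(lv == 2L))
    }
  }
  xic_from_table(tbl, target_mz, tol)
}

# ---- chromatographic peak detection -------------------------------------

#' Detect and integrate chromatographic peaks on an XIC trace
#'
#' Apexes are local maxima (above `noise_floor`) of a lightly smoothed
#' copy of the trace — a short running mean that keeps multiplicative
#' detector noise from fragmenting one elution peak into many. From each
#' apex the boundaries walk outward along the smoothed trace to the
#' nearest valley or to the first point at or below the floor: the walk
#' tracks its running minimum and stops once the trace rises clearly
#' above it again, placing the boundary at the minimum. The area is the
#' trapezoidal integral of the *raw* (baseline-unsubtracted) trace
#' between the boundaries, in intensity-minutes, and the reported height
#' and apex come from the raw trace. Peaks narrower than `min_points`
#' scans are dropped; overlapping detections of one region are merged
#' into the strongest.
#'
#' @param trace an `lp_xic` data frame (`rt`, `intensity`).
#' @param min_points minimum number of scans across a peak (>= 3).
#' @param noise_floor intensity below which the trace is considered blank.
#' @param smooth running-mean half-width in scans (0 disables smoothing).
#' @return data frame with one row per peak (`rt_apex`, `rt_start`,
#'   `rt_end`, `height`, `area`, `n_points`), sorted by area descending.
#' @export
detect_chrom_peaks <- function(trace, min_points = 3L, noise_floor = 0,
                               smooth = 2L) {
  stopifnot(min_points >= 3L)
  y <- trace$intensity; x <- trace$rt; n <- length(y)
  empty <- data.frame(rt_apex = numeric(0), rt_start = numeric(0),
                      rt_end = numeric(0), height = numeric(0),
                      area = numeric(0), n_points = integer(0))
  if (n < min_points || all(y <= noise_floor)) return(empty)
  ys <- if (smooth > 0L && n > 2L * smooth + 1L) {
    k <- 2L * smooth + 1L
    as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  } else y
  ys[is.na(ys)] <- y[is.na(ys)]
  is_max <- ys > noise_floor & ys >= c(-Inf, ys[-n]) & ys > c(ys[-1], -Inf)
  apexes <- which(is_max)
  if (!length(apexes)) return(empty)
  apexes <- apexes[order(-ys[apexes])]
  claimed <- logical(n)
  walk <- function(i, d, height) {
    j <- i; minj <- i
    repeat {
      nxt <- j + d
      if (nxt < 1L || nxt > n) return(minj)
      if (ys[nxt] <= noise_floor) return(nxt)      # first sub-floor point
      if (ys[nxt] < ys[minj]) { j <- nxt; minj <- nxt; next }
      if (ys[nxt] > ys[minj] + pmax(0.1 * ys[minj], 0.005 * height))
        return(minj)                                # valley: rising again
      j <- nxt                                      # plateau; keep walking
    }
  }
  rows <- list()
  for (i in apexes) {
    if (claimed[i]) next
    lo <- walk(i, -1L, ys[i])
    hi <- walk(i, +1L, ys[i])
    np <- hi - lo + 1L
    # boundary points may be shared with a neighbouring peak (the common
    # valley); the interior must be unclaimed
    if (np < min_points || any(claimed[(lo + 1L):(hi - 1L)])) next
    claimed[lo:hi] <- TRUE
    seg <- lo:hi
    apx <- seg[which.max(y[seg])]
    area <- sum(diff(x[seg]) * (y[seg][-1] + y[seg][-length(seg)]) / 2)
    rows[[length(rows) + 1L]] <-
      data.frame(rt_apex = x[apx], rt_start = x[lo], rt_end = x[hi],
                 height = y[apx], area = area, n_points = np)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$area), , drop = FALSE]
}

# ---- MS1 feature detection ----------------------------------------------

#' Detect MS1 features on a run
#'
#' Greedy mass-trace construction: the most intense unclaimed MS1 peak
#' seeds a trace, which claims the nearest unclaimed peak within
#' `+/- tol` in every MS1 scan. Each trace is then passed through
#' [detect_chrom_peaks()] and every chromatographic peak becomes one
#' feature whose m/z is the intensity-weighted mean of the claimed peaks
#' inside the peak boundaries. No deisotoping is performed: isotope
#' satellites are reported as separate features, which is deliberate —
#' downstream window design weighs quadrupole load, to which isotopes
#' contribute.
#'
#' @param run an [lp_run()] with MS1 scans.
#' @param tol mass-trace tolerance (Th); default 0.005.
#' @param min_points,noise_floor passed to [detect_chrom_peaks()].
#' @return data frame of features (`mz`, `rt_apex`, `height`, `area`,
#'   `density`), sorted by m/z; `density` is `NA` until
#'   [compute_density()] fills it.
#' @export
detect_ms1_features <- function(run, tol = 0.005, min_points = 3L,
                                noise_floor = 0) {
  lv <- vapply(run$spectra, `[[`, integer(1), "ms_level")
  ms1 <- which(lv == 1L)
  empty <- data.frame(mz = numeric(0), rt_apex = numeric(0),
                      height = numeric(0), area = numeric(0),
                      density = numeric(0))
  if (!length(ms1)) return(empty)
  tbl <- build_peak_table(run$spectra, ms1)
  if (!length(tbl$mz)) return(empty)
  claimed <- logical(length(tbl$mz))
  ord_int <- order(-tbl$intensity)
  feats <- list(); k <- 0L
  for (seed in ord_int) {
    if (claimed[seed]) next
    smz <- tbl$mz[seed]
    i1 <- findInterval(smz - tol, tbl$mz, left.open = TRUE) + 1L
    i2 <- findInterval(smz + tol, tbl$mz)
    cand <- (i1:i2)[!claimed[i1:i2]]
    # at most one peak per scan: keep the one closest to the seed m/z
    if (length(cand) > 1L) {
      d <- abs(tbl$mz[cand] - smz)
      cand <- cand[order(tbl$scan[cand], d)]
      cand <- cand[!duplicated(tbl$scan[cand])]
    }
    claimed[cand] <- TRUE
    y <- numeric(tbl$n_scans)
    y[tbl$scan[cand]] <- tbl$intensity[cand]
    trace <- structure(data.frame(rt = tbl$rt, intensity = y),
                       class = c("lp_xic", "data.frame"))
    pks <- detect_chrom_peaks(trace, min_points, noise_floor)
    if (!nrow(pks)) next
    for (p in seq_len(nrow(pks))) {
      inpk <- cand[tbl$rt[tbl$scan[cand]] >= pks$rt_start[p] &
                     tbl$rt[tbl$scan[cand]] <= pks$rt_end[p]]
      if (!length(inpk)) next
      wmz <- sum(tbl$mz[inpk] * tbl$intensity[inpk]) /
        sum(tbl$intensity[inpk])
      k <- k + 1L
      feats[[k]] <- data.frame(mz = wmz, rt_apex = pks$rt_apex[p],
                               height = pks$height[p], area = pks$area[p],
                               density = NA_real_)
    }
  }
  if (!k) return(empty)
  out <- do.call(rbind, feats)
  out[order(out$mz), , drop = FALSE]
}

#' Write a feature table
#' @param features data frame from [detect_ms1_features()].
#' @param path output TSV path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
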