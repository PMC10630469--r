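# ---- in-memory run model -----------------------------------------------

#' Construct a single centroided spectrum
#'
#' The spectrum is the atomic unit of the in-memory run model. Peaks are
#' stored as parallel `mz` / `intensity` vectors sorted by ascending m/z;
#' duplicate m/z values within one spectrum are not allowed.
#'
#' @param index ordinal position of the scan in the run (1-based).
#' @param ms_level 1 (survey) or 2 (product-ion scan).
#' @param rt retention time in minutes.
#' @param mz,intensity numeric vectors of equal length; `mz > 0`,
#'   `intensity >= 0`.
#' @param polarity `"positive"` or `"negative"`.
#' @param precursor_window for MS2 scans, the `[low, high]` m/z bounds of
#'   the quadrupole isolation window (the *extended* bounds for DIA).
#' @return an object of class `"lp_spectrum"`.
#' @export
lp_spectrum <- function(index, ms_level, rt, mz, intensity,
                        polarity = "positive", precursor_window = NULL) {
  stopifnot(length(mz) == length(intensity), rt >= 0,
            ms_level %in% c(1L, 2L))
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (any(mz <= 0)) stop("spectrum m/z values must be positive")
    if (any(intensity < 0)) stop("spectrum intensities must be non-negative")
    if (anyDuplicated(mz))
      stop("duplicate m/z within one spectrum (scan ", index, ")")
  }
  if (ms_level == 2L) {
    if (is.null(precursor_window) || length(precursor_window) != 2L ||
        precursor_window[1] >= precursor_window[2])
      stop("MS2 scan ", index, " needs a valid precursor isolation window")
  }
  structure(list(index = as.integer(index), ms_level = as.integer(ms_level),
                 rt = as.numeric(rt), polarity = polarity,
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 precursor_window = precursor_window),
            class = "lp_spectrum")
}

#' Construct an acquisition run
#'
#' @param spectra list of [lp_spectrum()] objects, ordered by retention
#'   time (ties broken by index).
#' @param mode `"DDA"` or `"DIA"`.
#' @param windows for DIA runs, a window-scheme data frame as produced by
#'   [partition_windows()] / [extend_windows()]; `NULL` for DDA.
#' @param sample_id sample identifier carried into quantification tables.
#' @return an object of class `"lp_run"`.
#' @export
lp_run <- function(spectra, mode = c("DDA", "DIA"), windows = NULL,
                   sample_id = "sample") {
  mode <- match.arg(mode)
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (is.unsorted(rts)) stop("spectra must be ordered by retention time")
  structure(list(spectra = spectra, mode = mode, windows = windows,
                 sample_id = sample_id),
            class = "lp_run")
}

#' @export
print.lp_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat(sprintf("<lp_run '%s'> %s, %d spectra (%d MS1 / %d MS2)",
              x$sample_id, x$mode, length(lv), sum(lv == 1L), sum(lv == 2L)))
  if (!is.null(x$windows))
    cat(sprintf(", %d isolation windows", nrow(x$windows)))
  rng <- range(vapply(x$spectra, `[[`, numeric(1), "rt"))
  cat(sprintf(", RT %.2f-%.2f min\n", rng[1], rng[2]))
  invisible(x)
}

run_polarity <- function(run) {
  pol <- unique(vapply(run$spectra, `[[`, character(1), "polarity"))
  if (length(pol) > 1L) stop("run mixes polarities")
  if (length(pol)) pol else NA_character_
}

# A run is DIA iff at least two MS2 scans share identical isolation-window
# bounds spanning more than 2 Th (DDA isolation is ~1.3 Th and precursor-
# specific); otherwise DDA.
detect_run_mode <- function(spectra) {
  wins <- lapply(spectra, function(s)
    if (s$ms_level == 2L) s$precursor_window else NULL)
  wins <- wins[!vapply(wins, is.null, logical(1))]
  if (!length(wins)) return("DDA")
  key <- vapply(wins, function(w) sprintf("%.6f_%.6f", w[1], w[2]), character(1))
  span <- vapply(wins, diff, numeric(1))
  wide <- span > 2
  if (any(table(key[wide]) >= 2L)) "DIA" else "DDA"
}

# Rebuild the window scheme from the distinct MS2 isolation bounds of a DIA
# run.  Core boundaries are recovered at the midpoints of adjacent-window
# overlaps, which reproduces the original scheme when the edge extension is
# constant.
reconstruct_windows <- function(spectra) {
  wins <- unique(do.call(rbind, lapply(spectra, function(s)
    if (s$ms_level == 2L) s$precursor_window else NULL)))
  if (is.null(wins) || !nrow(wins)) return(NULL)
  wins <- wins[order(wins[, 1]), , drop = FALSE]
  n <- nrow(wins)
  ext_low <- wins[, 1]; ext_high <- wins[, 2]
  if (n == 1L) {
    core_low <- ext_low; core_high <- ext_high
  } else {
    cuts <- (ext_high[-n] + ext_low[-1]) / 2
    e <- (ext_high[-n] - ext_low[-1]) / 2     # per-gap extension estimate
    core_low <- c(ext_low[1] + e[1], cuts)
    core_high <- c(cuts, ext_high[n] - e[n - 1L])
  }
  data.frame(index = seq_len(n), core_low = core_low, core_high = core_high,
             ext_low = ext_low, ext_high = ext_high,
             summed_density = NA_real_)
}

# ---- mzML input/output --------------------------------------------------

#' Read a centroided mzML file into a run
#'
#' Retention times are converted to minutes. For DIA runs the isolation-
#' window scheme is reconstructed from the distinct MS2 precursor windows,
#' sorted by lower bound. Mode is detected automatically: a run is DIA iff
#' two or more MS2 scans share identical isolation bounds wider than 2 Th.
#'
#' @param path path to an mzML file (plain or indexed), centroided.
#' @param sample_id sample identifier; defaults to the file base name.
#' @return an [lp_run()] object.
#' @export
read_mzml <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  if (!nrow(hd))
    return(lp_run(list(), mode = "DDA", sample_id = sample_id))
  if (any(!is.na(hd$centroided) & !hd$centroided))
    stop("profile-mode spectra in ", path,
         ": centroid the data (e.g. with msconvert peakPicking) first")
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- vector("list", nrow(hd))
  for (i in seq_len(nrow(hd))) {
    lev <- hd$msLevel[i]
    pw <- NULL
    if (lev == 2L) {
      tgt <- hd$isolationWindowTargetMZ[i]
      lo <- hd$isolationWindowLowerOffset[i]
      up <- hd$isolationWindowUpperOffset[i]
      if (is.na(tgt) || is.na(lo) || is.na(up))
        stop("MS2 scan ", i, " in ", path, " has no isolation window")
      pw <- c(tgt - lo, tgt + up)
    }
    pol <- if (!is.null(hd$polarity) && !is.na(hd$polarity[i]) &&
               hd$polarity[i] == 0L) "negative" else "positive"
    spectra[[i]] <- lp_spectrum(i, lev, hd$retentionTime[i] / 60,
                                pk[[i]][, 1], pk[[i]][, 2],
                                polarity = pol, precursor_window = pw)
  }
  mode <- detect_run_mode(spectra)
  windows <- if (mode == "DIA") reconstruct_windows(spectra) else NULL
  lp_run(spectra, mode = mode, windows = windows, sample_id = sample_id)
}

#' Write a run to mzML
#'
#' Standard-conformant mzML (written through the proteowizard-backed
#' serializer) that round-trips through [read_mzml()] within numeric
#' tolerance.
#'
#' @param run an [lp_run()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  n <- length(run$spectra)
  if (!dir.exists(dirname(path))) stop("unwritable path: ", path)
  if (n == 0L) {
    # serialize a minimal zero-spectrum mzML by hand; the backend
    # serializer needs at least one scan
    writeLines(c(
      '<?xml version="1.0" encoding="utf-8"?>',
      '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">',
      sprintf('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="%s">',
              run$sample_id),
      '<cvList count="1"><cv id="MS" fullName="PSI-MS" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
      '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/></fileContent></fileDescription>',
      '<softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/></software></softwareList>',
      '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>',
      '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
      sprintf('<run id="%s" defaultInstrumentConfigurationRef="IC">',
              run$sample_id),
      '<spectrumList count="0" defaultDataProcessingRef="dp">',
      '</spectrumList>', '</run>', '</mzML>', '</indexedmzML>'), path)
    return(invisible(path))
  }
  na_r <- rep(NA_real_, n); na_i <- rep(NA_integer_, n)
  hd <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(run$spectra, `[[`, integer(1), "ms_level"),
    polarity = ifelse(vapply(run$spectra, `[[`, character(1),
                             "polarity") == "positive", 1L, 0L),
    peaksCount = vapply(run$spectra, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(run$spectra, function(s)
      sum(s$intensity), numeric(1)),
    retentionTime = vapply(run$spectra, `[[`, numeric(1), "rt") * 60,
    basePeakMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(run$spectra, function(s)
      if (length(s$mz)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = na_r, ionisationEnergy = rep(0, n),
    lowMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = na_i, precursorMZ = na_r,
    precursorCharge = na_i, precursorIntensity = na_r,
    mergedScan = na_i, mergedResultScanNum = na_i,
    mergedResultStartScanNum = na_i, mergedResultEndScanNum = na_i,
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = na_r,
    isolationWindowTargetMZ = na_r, isolationWindowLowerOffset = na_r,
    isolationWindowUpperOffset = na_r,
    scanWindowLowerLimit = na_r, scanWindowUpperLimit = na_r,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- run$spectra[[i]]
    if (s$ms_level == 2L) {
      ctr <- mean(s$precursor_window)
      hd$precursorMZ[i] <- ctr
      hd$precursorCharge[i] <- 1L
      hd$precursorIntensity[i] <- 0
      hd$isolationWindowTargetMZ[i] <- ctr
      hd$isolationWindowLowerOffset[i] <- ctr - s$precursor_window[1]
      hd$isolationWindowUpperOffset[i] <- s$precursor_window[2] - ctr
    }
  }
  pks <- lapply(run$spectra, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  suppressWarnings(
    mzR::writeMSData(pks, file = path, header = hd, outformat = "mzml"))
  invisible(path)
}

# ---- sample manifests ---------------------------------------------------

#' Read a sample manifest
#'
#' Tab-separated, with header columns `sample_id`, `path`, `group`,
#' `injection_volume_uL`, `replicate`. `injection_volume_uL` may be empty
#' for designs without a dilution factor.
#'
#' @param path TSV file path.
#' @return a validated `data.frame` with one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(m)) stop("manifest is empty: ", path)
  need <- c("sample_id", "path", "group", "injection_volume_uL", "replicate")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  vol <- m$injection_volume_uL
  if (is.character(vol)) {
    vol[vol == ""] <- NA
    v <- suppressWarnings(as.numeric(vol))
    if (any(!is.na(vol) & is.na(v)))
      stop("non-numeric injection_volume_uL in manifest")
    m$injection_volume_uL <- v
  }
  if (any(!is.na(m$injection_volume_uL) & m$injection_volume_uL <= 0))
    stop("injection_volume_uL must be positive")
  m
}

#' Write a sample manifest
#' @param manifest data frame as returned by [read_manifest()].
#' @param path output TSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
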