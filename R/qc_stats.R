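# ---- QC, fragment selection and differential abundance ------------------

#' Statistical thresholds of the workflow
#'
#' @param rsd_pass RSD (%) below which a channel is quantifiable (30).
#' @param rsd_tight RSD (%) bounding the best reproducibility class (20).
#' @param r2_ms1_min minimum Pearson R-squared between a fragment and its
#'   MS1 precursor (0.8).
#' @param linearity_max_volume largest injection volume (uL) entering the
#'   linearity fit; signal saturates above it (4).
#' @param fc_threshold fold-change threshold for significance (2).
#' @param fdr_threshold BH-adjusted q-value threshold (0.05).
#' @return a list of class `"lp_stat_params"`.
#' @export
stat_params <- function(rsd_pass = 30, rsd_tight = 20, r2_ms1_min = 0.8,
                        linearity_max_volume = 4, fc_threshold = 2,
                        fdr_threshold = 0.05) {
  stopifnot(rsd_tight > 0, rsd_tight < rsd_pass, r2_ms1_min > 0,
            r2_ms1_min <= 1, fc_threshold >= 1, fdr_threshold > 0,
            fdr_threshold <= 1)
  structure(list(rsd_pass = rsd_pass, rsd_tight = rsd_tight,
                 r2_ms1_min = r2_ms1_min,
                 linearity_max_volume = linearity_max_volume,
                 fc_threshold = fc_threshold,
                 fdr_threshold = fdr_threshold),
            class = "lp_stat_params")
}

#' Relative standard deviation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. Fewer than
#' two non-missing values make the channel non-quantifiable and return
#' `NA`.
#'
#' @param values numeric vector of peak areas.
#' @return RSD in percent, or `NA_real_`.
#' @export
rsd <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  100 * stats::sd(v) / mean(v)
}

#' Squared Pearson correlation
#'
#' Complete pairs only; fewer than three pairs or zero variance on either
#' side leaves the correlation undefined (`NA`), which fails any
#' greater-than-threshold gate.
#'
#' @param x,y numeric vectors of equal length.
#' @return R-squared in `[0, 1]`, or `NA_real_`.
#' @export
pearson_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# channel key within a quant table
chan_key <- function(q) paste(q$entry_id, q$adduct, q$polarity, q$channel,
                              sep = "\r")

# Wide numeric matrix (channels x samples) from the long quant table.
# `use` selects filled or detected-only areas.
quant_wide <- function(q, samples = unique(q$sample),
                       use = c("filled", "detected")) {
  use <- match.arg(use)
  area <- if (use == "detected") {
    if ("area_detected" %in% names(q)) q$area_detected
    else ifelse(q$filled, NA_real_, q$area)
  } else q$area
  keys <- chan_key(q)
  ukey <- unique(keys)
  m <- matrix(NA_real_, length(ukey), length(samples),
              dimnames = list(ukey, samples))
  sel <- q$sample %in% samples
  m[cbind(match(keys[sel], ukey), match(q$sample[sel], samples))] <- area[sel]
  m
}

#' Per-channel QC statistics
#'
#' RSD is computed over the QC samples using detected (unfilled) values
#' only, so forced integration cannot flatter reproducibility. Fragment
#' channels additionally get the Pearson R-squared of their filled areas
#' against the entry's MS1 channel across the study samples.
#'
#' @param q long quant table ([quantify_batch()] output or equivalent).
#' @param qc_samples character vector of QC sample ids.
#' @param params an [stat_params()] object.
#' @param study_samples samples over which fragment-MS1 correlation is
#'   computed; defaults to all non-QC samples.
#' @return data frame with one row per channel: `entry_id`, `adduct`,
#'   `polarity`, `sum_composition`, `channel`, `rsd_qc`, `rsd_category`,
#'   `r2_vs_ms1`, `median_area`.
#' @export
channel_stats <- function(q, qc_samples, params = stat_params(),
                          study_samples = NULL) {
  if (is.null(study_samples))
    study_samples <- setdiff(unique(q$sample), qc_samples)
  meta <- q[!duplicated(chan_key(q)),
            c("entry_id", "adduct", "polarity", "sum_composition",
              "channel")]
  rownames(meta) <- NULL
  wqc <- quant_wide(q, qc_samples, use = "detected")
  wst <- if (length(study_samples))
    quant_wide(q, study_samples, use = "filled") else NULL
  rsd_qc <- apply(wqc, 1, rsd)
  cat_of <- function(r) {
    if (is.na(r)) "non_quantifiable"
    else if (r < params$rsd_tight) "<20"
    else if (r < params$rsd_pass) "20-30"
    else ">30"
  }
  meta$rsd_qc <- as.numeric(rsd_qc)
  meta$rsd_category <- vapply(meta$rsd_qc, cat_of, character(1))
  # fragment vs MS1 correlation over study samples, per entry
  meta$r2_vs_ms1 <- NA_real_
  if (!is.null(wst)) {
    ekey <- paste(meta$entry_id, meta$adduct, meta$polarity, sep = "\r")
    for (e in unique(ekey)) {
      ix <- which(ekey == e)
      ms1 <- ix[meta$channel[ix] == "MS1"]
      if (!length(ms1)) next
      for (j in setdiff(ix, ms1))
        meta$r2_vs_ms1[j] <- pearson_r2(wst[ms1[1], ], wst[j, ])
    }
  }
  allw <- quant_wide(q, use = "filled")
  meta$median_area <- apply(allw[, c(qc_samples, study_samples),
                                 drop = FALSE], 1,
                            stats::median, na.rm = TRUE)
  meta
}

#' QC summary tables
#'
#' Per-channel RSD over the QC samples plus the descriptive counts used to
#' report reproducibility: totals and category counts split by channel
#' level (MS1 vs MS2), the median RSD among channels passing `rsd_pass`
#' (the dilution-series convention) and the overall median across all
#' quantifiable channels (the two-group-study convention).
#'
#' @inheritParams channel_stats
#' @return list with `channels` (the [channel_stats()] table) and
#'   `summary` (one row per channel level).
#' @export
qc_summary <- function(q, qc_samples, params = stat_params(),
                       study_samples = NULL) {
  ch <- channel_stats(q, qc_samples, params, study_samples)
  lev <- ifelse(ch$channel == "MS1", "MS1", "MS2")
  summ <- do.call(rbind, lapply(split(seq_len(nrow(ch)), lev), function(ix) {
    r <- ch$rsd_qc[ix]
    data.frame(
      level = if (ch$channel[ix[1]] == "MS1") "MS1" else "MS2",
      n_total = length(ix),
      n_rsd_lt20 = sum(ch$rsd_category[ix] == "<20"),
      n_rsd_20_30 = sum(ch$rsd_category[ix] == "20-30"),
      n_rsd_gt30 = sum(ch$rsd_category[ix] == ">30"),
      n_non_quantifiable = sum(ch$rsd_category[ix] == "non_quantifiable"),
      median_rsd_pass = stats::median(r[!is.na(r) & r < params$rsd_pass]),
      median_rsd_all = stats::median(r, na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  list(channels = ch, summary = summ)
}

#' Select the best-correlated fragment of an entry
#'
#' The fragment whose filled areas have the highest Pearson R-squared
#' against the MS1 precursor; ties go to the lower QC RSD, then to the
#' higher median area.
#'
#' @param ch a [channel_stats()] table.
#' @param entry_id,adduct,polarity entry identifier.
#' @return the winning channel row, or `NULL` when the entry has no
#'   fragment with a defined correlation.
#' @export
select_best_fragment <- function(ch, entry_id,
                                 adduct = NULL, polarity = NULL) {
  ix <- ch$entry_id == entry_id & ch$channel != "MS1"
  if (!is.null(adduct)) ix <- ix & ch$adduct == adduct
  if (!is.null(polarity)) ix <- ix & ch$polarity == polarity
  sub <- ch[ix & !is.na(ch$r2_vs_ms1), , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  o <- order(-sub$r2_vs_ms1, sub$rsd_qc, -sub$median_area)
  sub[o[1], , drop = FALSE]
}

#' Dilution-series linearity per channel
#'
#' Least-squares fit of the mean area (across replicate injections)
#' against injection volume, restricted to volumes at or below
#' `linearity_max_volume` because signal saturates above it. The reported
#' value is the fit's R-squared.
#'
#' @param q long quant table.
#' @param manifest sample manifest with `sample_id` and
#'   `injection_volume_uL`.
#' @param params an [stat_params()] object.
#' @return data frame: channel identity columns plus `r2_linearity` and
#'   `n_volumes` used.
#' @export
linearity <- function(q, manifest, params = stat_params()) {
  vol <- manifest$injection_volume_uL[match(q$sample, manifest$sample_id)]
  keep <- !is.na(vol) & vol <= params$linearity_max_volume
  qq <- q[keep, , drop = FALSE]; vol <- vol[keep]
  keys <- chan_key(qq)
  meta <- qq[!duplicated(keys), c("entry_id", "adduct", "polarity",
                                  "sum_composition", "channel")]
  rownames(meta) <- NULL
  ukey <- unique(keys)
  meta$r2_linearity <- NA_real_
  meta$n_volumes <- 0L
  for (i in seq_along(ukey)) {
    sel <- keys == ukey[i]
    mv <- tapply(qq$area[sel], vol[sel], mean, na.rm = TRUE)
    v <- as.numeric(names(mv))
    meta$n_volumes[i] <- sum(!is.na(mv))
    meta$r2_linearity[i] <- pearson_r2(v, as.numeric(mv))
  }
  meta
}

#' Filter entries for differential analysis
#'
#' An entry is retained iff (1) its MS1 channel and at least one fragment
#' have QC RSD strictly below `rsd_pass`, and (2) at least one of those
#' fragments has Pearson R-squared above `r2_ms1_min` against MS1 over all
#' study samples. Loosening any threshold can only grow the retained set.
#'
#' @inheritParams channel_stats
#' @param study_samples samples for the fragment-MS1 correlation
#'   (defaults to all non-QC samples).
#' @return list with `entries` (data frame of retained entries) and
#'   `channels` (the [channel_stats()] table with a `qualifying` flag on
#'   fragments meeting both gates).
#' @export
filter_for_diff <- function(q, qc_samples, study_samples = NULL,
                            params = stat_params()) {
  ch <- channel_stats(q, qc_samples, params, study_samples)
  ekey <- paste(ch$entry_id, ch$adduct, ch$polarity, sep = "\r")
  ch$qualifying <- ch$channel != "MS1" &
    !is.na(ch$rsd_qc) & ch$rsd_qc < params$rsd_pass &
    !is.na(ch$r2_vs_ms1) & ch$r2_vs_ms1 > params$r2_ms1_min
  keep <- vapply(unique(ekey), function(e) {
    ix <- which(ekey == e)
    ms1 <- ix[ch$channel[ix] == "MS1"]
    length(ms1) == 1L && !is.na(ch$rsd_qc[ms1]) &&
      ch$rsd_qc[ms1] < params$rsd_pass && any(ch$qualifying[ix])
  }, logical(1))
  retained <- unique(ekey)[keep]
  ent <- ch[ch$channel == "MS1" & ekey %in% retained,
            c("entry_id", "adduct", "polarity", "sum_composition")]
  rownames(ent) <- NULL
  list(entries = ent, channels = ch)
}

#' Choose the representative readout per lipid
#'
#' For each sum composition, all passing channels of its retained entries
#' — MS1 channels and qualifying fragments, both polarities merged — are
#' compared and the channel with the lowest QC RSD wins.
#'
#' @param flt output of [filter_for_diff()].
#' @return data frame: `sum_composition`, `entry_id`, `adduct`,
#'   `polarity`, `channel`, `rsd_qc`.
#' @export
representative_readout <- function(flt) {
  ch <- flt$channels
  ekey <- paste(ch$entry_id, ch$adduct, ch$polarity, sep = "\r")
  rkey <- paste(flt$entries$entry_id, flt$entries$adduct,
                flt$entries$polarity, sep = "\r")
  cand <- ch[ekey %in% rkey &
               ((ch$channel == "MS1" & !is.na(ch$rsd_qc) ) | ch$qualifying),
             , drop = FALSE]
  out <- do.call(rbind, lapply(split(cand, cand$sum_composition),
                               function(g) {
    g[which.min(g$rsd_qc),
      c("sum_composition", "entry_id", "adduct", "polarity", "channel",
        "rsd_qc")]
  }))
  rownames(out) <- NULL
  out
}

#' Differential abundance between two groups
#'
#' Each lipid is tested on its representative channel: the fold change is
#' the ratio of arithmetic group means of (filled) areas, the p-value a
#' two-sided Welch t-test on log2 areas, and multiplicity is controlled by
#' Benjamini-Hochberg across all tested lipids. Significance requires the
#' fold change to exceed `fc_threshold` in either direction and the
#' q-value to fall below `fdr_threshold`. A group with zero variance gets
#' a variance floor of 1e-12 and is flagged.
#'
#' @param q long quant table (filled).
#' @param groups named character vector mapping sample id to group label.
#' @param reps representative-readout table from
#'   [representative_readout()].
#' @param params an [stat_params()] object.
#' @param group_order length-2 character vector; the fold change is
#'   `mean(second) / mean(first)`.
#' @return data frame of class `"lp_diff"`: `sum_composition`, `channel`,
#'   `polarity`, `log2_fc`, `p_value`, `q_value`, `significant`,
#'   `var_floored`.
#' @export
differential <- function(q, groups, reps, params = stat_params(),
                         group_order = NULL) {
  labs <- unique(stats::na.omit(groups))
  if (is.null(group_order)) group_order <- labs[1:2]
  stopifnot(length(group_order) == 2L)
  s1 <- names(groups)[groups == group_order[1]]
  s2 <- names(groups)[groups == group_order[2]]
  if (length(s1) < 2L || length(s2) < 2L)
    stop("need at least two samples per group")
  w <- quant_wide(q, c(s1, s2), use = "filled")
  meta <- q[!duplicated(chan_key(q)), ]
  key_of <- function(r) paste(r$entry_id, r$adduct, r$polarity, r$channel,
                              sep = "\r")
  rows <- lapply(seq_len(nrow(reps)), function(i) {
    k <- key_of(reps[i, ])
    x1 <- w[k, s1]; x2 <- w[k, s2]
    if (all(is.na(x1)) || all(is.na(x2))) return(NULL)
    m1 <- mean(x1, na.rm = TRUE); m2 <- mean(x2, na.rm = TRUE)
    l1 <- log2(pmax(x1[!is.na(x1)], .Machine$double.xmin))
    l2 <- log2(pmax(x2[!is.na(x2)], .Machine$double.xmin))
    floored <- stats::var(l1) < 1e-12 || stats::var(l2) < 1e-12
    p <- tryCatch(stats::t.test(l1, l2)$p.value, error = function(e) {
      # zero variance in both groups: fall back to a floored z statistic
      se <- sqrt(2e-12 / length(l1))
      2 * stats::pnorm(-abs(mean(l2) - mean(l1)) / se)
    })
    data.frame(sum_composition = reps$sum_composition[i],
               channel = reps$channel[i], polarity = reps$polarity[i],
               log2_fc = log2(m2 / m1), p_value = p,
               var_floored = floored)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- abs(out$log2_fc) > log2(params$fc_threshold) &
    out$q_value < params$fdr_threshold
  out <- out[, c("sum_composition", "channel", "polarity", "log2_fc",
                 "p_value", "q_value", "significant", "var_floored")]
  class(out) <- c("lp_diff", "data.frame")
  out
}

#' Median-centred log2 fold-change matrix
#'
#' For each lipid (row), every sample's value becomes the log2 ratio of
#' its area to the lipid's median across samples (centring on the median
#' of the log2 areas, so row medians are exactly zero for any sample
#' count) — the normalization used for heatmap display.
#'
#' @param m numeric matrix, lipids in rows, samples in columns.
#' @return matrix of the same shape.
#' @export
median_center <- function(m) {
  lx <- log2(m)
  med <- apply(lx, 1, stats::median, na.rm = TRUE)
  out <- sweep(lx, 1, med, "-")
  dimnames(out) <- dimnames(m)
  out
}
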