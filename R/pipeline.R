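# ---- end-to-end workflow orchestration ----------------------------------

#' Load and validate a pipeline configuration
#'
#' Flat YAML (or an equivalent named list): file paths plus the standard
#' parameter names — `ms1to1`, `ms2to1`, `MS2_score`, `min_peaks`,
#' `RT_shift` for matching; `mass_low`, `mass_high`, `n_windows`,
#' `min_width`, `max_width`, `extension`, `density_radius` for window
#' design; `rsd_pass`, `rsd_tight`, `r2_ms1_min`, `fc_threshold`,
#' `fdr_threshold` for statistics. Unspecified keys take the workflow
#' defaults.
#'
#' @param x path to a YAML file, or a named list.
#' @return validated config list of class `"lp_config"`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(polarity = "positive", seed = 1L,
                   ms1to1 = 0.005, ms2to1 = 0.01, MS2_score = 0.5,
                   min_peaks = 1L, RT_shift = 20,
                   rt_shift_units = "sec",
                   mass_low = 300, mass_high = 1000, n_windows = 20L,
                   min_width = 10, max_width = 100, extension = 0.5,
                   density_radius = 2.5,
                   rsd_pass = 30, rsd_tight = 20, r2_ms1_min = 0.8,
                   fc_threshold = 2, fdr_threshold = 0.05)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("dda_runs", "dia_runs", "reference_library", "manifest",
              "output_dir"))
    if (is.null(cfg[[k]])) stop("pipeline config lacks '", k, "'")
  for (p in c(cfg$dda_runs, cfg$dia_runs, cfg$reference_library,
              cfg$manifest))
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  cfg$match_params <- match_params(
    ms1to1 = cfg$ms1to1, ms2to1 = cfg$ms2to1,
    ms2_score_min = cfg$MS2_score, min_peaks = cfg$min_peaks,
    rt_shift = cfg$RT_shift, rt_shift_units = cfg$rt_shift_units)
  cfg$window_params <- window_params(
    mass_low = cfg$mass_low, mass_high = cfg$mass_high,
    n_windows = cfg$n_windows, min_width = cfg$min_width,
    max_width = cfg$max_width, extension = cfg$extension,
    density_radius = cfg$density_radius)
  cfg$stat_params <- stat_params(
    rsd_pass = cfg$rsd_pass, rsd_tight = cfg$rsd_tight,
    r2_ms1_min = cfg$r2_ms1_min, fc_threshold = cfg$fc_threshold,
    fdr_threshold = cfg$fdr_threshold)
  class(cfg) <- "lp_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full workflow
#'
#' DDA runs -> in-house library -> variable windows -> targeted DIA
#' quantification -> QC statistics -> filtering -> differential
#' abundance. Input runs are sorted by sample id, so file order does not
#' affect output. Artifacts written to the output directory:
#' `inhouse.msp`, `windows.tsv`, `quant_all.tsv`, `quant_fill_all.tsv`,
#' `channel_stats.tsv`, `qc_summary.tsv`, `diff_results.tsv` and
#' `run_log.txt` with a parameter echo.
#'
#' @param config an [pipeline_config()] object (or path / list coercible
#'   to one).
#' @return the output directory, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "lp_config")) config <- pipeline_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("lipidia run %s", format(Sys.time())),
                 sprintf("seed=%d polarity=%s", config$seed,
                         config$polarity),
                 sprintf("ms1to1=%g ms2to1=%g MS2_score=%g min_peaks=%d RT_shift=%g (%s)",
                         config$ms1to1, config$ms2to1, config$MS2_score,
                         config$min_peaks, config$RT_shift,
                         config$rt_shift_units),
                 sprintf("windows: %d x [%g,%g] Th over %g-%g, ext %g, radius %g",
                         config$n_windows, config$min_width,
                         config$max_width, config$mass_low,
                         config$mass_high, config$extension,
                         config$density_radius))
  manifest <- stage("manifest", read_manifest(config$manifest))

  refs <- stage("reference_library",
                read_library(config$reference_library, format = "msp"))
  dda <- stage("read_dda", {
    runs <- lapply(config$dda_runs, read_mzml)
    runs[order(vapply(runs, `[[`, character(1), "sample_id"))]
  })
  lib <- stage("build_library",
               build_library(dda, refs, config$match_params,
                             polarity = config$polarity))
  if (!length(lib))
    stop("pipeline stage 'build_library' produced no annotated entries")
  write_library(lib, file.path(out, "inhouse.msp"), format = "msp")
  log_lines <- c(log_lines, sprintf("library: %d entries from %d DDA runs",
                                    length(lib), length(dda)))

  windows <- stage("window_calc", {
    feats <- do.call(rbind, lapply(dda, detect_ms1_features,
                                   tol = config$ms1to1))
    feats <- compute_density(feats, config$window_params$density_radius)
    partition_windows(feats, config$window_params)
  })
  write_window_table(windows, file.path(out, "windows.tsv"))

  dia <- stage("read_dia", {
    runs <- lapply(config$dia_runs, read_mzml)
    runs[order(vapply(runs, `[[`, character(1), "sample_id"))]
  })
  quant <- stage("quantify",
                 quantify_batch(dia, lib, windows, config$match_params,
                                fill = TRUE, outdir = out))

  qc_ids <- manifest$sample_id[manifest$group == "QC"]
  qc_ids <- intersect(qc_ids, unique(quant$sample))
  study_ids <- setdiff(unique(quant$sample), qc_ids)
  qcres <- stage("qc_stats",
                 qc_summary(quant, qc_ids, config$stat_params, study_ids))
  utils::write.table(qcres$channels, file.path(out, "channel_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qcres$summary, file.path(out, "qc_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  diff <- stage("differential", {
    flt <- filter_for_diff(quant, qc_ids, study_ids, config$stat_params)
    if (!nrow(flt$entries)) NULL else {
      reps <- representative_readout(flt)
      grp <- manifest$group[match(study_ids, manifest$sample_id)]
      names(grp) <- study_ids
      lv <- setdiff(unique(grp), "QC")
      if (length(lv) == 2L)
        differential(quant, grp, reps, config$stat_params,
                     group_order = lv)
      else NULL
    }
  })
  if (is.null(diff))
    diff <- data.frame(sum_composition = character(0),
                       channel = character(0), polarity = character(0),
                       log2_fc = numeric(0), p_value = numeric(0),
                       q_value = numeric(0), significant = logical(0),
                       var_floored = logical(0))
  utils::write.table(diff, file.path(out, "diff_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("quantified %d entries x %d samples",
                         length(lib), length(unique(quant$sample))),
                 sprintf("differential: %d lipids tested, %d significant",
                         nrow(diff), sum(diff$significant)))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(out)
}
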