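# ---- matching parameters ------------------------------------------------

#' Library matching / extraction parameters
#'
#' Defaults follow the workflow's standard settings: precursor tolerance
#' `ms1to1 = 0.005` Th, fragment deconvolution/extraction tolerance
#' `ms2to1 = 0.01` Th, MS/MS library matching fixed at 0.01 Da, match
#' score threshold 0.5, at least one matched peak, and an RT-shift window
#' of 10 (DDA) or 20 (DIA). The RT-shift unit is not standardized across
#' tools; it defaults to seconds here and can be switched to minutes.
#'
#' @param ms1to1 precursor m/z tolerance (Th).
#' @param ms2to1 fragment extraction tolerance (Th).
#' @param frag_match_tol fragment tolerance for library matching (Da).
#' @param ms2_score_min minimum spectral match score in `[0, 1]`.
#' @param min_peaks minimum number of matched fragment peaks.
#' @param rt_shift retention-time gate half-width, in `rt_shift_units`.
#' @param rt_shift_units `"sec"` or `"min"`.
#' @return a list of class `"lp_match_params"`.
#' @export
match_params <- function(ms1to1 = 0.005, ms2to1 = 0.01,
                         frag_match_tol = 0.01, ms2_score_min = 0.5,
                         min_peaks = 1L, rt_shift = 10,
                         rt_shift_units = c("sec", "min")) {
  rt_shift_units <- match.arg(rt_shift_units)
  stopifnot(ms1to1 > 0, ms2to1 > 0, frag_match_tol > 0,
            ms2_score_min >= 0, ms2_score_min <= 1, min_peaks >= 1,
            rt_shift > 0)
  structure(list(ms1to1 = ms1to1, ms2to1 = ms2to1,
                 frag_match_tol = frag_match_tol,
                 ms2_score_min = ms2_score_min,
                 min_peaks = as.integer(min_peaks), rt_shift = rt_shift,
                 rt_shift_units = rt_shift_units),
            class = "lp_match_params")
}

# RT gate half-width in minutes, whatever unit the user configured.
rt_shift_min <- function(params) {
  if (params$rt_shift_units == "sec") params$rt_shift / 60 else params$rt_shift
}

# ---- lipid shorthand nomenclature ---------------------------------------

ADDUCTS_POS <- c("[M+H]+", "[M+NH4]+")
ADDUCTS_NEG <- c("[M-H]-", "[M+HCOO]-")

# Unicode minus signs occasionally appear in adduct strings; normalize.
normalize_adduct <- function(x) {
  x <- gsub("−|–", "-", x)
  gsub(" ", "", x)
}

#' Parse a lipid shorthand name
#'
#' Grammar: a class token (optionally carrying an ether suffix `-P` or
#' `-O`), followed by one or more chains separated by `/` or `_`. Each
#' chain is `C:D`, optionally preceded by a legacy sphingoid prefix
#' (`d`/`t`/`m`, mapped to 2/3/1 hydroxyls) or an ether prefix (`O-`,
#' `P-`), optionally followed by `;xO` hydroxyl counts, and optionally
#' carrying a stable-isotope label suffix (`-d9` etc.), which is ignored
#' for composition purposes. Classes without chains (e.g. sterols) parse
#' to an empty chain list.
#'
#' @param name lipid shorthand string, e.g. `"SM 30:1;2O/2:0"`.
#' @return list with `class` (string), `ether` (logical), `chains` (data
#'   frame with columns `carbons`, `double_bonds`, `oxygens`).
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  s <- trimws(name)
  if (!nzchar(s)) stop("empty lipid name")
  # split class token from chain block at the first space
  sp <- regexpr(" ", s)
  if (sp < 0) { cls <- s; chain_str <- "" } else {
    cls <- substr(s, 1L, sp - 1L)
    chain_str <- trimws(substr(s, sp + 1L, nchar(s)))
  }
  # isotope label on the class itself (e.g. COH-d7)
  cls <- sub("-d[0-9]+$", "", cls)
  ether <- grepl("-(P|O)$", cls)
  chains <- data.frame(carbons = integer(0), double_bonds = integer(0),
                       oxygens = integer(0))
  if (nzchar(chain_str)) {
    toks <- strsplit(chain_str, "[/_]")[[1]]
    parsed <- lapply(toks, function(tok) {
      tok <- sub("-d[0-9]+$", "", trimws(tok))   # isotope label
      m <- regmatches(tok, regexec(
        "^([dtm]|O-|P-)?([0-9]+):([0-9]+)(;([0-9]*)O)?$", tok))[[1]]
      if (!length(m))
        stop("cannot parse lipid chain token '", tok, "' in '", name, "'")
      pre <- m[2]
      oxy <- 0L
      if (pre %in% c("d", "t", "m"))
        oxy <- c(d = 2L, t = 3L, m = 1L)[[pre]]
      if (nzchar(m[5]))            # explicit ;xO overrides/adds
        oxy <- if (nzchar(m[6])) as.integer(m[6]) else 1L
      data.frame(carbons = as.integer(m[3]),
                 double_bonds = as.integer(m[4]), oxygens = oxy)
    })
    chains <- do.call(rbind, parsed)
    if (any(vapply(toks, function(t) grepl("^(O|P)-", trimws(t)), logical(1))))
      ether <- TRUE
  }
  list(class = cls, ether = ether, chains = chains)
}

#' Collapse a lipid name to its sum composition
#'
#' Chains are summed to total carbons : total double bonds and reported as
#' `"CLASS C:D"`, the species-level shorthand used for readouts. Extra
#' hydroxyl counts are tracked internally but omitted from the display
#' string. Already-summed names are returned unchanged (idempotent).
#'
#' @param name lipid shorthand string.
#' @return sum-composition string, e.g. `"SM 32:1"`.
#' @export
to_sum_composition <- function(name) {
  p <- parse_lipid_name(name)
  if (!nrow(p$chains)) return(p$class)
  sprintf("%s %d:%d", p$class, sum(p$chains$carbons),
          sum(p$chains$double_bonds))
}

# ---- library entries ----------------------------------------------------

#' Construct a spectral-library entry
#'
#' @param species_name molecular-species-level shorthand name.
#' @param adduct one of `"[M+H]+"`, `"[M+NH4]+"`, `"[M-H]-"`,
#'   `"[M+HCOO]-"`.
#' @param precursor_mz precursor m/z (Th).
#' @param rt library retention time (minutes); `NA` disables the RT gate.
#' @param fragments data frame `mz`, `intensity`; stored sorted by
#'   intensity descending.
#' @param polarity `"positive"` or `"negative"`; inferred from the adduct
#'   when missing.
#' @param match_score score recorded at annotation time.
#' @param source `"in_house"` or a reference-library name.
#' @param sum_composition computed from `species_name` when missing.
#' @param lipid_class parsed from the name when missing.
#' @return a list of class `"lp_library_entry"`.
#' @export
library_entry <- function(species_name, adduct, precursor_mz, rt = NA_real_,
                          fragments, polarity = NULL,
                          match_score = NA_real_, source = "in_house",
                          sum_composition = NULL, lipid_class = NULL) {
  adduct <- normalize_adduct(adduct)
  if (is.null(polarity))
    polarity <- if (adduct %in% ADDUCTS_POS) "positive" else "negative"
  if ((polarity == "positive") != (adduct %in% ADDUCTS_POS) &&
      adduct %in% c(ADDUCTS_POS, ADDUCTS_NEG))
    stop("adduct ", adduct, " inconsistent with polarity ", polarity)
  stopifnot(nrow(fragments) >= 1, precursor_mz > 0)
  fragments <- fragments[order(-fragments$intensity), , drop = FALSE]
  rownames(fragments) <- NULL
  if (is.null(sum_composition))
    sum_composition <- tryCatch(to_sum_composition(species_name),
                                error = function(e) species_name)
  if (is.null(lipid_class))
    lipid_class <- tryCatch(parse_lipid_name(species_name)$class,
                            error = function(e) NA_character_)
  structure(list(species_name = species_name,
                 sum_composition = sum_composition,
                 lipid_class = lipid_class, adduct = adduct,
                 polarity = polarity, precursor_mz = precursor_mz,
                 rt = rt, fragments = fragments, match_score = match_score,
                 source = source),
            class = "lp_library_entry")
}

# ---- spectral match scoring ---------------------------------------------

#' Score the spectral match between two peak lists
#'
#' Peaks are paired one-to-one within `tol`, closest m/z difference first,
#' so one query peak can never match two reference peaks. The score is the
#' cosine similarity of square-root intensities over the union of paired
#' and unpaired peaks, in `[0, 1]`.
#'
#' @param query,reference data frames with columns `mz`, `intensity`.
#' @param tol pairing tolerance (Da), default 0.01.
#' @return list with `score` and `n_matched`.
#' @export
match_score <- function(query, reference, tol = 0.01) {
  if (!nrow(query) || !nrow(reference))
    stop("match_score needs non-empty peak lists")
  dm <- abs(outer(query$mz, reference$mz, "-"))
  pairs <- which(dm <= tol, arr.ind = TRUE)
  qi <- ri <- integer(0)
  if (nrow(pairs)) {
    pairs <- pairs[order(dm[pairs]), , drop = FALSE]
    used_q <- logical(nrow(query)); used_r <- logical(nrow(reference))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      if (!used_q[a] && !used_r[b]) {
        used_q[a] <- TRUE; used_r[b] <- TRUE
        qi <- c(qi, a); ri <- c(ri, b)
      }
    }
  }
  dot <- sum(sqrt(query$intensity[qi] * reference$intensity[ri]))
  denom <- sqrt(sum(query$intensity)) * sqrt(sum(reference$intensity))
  score <- if (denom > 0) dot / denom else 0
  list(score = score, n_matched = length(qi))
}

# ---- consensus building from DDA runs -----------------------------------

#' Build consensus MS2 spectra from iterative DDA injections
#'
#' MS2 scans from all runs are grouped by precursor m/z (within
#' `+/- ms1to1`) and retention time (within `+/- rt_tol`); within a group,
#' peaks are merged at `ms2to1` resolution with the median intensity
#' across injections. The consensus precursor m/z is the intensity-weighted
#' mean over the member scans.
#'
#' @param dda_runs list of DDA [lp_run()] objects.
#' @param ms1to1 precursor grouping tolerance (Th).
#' @param rt_tol retention-time grouping tolerance (minutes).
#' @param ms2to1 fragment merge resolution (Th).
#' @return list of consensus spectra, each a list with `id`,
#'   `precursor_mz`, `rt`, `n_scans`, `peaks` (data frame `mz`,
#'   `intensity`).
#' @export
build_consensus <- function(dda_runs, ms1to1 = 0.005, rt_tol = 0.2,
                            ms2to1 = 0.01) {
  if (inherits(dda_runs, "lp_run")) dda_runs <- list(dda_runs)
  for (r in dda_runs)
    if (r$mode != "DDA")
      stop("build_consensus expects DDA runs; got a DIA run (",
           r$sample_id, ")")
  scans <- list()
  for (r in dda_runs)
    for (s in r$spectra)
      if (s$ms_level == 2L && length(s$mz))
        scans[[length(scans) + 1L]] <- list(
          prec = mean(s$precursor_window), rt = s$rt,
          tic = sum(s$intensity),
          peaks = data.frame(mz = s$mz, intensity = s$intensity))
  if (!length(scans)) return(list())
  prec <- vapply(scans, `[[`, numeric(1), "prec")
  rt <- vapply(scans, `[[`, numeric(1), "rt")
  ord <- order(prec, rt)
  grp <- integer(length(scans)); g <- 0L
  # greedy grouping: a scan joins the open group if it stays within the
  # precursor and RT gates of the group seed
  seed_p <- seed_r <- NULL
  for (i in ord) {
    if (g == 0L || abs(prec[i] - seed_p) > ms1to1 ||
        abs(rt[i] - seed_r) > rt_tol) {
      g <- g + 1L; seed_p <- prec[i]; seed_r <- rt[i]
    }
    grp[i] <- g
  }
  out <- vector("list", g)
  for (k in seq_len(g)) {
    mem <- scans[grp == k]
    tw <- vapply(mem, `[[`, numeric(1), "tic")
    pmz <- vapply(mem, `[[`, numeric(1), "prec")
    wmean <- if (sum(tw) > 0) sum(pmz * tw) / sum(tw) else mean(pmz)
    all_pk <- do.call(rbind, lapply(seq_along(mem), function(j)
      cbind(mem[[j]]$peaks, scan = j)))
    all_pk <- all_pk[order(all_pk$mz), , drop = FALSE]
    cl <- cumsum(c(1L, diff(all_pk$mz) > ms2to1))
    merged <- do.call(rbind, lapply(split(all_pk, cl), function(d)
      data.frame(mz = stats::weighted.mean(d$mz, d$intensity),
                 intensity = stats::median(d$intensity))))
    merged <- merged[order(merged$mz), , drop = FALSE]
    out[[k]] <- list(id = k, precursor_mz = wmean,
                     rt = mean(vapply(mem, `[[`, numeric(1), "rt")),
                     n_scans = length(mem), peaks = merged)
  }
  out
}

# ---- library search -----------------------------------------------------

#' Search consensus spectra against reference libraries
#'
#' Candidates are gated on precursor m/z (`ms1to1`) and, when the
#' reference entry carries a retention time, on `|delta RT| <= rt_shift`;
#' surviving candidates are scored with [match_score()] at
#' `frag_match_tol`. All candidates are retained for audit; the `passed`
#' flag records whether score and matched-peak thresholds were met.
#'
#' @param consensus list from [build_consensus()].
#' @param references list of [library_entry()] objects (the reference
#'   library, in file order — order matters for tie-breaking).
#' @param params an [match_params()] object.
#' @return data frame of candidate annotations: `spectrum_id`,
#'   `ref_index`, `species_name`, `sum_composition`, `adduct`,
#'   `polarity`, `score`, `n_matched`, `passed`.
#' @export
search_library <- function(consensus, references, params = match_params()) {
  if (!length(references)) stop("reference library is empty")
  ref_prec <- vapply(references, `[[`, numeric(1), "precursor_mz")
  ref_rt <- vapply(references, `[[`, numeric(1), "rt")
  rows <- list()
  gate_rt <- rt_shift_min(params)
  for (cs in consensus) {
    hit <- which(abs(ref_prec - cs$precursor_mz) <= params$ms1to1)
    hit <- hit[is.na(ref_rt[hit]) | abs(ref_rt[hit] - cs$rt) <= gate_rt]
    for (j in hit) {
      sc <- match_score(cs$peaks, references[[j]]$fragments,
                        params$frag_match_tol)
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_id = cs$id, ref_index = j,
        species_name = references[[j]]$species_name,
        sum_composition = references[[j]]$sum_composition,
        adduct = references[[j]]$adduct,
        polarity = references[[j]]$polarity,
        score = sc$score, n_matched = sc$n_matched,
        passed = sc$score >= params$ms2_score_min &&
          sc$n_matched >= params$min_peaks)
    }
  }
  if (!length(rows))
    return(data.frame(spectrum_id = integer(0), ref_index = integer(0),
                      species_name = character(0),
                      sum_composition = character(0), adduct = character(0),
                      polarity = character(0), score = numeric(0),
                      n_matched = integer(0), passed = logical(0)))
  do.call(rbind, rows)
}

#' Resolve the annotation for one spectrum
#'
#' Among passed candidates, the highest score wins; exact score ties are
#' broken by the *last* position in the reference list. That tie rule
#' follows the established tool behaviour this workflow reproduces (which
#' is why a molecular species can be reported by its last-listed
#' constituent); `tie = "first"` gives the conventional alternative.
#'
#' @param candidates rows of the [search_library()] output for one
#'   spectrum.
#' @param tie `"last"` (default) or `"first"`.
#' @return a single candidate row, or `NULL` when none passed.
#' @export
resolve_annotation <- function(candidates, tie = c("last", "first")) {
  tie <- match.arg(tie)
  ok <- candidates[candidates$passed, , drop = FALSE]
  if (!nrow(ok)) return(NULL)
  best <- ok[ok$score == max(ok$score), , drop = FALSE]
  pick <- if (tie == "last") which.max(best$ref_index)
          else which.min(best$ref_index)
  best[pick, , drop = FALSE]
}

#' Filter annotations or entries by permitted adducts
#'
#' Positive mode admits `[M+H]+` and `[M+NH4]+`; negative mode admits
#' `[M-H]-` and `[M+HCOO]-`. Everything else is removed.
#'
#' @param x a data frame with an `adduct` column, or a list of
#'   [library_entry()] objects.
#' @param polarity `"positive"` or `"negative"`.
#' @return `x` with non-permitted adducts removed.
#' @export
filter_adducts <- function(x, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  allowed <- if (polarity == "positive") ADDUCTS_POS else ADDUCTS_NEG
  if (is.data.frame(x))
    return(x[normalize_adduct(x$adduct) %in% allowed, , drop = FALSE])
  x[vapply(x, function(e) normalize_adduct(e$adduct) %in% allowed,
           logical(1))]
}

#' Remove duplicate library entries
#'
#' One entry is kept per `(sum_composition, adduct, polarity)`: the one
#' with the highest match score, ties resolved by earliest retention time.
#'
#' @param entries list of [library_entry()] objects.
#' @return deduplicated list.
#' @export
dedupe_entries <- function(entries) {
  if (!length(entries)) return(entries)
  key <- vapply(entries, function(e)
    paste(e$sum_composition, e$adduct, e$polarity, sep = "|"), character(1))
  score <- vapply(entries, function(e)
    if (is.na(e$match_score)) -Inf else e$match_score, numeric(1))
  rt <- vapply(entries, function(e)
    if (is.na(e$rt)) Inf else e$rt, numeric(1))
  keep <- unlist(lapply(split(seq_along(entries), key), function(ix) {
    ix <- ix[score[ix] == max(score[ix])]
    ix[which.min(rt[ix])]
  }), use.names = FALSE)
  entries[sort(keep)]
}

# ---- library serialization ----------------------------------------------

#' Write a spectral library
#'
#' MSP uses the NIST-style dialect (`Name:`, `PRECURSORMZ:`,
#' `PRECURSORTYPE:`, `IONMODE:`, `RETENTIONTIME:`, `COMMENT:`,
#' `Num Peaks:` followed by `mz intensity` lines). TSV is long format with
#' one row per fragment.
#'
#' @param entries list of [library_entry()] objects.
#' @param path output path.
#' @param format `"msp"` or `"tsv"`.
#' @export
write_library <- function(entries, path, format = c("msp", "tsv")) {
  format <- match.arg(format)
  if (format == "msp") {
    con <- file(path, "w"); on.exit(close(con))
    for (e in entries) {
      writeLines(c(
        paste0("Name: ", e$species_name),
        paste0("PRECURSORMZ: ", format(e$precursor_mz, digits = 15)),
        paste0("PRECURSORTYPE: ", e$adduct),
        paste0("IONMODE: ", e$polarity),
        if (!is.na(e$rt)) paste0("RETENTIONTIME: ",
                                 format(e$rt, digits = 15)),
        paste0("COMMENT: sum=", e$sum_composition, "; class=",
               e$lipid_class, "; score=",
               format(e$match_score, digits = 15), "; source=", e$source),
        paste0("Num Peaks: ", nrow(e$fragments)),
        sprintf("%s %s", format(e$fragments$mz, digits = 15),
                format(e$fragments$intensity, digits = 15)),
        ""), con)
    }
  } else {
    rows <- do.call(rbind, lapply(entries, function(e)
      data.frame(species_name = e$species_name,
                 sum_composition = e$sum_composition,
                 lipid_class = e$lipid_class, adduct = e$adduct,
                 polarity = e$polarity, precursor_mz = e$precursor_mz,
                 rt = e$rt, fragment_mz = e$fragments$mz,
                 fragment_intensity = e$fragments$intensity,
                 match_score = e$match_score, source = e$source)))
    if (is.null(rows))
      rows <- data.frame(species_name = character(0),
                         sum_composition = character(0),
                         lipid_class = character(0), adduct = character(0),
                         polarity = character(0), precursor_mz = numeric(0),
                         rt = numeric(0), fragment_mz = numeric(0),
                         fragment_intensity = numeric(0),
                         match_score = numeric(0), source = character(0))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_library
#' @param path library file path.
#' @return for `read_library`, a list of [library_entry()] objects.
#' @export
read_library <- function(path, format = c("msp", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!nrow(d)) return(list())
    keys <- paste(d$species_name, d$adduct, d$polarity, sep = "|")
    return(unname(lapply(split(d, factor(keys, levels = unique(keys))),
                         function(g)
      library_entry(g$species_name[1], g$adduct[1], g$precursor_mz[1],
                    rt = g$rt[1],
                    fragments = data.frame(mz = g$fragment_mz,
                                           intensity = g$fragment_intensity),
                    polarity = g$polarity[1],
                    match_score = g$match_score[1], source = g$source[1],
                    sum_composition = g$sum_composition[1],
                    lipid_class = g$lipid_class[1]))))
  }
  lines <- readLines(path)
  entries <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (!grepl("^Name:", lines[i])) { i <- i + 1L; next }
    fields <- list(Name = trimws(sub("^Name:", "", lines[i])))
    i <- i + 1L
    while (i <= n && !grepl("^Num Peaks:", lines[i], ignore.case = TRUE)) {
      kv <- regmatches(lines[i], regexec("^([^:]+):\\s*(.*)$", lines[i]))[[1]]
      if (length(kv) == 3L) fields[[toupper(trimws(kv[2]))]] <- trimws(kv[3])
      i <- i + 1L
    }
    if (i > n) break
    npk <- as.integer(sub("^Num Peaks:\\s*", "", lines[i],
                          ignore.case = TRUE))
    pk <- matrix(NA_real_, npk, 2)
    for (j in seq_len(npk)) {
      i <- i + 1L
      xs <- strsplit(trimws(lines[i]), "[ \t;]+")[[1]]
      pk[j, ] <- as.numeric(xs[1:2])
    }
    i <- i + 1L
    cm <- fields[["COMMENT"]]
    meta <- c(sum = NA, class = NA, score = NA, source = NA)
    if (!is.null(cm)) {
      for (part in strsplit(cm, ";\\s*")[[1]]) {
        kv <- strsplit(part, "=")[[1]]
        if (length(kv) == 2L) meta[trimws(kv[1])] <- trimws(kv[2])
      }
    }
    entries[[length(entries) + 1L]] <- library_entry(
      species_name = fields$Name,
      adduct = if (!is.null(fields[["PRECURSORTYPE"]]))
        fields[["PRECURSORTYPE"]] else "[M+H]+",
      precursor_mz = as.numeric(fields[["PRECURSORMZ"]]),
      rt = if (!is.null(fields[["RETENTIONTIME"]]))
        as.numeric(fields[["RETENTIONTIME"]]) else NA_real_,
      fragments = data.frame(mz = pk[, 1], intensity = pk[, 2]),
      polarity = if (!is.null(fields[["IONMODE"]]))
        fields[["IONMODE"]] else NULL,
      match_score = suppressWarnings(as.numeric(meta[["score"]])),
      source = if (!is.na(meta[["source"]])) meta[["source"]] else "file",
      sum_composition = if (!is.na(meta[["sum"]])) meta[["sum"]] else NULL,
      lipid_class = if (!is.na(meta[["class"]])) meta[["class"]] else NULL)
  }
  entries
}

#' Build an annotated in-house library from DDA runs
#'
#' The full DDA identification chain: consensus building across iterative
#' injections, library search, per-spectrum resolution (highest score,
#' last-entry tie rule), adduct filtering and deduplication. Each accepted
#' consensus spectrum becomes an in-house entry carrying its own measured
#' peaks and retention time, annotated with the winning reference name.
#'
#' @param dda_runs list of DDA [lp_run()] objects.
#' @param references list of [library_entry()] reference spectra.
#' @param params an [match_params()] object.
#' @param polarity acquisition polarity for adduct filtering.
#' @param rt_tol consensus RT grouping tolerance (minutes).
#' @return list of [library_entry()] objects (the in-house library).
#' @export
build_library <- function(dda_runs, references, params = match_params(),
                          polarity = c("positive", "negative"),
                          rt_tol = 0.2) {
  polarity <- match.arg(polarity)
  references <- filter_adducts(references, polarity)
  if (!length(references)) stop("no reference entries after adduct filter")
  consensus <- build_consensus(dda_runs, ms1to1 = params$ms1to1,
                               rt_tol = rt_tol, ms2to1 = params$ms2to1)
  cands <- search_library(consensus, references, params)
  entries <- list()
  for (cs in consensus) {
    sub <- cands[cands$spectrum_id == cs$id, , drop = FALSE]
    win <- resolve_annotation(sub)
    if (is.null(win)) next
    ref <- references[[win$ref_index]]
    entries[[length(entries) + 1L]] <- library_entry(
      species_name = ref$species_name, adduct = ref$adduct,
      precursor_mz = cs$precursor_mz, rt = cs$rt,
      fragments = cs$peaks[order(-cs$peaks$intensity), , drop = FALSE],
      polarity = ref$polarity, match_score = win$score,
      source = "in_house", sum_composition = ref$sum_composition,
      lipid_class = ref$lipid_class)
  }
  dedupe_entries(entries)
}
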