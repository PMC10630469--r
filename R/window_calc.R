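# ---- variable isolation-window design -----------------------------------
#
# The calculator partitions the precursor mass range into a fixed number of
# contiguous windows whose summed MS1-feature density is approximately
# equal, subject to instrument limits on window width.  Narrow windows land
# where precursors are dense, wide windows where they are sparse, so the
# cycle time stays fixed while co-isolation is spread evenly.

#' Parameters of the variable-window calculator
#'
#' @param mass_low,mass_high precursor mass range (Th), e.g. 300-1000.
#' @param n_windows number of isolation windows, e.g. 20.
#' @param min_width,max_width instrument limits on core window width (Th),
#'   e.g. 10 and 100.
#' @param extension edge extension applied to each side of every core
#'   window (Th); 0.5 gives adjacent windows a 1 Th overlap.
#' @param density_radius m/z radius within which features count as
#'   "nearby" for the density estimate (Th).
#' @return a validated list of class `"lp_window_params"`.
#' @export
window_params <- function(mass_low = 300, mass_high = 1000, n_windows = 20,
                          min_width = 10, max_width = 100, extension = 0.5,
                          density_radius = 2.5) {
  if (mass_low >= mass_high) stop("mass_low must be below mass_high")
  if (n_windows < 1) stop("n_windows must be >= 1")
  if (min_width <= 0 || min_width > max_width)
    stop("need 0 < min_width <= max_width")
  span <- mass_high - mass_low
  if (n_windows * min_width > span || n_windows * max_width < span)
    stop(sprintf(
      "infeasible window scheme: %d windows of width [%g, %g] cannot tile %g Th",
      n_windows, min_width, max_width, span))
  if (extension < 0) stop("extension must be >= 0")
  if (density_radius <= 0) stop("density_radius must be > 0")
  structure(list(mass_low = mass_low, mass_high = mass_high,
                 n_windows = as.integer(n_windows), min_width = min_width,
                 max_width = max_width, extension = extension,
                 density_radius = density_radius),
            class = "lp_window_params")
}

#' Compute per-feature precursor density
#'
#' The density of a feature is the number of features (itself included)
#' whose m/z lies within `+/- radius` of its own. Input order is
#' preserved.
#'
#' @param features feature data frame with an `mz` column.
#' @param radius counting radius (Th).
#' @return `features` with the `density` column filled.
#' @export
compute_density <- function(features, radius = 2.5) {
  stopifnot(radius > 0)
  if (!nrow(features)) {
    features$density <- numeric(0)
    return(features)
  }
  s <- sort(features$mz)
  hi <- findInterval(features$mz + radius, s)
  lo <- findInterval(features$mz - radius, s, left.open = TRUE)
  features$density <- as.numeric(hi - lo)
  features
}

#' Partition the mass range into equal-density windows
#'
#' Cut points live on the grid of midpoints between consecutive feature
#' m/z values (so no precursor sits exactly on a cut unless duplicated
#' m/z forces it). Among all feasible placements of `n_windows - 1` cuts
#' on that grid — every core width within `[min_width, max_width]`, last
#' window ending exactly at `mass_high` — the partition minimizing the
#' variance of the per-window summed density is found by dynamic
#' programming (minimizing the variance is equivalent to minimizing the
#' sum of squared window sums, since the total and the window count are
#' fixed). A feature sitting exactly on a cut belongs to the lower
#' window.
#'
#' When the grid admits no feasible placement (few or clustered
#' features), a greedy cumulative-density sweep with feasibility clamping
#' places the cuts off-grid instead; with an empty feature list the range
#' is tiled uniformly.
#'
#' @param features feature data frame with `mz` and `density` columns
#'   (see [compute_density()]); may have zero rows.
#' @param params an [window_params()] object.
#' @return data frame of class `"lp_windows"`: `index`, `core_low`,
#'   `core_high`, `ext_low`, `ext_high`, `summed_density`.
#' @export
partition_windows <- function(features, params) {
  stopifnot(inherits(params, "lp_window_params"))
  nw <- params$n_windows
  keep <- features$mz >= params$mass_low & features$mz <= params$mass_high
  features <- features[keep, , drop = FALSE]
  if (nrow(features) && any(is.na(features$density)))
    stop("features lack density; run compute_density() first")
  o <- order(features$mz)
  fmz <- features$mz[o]; fd <- features$density[o]
  bounds <- numeric(nw + 1L)
  bounds[1L] <- params$mass_low; bounds[nw + 1L] <- params$mass_high
  if (!length(fmz)) {
    bounds <- seq(params$mass_low, params$mass_high, length.out = nw + 1L)
  } else if (nw > 1L) {
    # candidate cuts: midpoints between consecutive distinct feature m/z
    umz <- unique(fmz)
    cand <- if (length(umz) > 1L) (umz[-1] + umz[-length(umz)]) / 2 else numeric(0)
    cand <- cand[cand > params$mass_low & cand < params$mass_high]
    cum <- cumsum(fd)
    total <- cum[length(cum)]
    dp <- partition_dp(fmz, cum, cand, params)
    if (!is.null(dp)) {
      bounds[2:nw] <- dp
    } else bounds <- partition_greedy(fmz, cum, cand, params, bounds)
  }
  sd_per <- window_density_sums(fmz, fd, bounds)
  out <- data.frame(index = seq_len(nw),
                    core_low = bounds[-(nw + 1L)],
                    core_high = bounds[-1L],
                    ext_low = bounds[-(nw + 1L)],
                    ext_high = bounds[-1L],
                    summed_density = sd_per)
  class(out) <- c("lp_windows", "data.frame")
  extend_windows(out, params$extension)
}

# Exact equal-density partition: dynamic program over the cut grid
# minimizing the sum of squared window density sums under width bounds.
# Returns the interior cut positions, or NULL when the grid is infeasible.
partition_dp <- function(fmz, cum, cand, params) {
  nw <- params$n_windows
  if (length(cand) < nw - 1L) return(NULL)
  pos <- c(params$mass_low, cand, params$mass_high)
  cumn <- c(0, cum[findInterval(cand, fmz)], cum[length(cum)])
  m <- length(pos)
  cost <- matrix(Inf, m, nw)
  back <- matrix(NA_integer_, m, nw)
  wd1 <- pos - pos[1]
  ok1 <- wd1 >= params$min_width - 1e-12 & wd1 <= params$max_width + 1e-12
  cost[ok1, 1L] <- cumn[ok1]^2
  for (k in 2:nw) {
    js <- if (k == nw) m else seq_len(m)
    for (j in js) {
      wd <- pos[j] - pos
      feas <- which(wd >= params$min_width - 1e-12 &
                      wd <= params$max_width + 1e-12 &
                      is.finite(cost[, k - 1L]))
      if (!length(feas)) next
      tot <- cost[feas, k - 1L] + (cumn[j] - cumn[feas])^2
      b <- which.min(tot)                 # ties: smallest index (leftmost)
      cost[j, k] <- tot[b]
      back[j, k] <- feas[b]
    }
  }
  if (!is.finite(cost[m, nw])) return(NULL)
  cuts <- integer(nw - 1L)
  j <- m
  for (k in nw:2) {
    j <- back[j, k]
    cuts[k - 1L] <- j
  }
  pos[cuts]
}

# Greedy cumulative-density sweep with feasibility clamping: each cut aims
# at (density remaining)/(windows remaining) and is clamped into the width
# bounds and into the interval keeping the tail feasible.
partition_greedy <- function(fmz, cum, cand, params, bounds) {
  nw <- params$n_windows
  total <- cum[length(cum)]
  used <- 0        # density already assigned to closed windows
  for (i in seq_len(nw - 1L)) {
      prev <- bounds[i]
      remaining <- nw - i + 1L
      target <- used + (total - used) / remaining
      lo_cl <- max(prev + params$min_width,
                   params$mass_high - (remaining - 1L) * params$max_width)
      hi_cl <- min(prev + params$max_width,
                   params$mass_high - (remaining - 1L) * params$min_width)
      ok <- cand > prev & cand >= lo_cl & cand <= hi_cl
      if (any(ok)) {
        cc <- cand[ok]
        # density accumulated up to each candidate (features on a cut
        # cannot occur at a midpoint unless m/z values repeat)
        cumc <- cum[findInterval(cc, fmz)]
        cut <- cc[which.min(abs(cumc - target))]
      } else {
        # no feature midpoint is feasible; fall back to the clamp bound
        # nearest the unconstrained equal-density position
        free <- if (length(cand) && any(cand > prev)) {
          cc <- cand[cand > prev]
          cc[which.min(abs(cum[findInterval(cc, fmz)] - target))]
        } else (lo_cl + hi_cl) / 2
        cut <- min(max(free, lo_cl), hi_cl)
      }
      bounds[i + 1L] <- cut
      used <- if (length(fmz)) {
        j <- findInterval(cut, fmz)   # features with mz <= cut (tie: lower)
        if (j >= 1L) cum[j] else 0
      } else 0
  }
  bounds
}

# Sum feature density per window; a feature exactly on a boundary counts
# toward the lower window, and the first window is closed at mass_low.
window_density_sums <- function(fmz, fd, bounds) {
  nw <- length(bounds) - 1L
  if (!length(fmz)) return(rep(0, nw))
  idx <- pmax(1L, findInterval(fmz, bounds, left.open = TRUE))
  idx <- pmin(idx, nw)
  out <- rep(0, nw)
  agg <- rowsum(fd, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Extend window edges for overlap
#'
#' Each core window is widened by `extension` on both sides, so adjacent
#' extended windows overlap by exactly `2 * extension`.
#'
#' @param windows an `lp_windows` data frame (contiguous cores).
#' @param extension per-edge extension (Th).
#' @return the windows with `ext_low` / `ext_high` set.
#' @export
extend_windows <- function(windows, extension = 0.5) {
  stopifnot(extension >= 0)
  if (nrow(windows) > 1L &&
      any(abs(windows$core_high[-nrow(windows)] -
              windows$core_low[-1]) > 1e-9))
    stop("core windows must tile contiguously")
  windows$ext_low <- windows$core_low - extension
  windows$ext_high <- windows$core_high + extension
  windows
}

#' Assign a precursor to its core window
#'
#' Overlap regions belong to two *extended* windows; quantification must
#' read each precursor from a single channel, so assignment uses the core
#' bounds, with an m/z exactly on an interior boundary going to the lower
#' window.
#'
#' @param precursor_mz numeric vector of precursor m/z values.
#' @param windows an `lp_windows` data frame.
#' @return integer vector of window indices.
#' @export
assign_window <- function(precursor_mz, windows) {
  breaks <- c(windows$core_low[1], windows$core_high)
  if (any(precursor_mz < breaks[1] | precursor_mz > breaks[length(breaks)]))
    stop("precursor m/z outside the window scheme range")
  idx <- findInterval(precursor_mz, breaks, left.open = TRUE)
  as.integer(pmax(1L, idx))
}

#' Write / read a window scheme table
#'
#' @param windows an `lp_windows` data frame.
#' @param path TSV path.
#' @export
write_window_table <- function(windows, path) {
  utils::write.table(
    windows[, c("index", "core_low", "core_high", "ext_low", "ext_high",
                "summed_density")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(w) <- c("lp_windows", "data.frame")
  w
}

#' End-to-end window design from a DDA run
#'
#' Convenience wrapper: detect MS1 features, compute density and partition.
#'
#' @param run an [lp_run()] with MS1 scans (typically DDA).
#' @param params an [window_params()] object.
#' @param tol MS1 feature mass-trace tolerance (Th).
#' @return an `lp_windows` data frame.
#' @export
design_windows <- function(run, params = window_params(), tol = 0.005) {
  feats <- detect_ms1_features(run, tol = tol)
  feats <- compute_density(feats, params$density_radius)
  partition_windows(feats, params)
}
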