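# Shared fixtures, built in code at test time.

# A small crowded catalog + window scheme at desk scale: species elute on
# a short gradient so runs stay small while peaks keep ~20 scans each.
desk_catalog <- function(n = 50, seed = 7, rt_range = c(0.5, 3.5)) {
  make_catalog(n, seed = seed, rt_range = rt_range)
}

desk_windows <- function(catalog, n_windows = 8, min_width = 10,
                         max_width = 250) {
  feats <- compute_density(data.frame(mz = catalog$precursor_mz), 2.5)
  partition_windows(feats, window_params(300, 1000, n_windows, min_width,
                                         max_width))
}

# A clean Gaussian XIC trace sampled on a uniform grid.
gaussian_trace <- function(A = 1000, t0 = 1, sigma = 0.04, dt = 0.004,
                           span = 6, extra = 0) {
  rt <- seq(t0 - span * sigma, t0 + span * sigma, by = dt)
  y <- A * exp(-(rt - t0)^2 / (2 * sigma^2))
  structure(data.frame(rt = rt, intensity = y + extra),
            class = c("lp_xic", "data.frame"))
}

# Exhaustive min-variance partition oracle on the feature-midpoint grid.
oracle_partition <- function(feats, params) {
  o <- order(feats$mz)
  fmz <- feats$mz[o]; fd <- feats$density[o]
  umz <- unique(fmz)
  cand <- (umz[-1] + umz[-length(umz)]) / 2
  nw <- params$n_windows
  bestv <- Inf; bestb <- NULL
  combos <- utils::combn(length(cand), nw - 1)
  for (k in seq_len(ncol(combos))) {
    b <- c(params$mass_low, cand[combos[, k]], params$mass_high)
    wdt <- diff(b)
    if (any(wdt < params$min_width - 1e-9 |
              wdt > params$max_width + 1e-9)) next
    idx <- pmin(pmax(1L, findInterval(fmz, b, left.open = TRUE)), nw)
    sums <- vapply(split(fd, factor(idx, seq_len(nw))), sum, numeric(1))
    v <- stats::var(sums)
    if (v < bestv - 1e-12) { bestv <- v; bestb <- b }
  }
  bestb
}

# Reference Benjamini-Hochberg, written from the step-up definition.
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}
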