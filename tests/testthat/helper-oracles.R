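# Independent brute-force oracles: plain per-pixel/per-window restatements
# of the published rules, kept free of the package's vectorized internals.

water_oracle <- function(s, cfg) {
  dims <- dim(s$bands$red)
  out <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    if (s$nodata_mask[i, j]) next
    red <- s$bands$red[i, j]; nir <- s$bands$nir[i, j]
    swir <- s$bands$swir1[i, j]
    nd <- if (nir + red > 0) (nir - red) / (nir + red) else NA_real_
    trend <- red > nir && nir > swir
    low_ndvi <- !is.na(nd) && nd < cfg$water_ndvi_max
    out[i, j] <- swir < cfg$water_swir_max && (trend || low_ndvi)
  }
  out
}

# dark-peak forest rule, one window at a time, with explicit loops
forest_oracle <- function(s, cfg) {
  red <- s$bands$red
  nr <- nrow(red); nc <- ncol(red)
  out <- matrix(FALSE, nr, nc)
  ws <- cfg$window_size
  for (r0 in seq(1, nr, by = ws)) for (c0 in seq(1, nc, by = ws)) {
    rs <- r0:min(nr, r0 + ws - 1); cs <- c0:min(nc, c0 + ws - 1)
    ok <- !s$nodata_mask[rs, cs, drop = FALSE]
    vals <- red[rs, cs, drop = FALSE][ok]
    if (length(vals) < 10) next
    bw <- cfg$forest_bin_width
    edges <- seq(0, 1 + bw, by = bw)
    counts <- integer(length(edges) - 1)
    for (v in pmin(vals, 1)) {
      b <- findInterval(v, edges, rightmost.closed = TRUE,
                        left.open = TRUE)
      b <- max(b, 1L)
      counts[b] <- counts[b] + 1L
    }
    k <- cfg$forest_smooth_bins
    sm <- numeric(length(counts))
    half <- (k - 1) / 2
    for (i in seq_along(counts)) {
      lo <- i - floor(half); hi <- i + ceiling(half)
      if (lo < 1 || hi > length(counts)) { sm[i] <- 0; next }
      sm[i] <- mean(counts[lo:hi])
    }
    mids <- edges[-length(edges)] + bw / 2
    prom <- cfg$forest_peak_prominence * length(vals)
    peak <- NA_integer_
    for (i in seq_along(sm)) {
      l <- if (i > 1) sm[i - 1] else -Inf
      r <- if (i < length(sm)) sm[i + 1] else -Inf
      if (sm[i] >= l && sm[i] >= r && sm[i] >= prom &&
          mids[i] <= cfg$forest_red_max) { peak <- i; break }
    }
    if (is.na(peak)) next
    hh <- sm[peak] / 2
    lo <- peak; while (lo > 1 && sm[lo - 1] >= hh) lo <- lo - 1
    hi <- peak; while (hi < length(sm) && sm[hi + 1] >= hh) hi <- hi + 1
    thr <- mids[peak] + max((hi - lo + 1) * bw, 2 * bw)
    win <- red[rs, cs, drop = FALSE]
    out[rs, cs] <- win <= thr & ok
  }
  out
}

# per-window +/- k sigma labelling of the difference image
training_label_oracle <- function(d, valid, cfg) {
  nr <- nrow(d); nc <- ncol(d)
  lab <- matrix(NA_character_, nr, nc)
  ws <- cfg$window_size; st <- cfg$window_stride
  for (r0 in seq(1, nr, by = st)) for (c0 in seq(1, nc, by = st)) {
    rs <- r0:min(nr, r0 + ws - 1); cs <- c0:min(nc, c0 + ws - 1)
    vm <- valid[rs, cs, drop = FALSE]
    dv <- d[rs, cs, drop = FALSE]
    n_valid <- sum(vm)
    if (n_valid / length(vm) < cfg$window_min_valid_frac) next
    mu <- mean(dv[vm]); sigma <- stats::sd(dv[vm])
    if (!is.finite(sigma) || sigma == 0) next
    k <- cfg$threshold_multiplier
    dist <- vm & dv < mu - k * sigma
    regr <- vm & dv > mu + k * sigma
    if (sum(dist) < cfg$min_tail_count) next
    sub <- matrix(NA_character_, length(rs), length(cs))
    sub[dist] <- "disturbed"
    if (sum(regr) >= cfg$min_tail_count) sub[regr] <- "regrowth"
    lab[rs, cs] <- sub
  }
  lab
}
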