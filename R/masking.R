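# --- binary morphology (square structuring element, vectorized shifts) ---

shift_pad <- function(m, drow, dcol, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + drow):min(nr, nr + drow)
  cs <- max(1, 1 + dcol):min(nc, nc + dcol)
  out[rs, cs] <- m[rs - drow, cs - dcol, drop = FALSE]
  out
}

erode_binary <- function(m, radius = 1L) {
  if (radius < 1L) return(m)
  out <- m
  for (dr in -radius:radius)
    for (dc in -radius:radius)
      if (dr || dc) out <- out & shift_pad(m, dr, dc, FALSE)
  out
}

dilate_binary <- function(m, radius = 1L) {
  if (radius < 1L) return(m)
  out <- m
  for (dr in -radius:radius)
    for (dc in -radius:radius)
      if (dr || dc) out <- out | shift_pad(m, dr, dc, FALSE)
  out
}

open_binary <- function(m, radius = 1L) dilate_binary(erode_binary(m, radius), radius)

#' Normalized difference vegetation index
#'
#' `(nir - red) / (nir + red)`, defined only where the denominator is
#' positive and the pixel has data; elsewhere `NA`.
#'
#' @param s A `scene`.
#' @return Numeric matrix in `[-1, 1]` with `NA` where undefined.
#' @export
ndvi <- function(s) {
  stopifnot(inherits(s, "scene"))
  nir <- s$bands$nir; red <- s$bands$red
  den <- nir + red
  out <- (nir - red) / den
  out[den <= 0 | s$nodata_mask] <- NA_real_
  out
}

#' Water mask
#'
#' A pixel is water iff its SWIR-1 reflectance is below
#' `cfg$water_swir_max` (default 25%) and it shows either a strictly
#' decreasing visible-to-infrared trend (`red > nir > swir1`) or an NDVI
#' below `cfg$water_ndvi_max` (default 0.3), or both. Nodata pixels are
#' never water.
#'
#' @param s A `scene`.
#' @param cfg A [pipeline_config()].
#' @return Logical matrix.
#' @export
water_mask <- function(s, cfg = pipeline_config()) {
  stopifnot(inherits(s, "scene"))
  nd <- ndvi(s)
  swir <- s$bands$swir1; red <- s$bands$red; nir <- s$bands$nir
  trend <- red > nir & nir > swir
  low_ndvi <- !is.na(nd) & nd < cfg$water_ndvi_max
  out <- swir < cfg$water_swir_max & (trend | low_ndvi)
  out[s$nodata_mask] <- FALSE
  out
}

# locate the forest dark peak of one window's red values; returns the
# red threshold or NA when no qualifying dark peak exists
forest_peak_threshold <- function(red_vals, cfg) {
  n <- length(red_vals)
  if (n < 10L) return(NA_real_)
  bw <- cfg$forest_bin_width
  breaks <- seq(0, 1 + bw, by = bw)
  h <- graphics::hist(pmin(red_vals, 1), breaks = breaks, plot = FALSE)
  counts <- h$counts
  k <- cfg$forest_smooth_bins
  sm <- as.numeric(stats::filter(counts, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  nb <- length(sm)
  prom <- cfg$forest_peak_prominence * n
  # local maxima that are prominent
  is_peak <- logical(nb)
  for (i in seq_len(nb)) {
    l <- if (i > 1) sm[i - 1] else -Inf
    r <- if (i < nb) sm[i + 1] else -Inf
    is_peak[i] <- sm[i] >= l && sm[i] >= r && sm[i] >= prom
  }
  mids <- h$mids
  cand <- which(is_peak & mids <= cfg$forest_red_max)
  if (!length(cand)) return(NA_real_)
  p <- cand[1]  # lowest-reflectance prominent dark mode
  half <- sm[p] / 2
  lo <- p; while (lo > 1 && sm[lo - 1] >= half) lo <- lo - 1
  hi <- p; while (hi < nb && sm[hi + 1] >= half) hi <- hi + 1
  width <- (hi - lo + 1) * bw  # full width at half prominence
  mids[p] + max(width, 2 * bw)
}

#' Forest mask from local red-band dark peaks
#'
#' Local windows of the red band are tiled across the scene; in each, the
#' lowest-reflectance prominent mode of the (smoothed) histogram is taken
#' as the forest peak, provided it sits at or below `cfg$forest_red_max`.
#' The window's forest threshold is the peak location plus a margin (the
#' peak's full width at half prominence, at least two bins); pixels at or
#' below the threshold are forest. Windows with no qualifying dark peak
#' contribute no forest pixels.
#'
#' @param s A `scene`.
#' @param cfg A [pipeline_config()]; uses `window_size`, `forest_*`.
#' @return Logical matrix.
#' @export
forest_mask <- function(s, cfg = pipeline_config()) {
  stopifnot(inherits(s, "scene"))
  red <- s$bands$red
  nr <- nrow(red); nc <- ncol(red)
  out <- matrix(FALSE, nr, nc)
  ws <- cfg$window_size
  for (r0 in seq(1, nr, by = ws)) {
    for (c0 in seq(1, nc, by = ws)) {
      rs <- r0:min(nr, r0 + ws - 1)
      cs <- c0:min(nc, c0 + ws - 1)
      sub <- red[rs, cs, drop = FALSE]
      ok <- !s$nodata_mask[rs, cs, drop = FALSE]
      if (!any(ok)) next
      thr <- forest_peak_threshold(sub[ok], cfg)
      if (is.na(thr)) next
      out[rs, cs] <- sub <= thr & ok
    }
  }
  out
}

#' Cloud and cloud-shadow masks
#'
#' A simplified spectral-thermal screen with geometric shadow projection.
#' Cloud candidates must pass a brightness test (blue above
#' `cfg$cloud_blue_min` and SWIR-1 above `cfg$cloud_swir_min`), a
#' whiteness test (mean absolute deviation of the visible bands from
#' their mean, relative to that mean, below `cfg$cloud_whiteness_max`)
#' and, when a thermal plane is present, a coldness test (brightness
#' temperature at least `cfg$cloud_bt_margin` Kelvin below the scene
#' median); the candidate layer is cleaned by binary opening. For each
#' connected cloud object, candidate shadows are projected along the
#' anti-solar azimuth over a sweep of cloud-base heights and the
#' projection that best overlaps dark-NIR pixels is kept.
#'
#' @param s A `scene` (thermal optional; without it the screen degrades
#'   to spectral-only with a warning).
#' @param cfg A [pipeline_config()].
#' @return List with logical matrices `cloud` and `shadow`.
#' @export
cloud_shadow_mask <- function(s, cfg = pipeline_config()) {
  stopifnot(inherits(s, "scene"))
  b <- s$bands
  ok <- !s$nodata_mask
  bright <- b$blue > cfg$cloud_blue_min & b$swir1 > cfg$cloud_swir_min
  vis_mean <- (b$blue + b$green + b$red) / 3
  white <- (abs(b$blue - vis_mean) + abs(b$green - vis_mean) +
              abs(b$red - vis_mean)) / pmax(vis_mean, 1e-6) <
    cfg$cloud_whiteness_max
  cand <- bright & white & ok
  if (is.null(s$thermal)) {
    warning("no thermal plane: cloud test is spectral-only")
  } else {
    med <- stats::median(s$thermal[ok])
    cand <- cand & s$thermal < med - cfg$cloud_bt_margin
  }
  cloud <- open_binary(cand, cfg$morph_radius)

  shadow <- matrix(FALSE, nrow(cloud), ncol(cloud))
  if (any(cloud)) {
    dark <- b$nir < cfg$shadow_nir_max & ok & !cloud
    lab <- label_components(cloud * 1L, background = 0L)
    az <- (s$sun_azimuth + 180) * pi / 180
    heights <- seq(cfg$cloud_height_min, cfg$cloud_height_max,
                   by = cfg$cloud_height_step)
    px <- s$grid$pixel_size %||% 30
    for (id in seq_len(max(lab))) {
      obj <- lab == id
      best <- NULL; best_score <- -1
      for (h in heights) {
        d_px <- h * tan(s$sun_zenith * pi / 180) / px
        proj <- shift_mask(obj, round(-cos(az) * d_px), round(sin(az) * d_px))
        score <- sum(proj & dark) / max(sum(proj), 1)
        if (score > best_score) { best_score <- score; best <- proj }
      }
      if (best_score > 0) shadow <- shadow | (best & !cloud)
    }
  }
  list(cloud = cloud, shadow = shadow)
}

#' Combine per-date masks into the valid-analysis mask set
#'
#' The valid plane excludes every pixel that is cloud, cloud shadow or
#' water at either date or nodata in either scene, and restricts analysis
#' to the early date's forest mask (pre-disturbance forest, so pixels
#' cleared between the dates stay inside the analysis region).
#'
#' @param p A `scene_pair`.
#' @param cfg A [pipeline_config()].
#' @param masks Optional precomputed list with per-date `cloud`, `shadow`,
#'   `water`, `forest` planes (elements `cloud1`, `cloud2`, ...); computed
#'   from `p` when omitted.
#' @return An object of class `mask_set`: per-date planes plus `valid`.
#' @export
combine_masks <- function(p, cfg = pipeline_config(), masks = NULL) {
  stopifnot(inherits(p, "scene_pair"))
  if (is.null(masks)) {
    cs1 <- cloud_shadow_mask(p$early, cfg)
    cs2 <- cloud_shadow_mask(p$late, cfg)
    masks <- list(cloud1 = cs1$cloud, shadow1 = cs1$shadow,
                  cloud2 = cs2$cloud, shadow2 = cs2$shadow,
                  water1 = water_mask(p$early, cfg),
                  water2 = water_mask(p$late, cfg),
                  forest1 = forest_mask(p$early, cfg),
                  forest2 = forest_mask(p$late, cfg))
  }
  dims <- dim(p$early$bands$red)
  for (nm in names(masks))
    if (!identical(dim(masks[[nm]]), dims))
      stop("registration error: mask '", nm, "' is not on the pair grid")
  nodata <- p$early$nodata_mask | p$late$nodata_mask
  valid <- !(masks$cloud1 | masks$cloud2 | masks$shadow1 | masks$shadow2 |
               masks$water1 | masks$water2 | nodata) & masks$forest1
  structure(c(masks, list(nodata = nodata, valid = valid)),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set %d x %d px, %.1f%% valid>\n", nrow(x$valid),
              ncol(x$valid), 100 * mean(x$valid)))
  invisible(x)
}
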