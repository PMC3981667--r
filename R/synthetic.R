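#' Default spectral archetypes of the synthetic scene generator
#'
#' Per-class mean TOA reflectance (fractions) for the six reflective bands
#' plus a brightness-temperature mean (Kelvin). These are package
#' constants chosen to satisfy the qualitative spectral orderings that the
#' pipeline's rules rely on (forest dark in red and SWIR; cleared surfaces
#' bright in SWIR; water below 25% SWIR with a decreasing
#' visible-to-infrared trend; clouds bright, white and cold). They are
#' synthetic stand-ins, not values measured from any sensor.
#'
#' Classes: `forest`, `cleared` (a disturbed pixel after clearing, and a
#' regrowth pixel before regreening), `ag_green`/`ag_bare` (the two
#' endmembers of the agriculture continuum: each field carries a
#' per-date phenological state in `[0, 1]` interpolating between them,
#' so cropping cycles flip brightness between dates and act as a change
#' confuser), `water`, `bare` (stable non-forest), `cloud`. Cloud shadow
#' is rendered by darkening the underlying surface by `shadow_factor`.
#'
#' @format Named list: per class a numeric vector
#'   `blue, green, red, nir, swir1, swir2, thermal`.
#' @export
default_archetypes <- function() {
  list(
    forest  = c(blue = 0.04, green = 0.06, red = 0.03, nir = 0.30,
                swir1 = 0.10, swir2 = 0.05, thermal = 295),
    cleared = c(blue = 0.08, green = 0.10, red = 0.12, nir = 0.22,
                swir1 = 0.28, swir2 = 0.20, thermal = 303),
    ag_green = c(blue = 0.05, green = 0.08, red = 0.07, nir = 0.45,
                 swir1 = 0.18, swir2 = 0.10, thermal = 297),
    ag_bare  = c(blue = 0.09, green = 0.12, red = 0.14, nir = 0.28,
                 swir1 = 0.32, swir2 = 0.24, thermal = 302),
    water   = c(blue = 0.06, green = 0.05, red = 0.03, nir = 0.02,
                swir1 = 0.01, swir2 = 0.01, thermal = 290),
    bare    = c(blue = 0.12, green = 0.14, red = 0.16, nir = 0.22,
                swir1 = 0.30, swir2 = 0.25, thermal = 303),
    cloud   = c(blue = 0.60, green = 0.60, red = 0.60, nir = 0.60,
                swir1 = 0.60, swir2 = 0.60, thermal = 275)
  )
}

#' Specify a synthetic bi-temporal scene pair
#'
#' Defines the study conditions for generated imagery: image size, target
#' class fractions, patch geometry, per-band noise, spectral archetypes
#' and solar geometry. Fractions are of the whole image; their sum must
#' not exceed 1 and the remainder becomes stable non-forest (`bare`).
#'
#' @param width,height Image size in pixels.
#' @param frac_forest Stable-forest fraction target.
#' @param frac_disturbance Forest at date 1, cleared at date 2.
#' @param frac_regrowth Cleared at date 1, forest at date 2.
#' @param frac_agriculture,frac_water Confuser-class fractions.
#' @param frac_cloud Per-date cloud cover fraction (placed independently
#'   at each date; shadows are cast from the clouds, not counted here).
#' @param patch_area_min,patch_area_max Patch areas are drawn log-uniform
#'   between these bounds (pixels).
#' @param noise_sd Per-band Gaussian noise SD (reflectance fraction).
#' @param thermal_noise_sd Thermal noise SD (Kelvin).
#' @param clutter_frac Fraction of pixels per date that receive an extra
#'   broadband perturbation, emulating the residual heterogeneity of real
#'   imagery (mixed pixels, phenology, misregistration). Clutter in the
#'   no-change bulk is what pushes individual pixels across the local
#'   training thresholds and so produces incoherent label noise.
#' @param clutter_sd SD of the clutter perturbation (reflectance
#'   fraction), drawn independently per band and date.
#' @param archetypes Archetype list as [default_archetypes()].
#' @param shadow_factor Multiplier darkening surfaces under cloud shadow.
#' @param cloud_height Cloud-base height (metres) used to displace shadows
#'   along the anti-solar azimuth.
#' @param sun_zenith,sun_azimuth Solar geometry in degrees.
#' @param pixel_size Grid pixel size in metres.
#' @param dates Length-2 vector of acquisition dates.
#' @param seed Integer seed; the same spec generates bit-identical output.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 256, height = 256,
                       frac_forest = 0.55,
                       frac_disturbance = 0.08,
                       frac_regrowth = 0.04,
                       frac_agriculture = 0.15,
                       frac_water = 0.05,
                       frac_cloud = 0.03,
                       patch_area_min = 40,
                       patch_area_max = 2000,
                       noise_sd = 0.01,
                       thermal_noise_sd = 1,
                       clutter_frac = 0.02,
                       clutter_sd = 0.08,
                       archetypes = default_archetypes(),
                       shadow_factor = 0.3,
                       cloud_height = 1000,
                       sun_zenith = 30,
                       sun_azimuth = 135,
                       pixel_size = 30,
                       dates = as.Date(c("2000-07-01", "2005-07-01")),
                       seed = 1L) {
  fr <- c(forest = frac_forest, disturbance = frac_disturbance,
          regrowth = frac_regrowth, agriculture = frac_agriculture,
          water = frac_water, cloud = frac_cloud)
  if (any(fr < 0) || any(fr > 1)) stop("spec error: fractions must lie in [0, 1]")
  if (sum(fr[setdiff(names(fr), "cloud")]) > 1)
    stop("spec error: land-class fractions sum to more than 1")
  if (noise_sd < 0 || thermal_noise_sd < 0 || clutter_sd < 0)
    stop("spec error: noise SD must be >= 0")
  if (clutter_frac < 0 || clutter_frac > 1)
    stop("spec error: clutter_frac must lie in [0, 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 fractions = fr,
                 patch_area_min = patch_area_min,
                 patch_area_max = patch_area_max,
                 noise_sd = noise_sd, thermal_noise_sd = thermal_noise_sd,
                 clutter_frac = clutter_frac, clutter_sd = clutter_sd,
                 archetypes = archetypes, shadow_factor = shadow_factor,
                 cloud_height = cloud_height,
                 sun_zenith = sun_zenith, sun_azimuth = sun_azimuth,
                 pixel_size = pixel_size, dates = as.Date(dates),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- patch placement ---------------------------------------------------

rect_patch <- function(nr, nc, area) {
  ar <- stats::runif(1, 0.3, 3)           # aspect ratio
  h <- max(1L, round(sqrt(area * ar)))
  w <- max(1L, round(area / h))
  r0 <- sample.int(max(1L, nr - h + 1L), 1L)
  c0 <- sample.int(max(1L, nc - w + 1L), 1L)
  cbind(rep(r0:min(nr, r0 + h - 1L), each = min(w, nc - c0 + 1L)),
        rep(c0:min(nc, c0 + w - 1L), times = min(h, nr - r0 + 1L)))
}

blob_patch <- function(nr, nc, area) {
  # dilated random walk: ragged boundary
  target <- max(4L, round(area / 4))
  r <- sample.int(nr, 1L); c <- sample.int(nc, 1L)
  seen <- matrix(FALSE, nr, nc)
  seen[r, c] <- TRUE
  n <- 1L; guard <- 0L
  while (n < target && guard < area * 20L) {
    guard <- guard + 1L
    step <- sample.int(4L, 1L)
    r <- min(nr, max(1L, r + c(-1L, 1L, 0L, 0L)[step]))
    c <- min(nc, max(1L, c + c(0L, 0L, -1L, 1L)[step]))
    if (!seen[r, c]) { seen[r, c] <- TRUE; n <- n + 1L }
  }
  seen <- dilate_binary(seen, 1L)
  which(seen, arr.ind = TRUE)
}

# place patches of `value` into canvas (restricted to allowed cells) until
# the image-wide fraction of `value` reaches target; `state$ids` records a
# distinct patch id per placed patch
place_patches <- function(state, allowed, value, target_frac, spec) {
  canvas <- state$canvas
  total <- length(canvas)
  attempts <- 0L
  while (sum(canvas == value) / total < target_frac && attempts < 400L) {
    attempts <- attempts + 1L
    deficit <- target_frac * total - sum(canvas == value)
    amax <- min(spec$patch_area_max, max(spec$patch_area_min, deficit * 2))
    area <- exp(stats::runif(1, log(spec$patch_area_min), log(amax)))
    pix <- if (stats::runif(1) < 0.5)
      rect_patch(nrow(canvas), ncol(canvas), area)
    else blob_patch(nrow(canvas), ncol(canvas), area)
    keep <- allowed[pix]
    pix <- pix[keep, , drop = FALSE]
    if (nrow(pix)) {
      canvas[pix] <- value
      state$next_id <- state$next_id + 1L
      state$ids[pix] <- state$next_id
    }
  }
  state$canvas <- canvas
  state
}

shadow_offset <- function(spec) {
  d_px <- spec$cloud_height * tan(spec$sun_zenith * pi / 180) / spec$pixel_size
  az <- (spec$sun_azimuth + 180) * pi / 180  # anti-solar direction
  c(drow = round(-cos(az) * d_px), dcol = round(sin(az) * d_px))
}

shift_mask <- function(mask, drow, dcol) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  src <- which(mask, arr.ind = TRUE)
  if (!nrow(src)) return(out)
  r <- src[, 1] + drow; c <- src[, 2] + dcol
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  out[cbind(r[ok], c[ok])] <- TRUE
  out
}

#' Corrupt the forest gate of a mask set
#'
#' Experimental harness for filter-efficacy studies: admits a random
#' fraction of non-forest land pixels (agriculture, bare ground, cleared
#' surfaces) into the early-date forest mask and rebuilds the combined
#' valid plane. Pixels of confuser classes then enter training extraction
#' and, when their difference values fall in a tail, produce mislabelled
#' samples - emulating the label noise that imperfect forest/non-forest
#' masking causes on real imagery.
#'
#' @param pair The `scene_pair` the masks belong to.
#' @param masks A `mask_set` from [combine_masks()].
#' @param truth The matching `truth_maps`.
#' @param fraction Fraction of eligible non-forest land pixels admitted.
#' @param cfg A [pipeline_config()]; `rng_seed` drives the draw.
#' @return A corrupted `mask_set`.
#' @export
corrupt_forest_mask <- function(pair, masks, truth, fraction = 0.3,
                                cfg = pipeline_config()) {
  stopifnot(inherits(masks, "mask_set"), inherits(truth, "truth_maps"))
  eligible <- !masks$forest1 & !truth$water &
    !masks$cloud1 & !masks$cloud2 & !masks$shadow1 & !masks$shadow2 &
    truth$class1 %in% c("agriculture", "bare", "cleared")
  ix <- which(eligible)
  with_local_seed(cfg$rng_seed + 5L, {
    take <- sample(ix, round(fraction * length(ix)))
    f1 <- masks$forest1
    f1[take] <- TRUE
    combine_masks(pair, cfg,
                  masks = list(cloud1 = masks$cloud1, shadow1 = masks$shadow1,
                               cloud2 = masks$cloud2, shadow2 = masks$shadow2,
                               water1 = masks$water1, water2 = masks$water2,
                               forest1 = f1, forest2 = masks$forest2))
  })
}

#' Generate a synthetic scene pair with per-pixel truth
#'
#' Renders two co-registered scenes from a [scene_spec()]: a patchwork of
#' forest, cleared/disturbed forest, regrowth, agriculture (which flips
#' brightness between dates), water and stable bare ground, plus per-date
#' clouds whose shadows are displaced along the anti-solar azimuth by
#' `cloud_height * tan(sun_zenith)`. Reflectances are archetype means plus
#' Gaussian noise, clipped to (0, 1). Deterministic given `spec$seed`.
#'
#' @param spec A `scene_spec`.
#' @return A list with elements `pair` (a `scene_pair`) and `truth`
#'   (class `truth_maps`): per-date class matrices (`class1`, `class2`),
#'   `change` matrix (`"disturbed"`, `"regrowth"`, `"none"`), and logical
#'   truth masks `water`, `forest1`, `forest2`, `cloud1`, `cloud2`,
#'   `shadow1`, `shadow2`.
#' @export
generate_scene_pair <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    nr <- spec$height; nc <- spec$width
    fr <- spec$fractions
    st <- list(canvas = matrix("bare", nr, nc),
               ids = matrix(0L, nr, nc), next_id = 0L)
    # forest super-region hosts stable forest + disturbance + regrowth
    super <- fr[["forest"]] + fr[["disturbance"]] + fr[["regrowth"]]
    st <- place_patches(st, matrix(TRUE, nr, nc), "forest", super, spec)
    st <- place_patches(st, st$canvas == "forest", "disturbance",
                        fr[["disturbance"]], spec)
    st <- place_patches(st, st$canvas == "forest", "regrowth",
                        fr[["regrowth"]], spec)
    st <- place_patches(st, st$canvas == "bare", "water", fr[["water"]], spec)
    st <- place_patches(st, st$canvas == "bare", "agriculture",
                        fr[["agriculture"]], spec)
    base <- st$canvas

    class1 <- base
    class1[base == "disturbance"] <- "forest"
    class1[base == "regrowth"] <- "cleared"
    class2 <- base
    class2[base == "disturbance"] <- "cleared"
    class2[base == "regrowth"] <- "forest"

    change <- matrix("none", nr, nc)
    change[base == "disturbance"] <- "disturbed"
    change[base == "regrowth"] <- "regrowth"

    # per-field phenological states of the agriculture continuum:
    # a per-patch base state per date plus per-pixel jitter
    ag <- base == "agriculture"
    ag_state <- list(matrix(NA_real_, nr, nc), matrix(NA_real_, nr, nc))
    if (any(ag)) {
      patch_ids <- unique(st$ids[ag])
      for (d in 1:2) {
        b_patch <- stats::setNames(stats::runif(length(patch_ids)), patch_ids)
        v <- b_patch[as.character(st$ids[ag])] +
          stats::rnorm(sum(ag), 0, 0.15)
        ag_state[[d]][ag] <- pmin(pmax(v, 0), 1)
      }
    }

    off <- shadow_offset(spec)
    clouds <- shadows <- list()
    for (d in 1:2) {
      cl <- list(canvas = matrix(FALSE, nr, nc),
                 ids = matrix(0L, nr, nc), next_id = 0L)
      cl <- place_patches(cl, matrix(TRUE, nr, nc), TRUE,
                          fr[["cloud"]], spec)
      sh <- shift_mask(cl$canvas, off[["drow"]], off[["dcol"]]) & !cl$canvas
      clouds[[d]] <- cl$canvas; shadows[[d]] <- sh
    }

    render <- function(cls, cloud, shadow, ag_v) {
      bands <- list()
      arch <- spec$archetypes
      clutter_ix <- if (spec$clutter_frac > 0)
        sample.int(nr * nc, round(spec$clutter_frac * nr * nc)) else integer(0)
      for (b in BAND_ROLES) {
        m <- matrix(0, nr, nc)
        for (k in setdiff(unique(as.vector(cls)), "agriculture"))
          m[cls == k] <- arch[[k]][[b]]
        if (any(ag))
          m[ag] <- ag_v[ag] * arch$ag_green[[b]] +
            (1 - ag_v[ag]) * arch$ag_bare[[b]]
        m[cloud] <- arch$cloud[[b]]
        m[shadow & !cloud] <- m[shadow & !cloud] * spec$shadow_factor
        m <- m + stats::rnorm(nr * nc, 0, spec$noise_sd)
        if (length(clutter_ix))
          m[clutter_ix] <- m[clutter_ix] +
            stats::rnorm(length(clutter_ix), 0, spec$clutter_sd)
        bands[[b]] <- pmin(pmax(m, 0.001), 0.999)
      }
      th <- matrix(0, nr, nc)
      for (k in setdiff(unique(as.vector(cls)), "agriculture"))
        th[cls == k] <- arch[[k]][["thermal"]]
      if (any(ag))
        th[ag] <- ag_v[ag] * arch$ag_green[["thermal"]] +
          (1 - ag_v[ag]) * arch$ag_bare[["thermal"]]
      th[cloud] <- arch$cloud[["thermal"]]
      th[shadow & !cloud] <- th[shadow & !cloud] - 3
      th <- th + stats::rnorm(nr * nc, 0, spec$thermal_noise_sd)
      list(bands = bands, thermal = th)
    }

    grid <- list(origin_x = 5e5, origin_y = 5e6,
                 pixel_size = spec$pixel_size, crs = "synthetic-utm")
    r1 <- render(class1, clouds[[1]], shadows[[1]], ag_state[[1]])
    r2 <- render(class2, clouds[[2]], shadows[[2]], ag_state[[2]])
    s1 <- new_scene(r1$bands, spec$dates[1], thermal = r1$thermal,
                    sun_zenith = spec$sun_zenith,
                    sun_azimuth = spec$sun_azimuth, grid = grid)
    s2 <- new_scene(r2$bands, spec$dates[2], thermal = r2$thermal,
                    sun_zenith = spec$sun_zenith,
                    sun_azimuth = spec$sun_azimuth, grid = grid)

    truth <- structure(list(
      class1 = class1, class2 = class2, change = change,
      water = base == "water",
      forest1 = class1 == "forest",
      forest2 = class2 == "forest",
      cloud1 = clouds[[1]], cloud2 = clouds[[2]],
      shadow1 = shadows[[1]], shadow2 = shadows[[2]]
    ), class = "truth_maps")

    list(pair = pair_scenes(s1, s2), truth = truth)
  })
}
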