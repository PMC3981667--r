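#' Tasseled-cap (Kauth-Thomas) coefficient sets
#'
#' Returns the 3 x 6 matrix mapping the six reflective bands
#' (blue, green, red, nir, swir1, swir2) to brightness, greenness and
#' wetness for a given sensor. Packaged sets:
#'
#' * `"TM"` - Landsat 5 TM reflectance-factor coefficients
#'   (Crist 1985, Remote Sens. Environ. 17:301-306).
#' * `"ETM+"` - Landsat 7 ETM+ at-satellite reflectance coefficients
#'   (Huang et al. 2002, Int. J. Remote Sens. 23:1741-1748).
#' * `"synthetic"` - a documented identity-like stand-in used by unit
#'   tests so they do not depend on literature constants: brightness is
#'   the band mean, greenness contrasts NIR against red and SWIR,
#'   wetness contrasts the visible bands against SWIR.
#'
#' @param sensor `"TM"`, `"ETM+"` or `"synthetic"`.
#' @return Object of class `kt_coefficients`: a 3 x 6 numeric matrix with
#'   rownames `brightness, greenness, wetness`, colnames the band roles,
#'   and attributes `sensor` and `citation`.
#' @export
kt_coefficients <- function(sensor = c("TM", "ETM+", "synthetic")) {
  sensor <- match.arg(sensor)
  m <- switch(sensor,
    "TM" = rbind(
      brightness = c(0.2043, 0.4158, 0.5524, 0.5741, 0.3124, 0.2303),
      greenness  = c(-0.1603, -0.2819, -0.4934, 0.7940, -0.0002, -0.1446),
      wetness    = c(0.0315, 0.2021, 0.3102, 0.1594, -0.6806, -0.6109)),
    "ETM+" = rbind(
      brightness = c(0.3561, 0.3972, 0.3904, 0.6966, 0.2286, 0.1596),
      greenness  = c(-0.3344, -0.3544, -0.4556, 0.6966, -0.0242, -0.2630),
      wetness    = c(0.2626, 0.2141, 0.0926, 0.0656, -0.7629, -0.5388)),
    "synthetic" = rbind(
      brightness = rep(1 / 6, 6),
      greenness  = c(0, 0, -0.5, 1, -0.25, -0.25),
      wetness    = c(0.25, 0.25, 0, 0, -0.5, -0.5))
  )
  colnames(m) <- BAND_ROLES
  attr(m, "sensor") <- sensor
  attr(m, "citation") <- switch(sensor,
    "TM" = "Crist (1985) RSE 17:301-306, reflectance factors",
    "ETM+" = "Huang et al. (2002) IJRS 23:1741-1748, at-satellite reflectance",
    "synthetic" = "package stand-in for unit testing, not a literature set")
  class(m) <- c("kt_coefficients", class(m))
  m
}

#' Kauth-Thomas transform of a scene
#'
#' Each output pixel is the matrix product of the coefficient rows with
#' the pixel's six-band reflectance vector; the transform is linear with
#' no offset term.
#'
#' @param s A `scene`.
#' @param coef A [kt_coefficients()] matrix (default: the `"TM"` set).
#' @return List of matrices `brightness`, `greenness`, `wetness`.
#' @export
kt_transform <- function(s, coef = kt_coefficients("TM")) {
  stopifnot(inherits(s, "scene"))
  if (!inherits(coef, "kt_coefficients") ||
      !identical(dim(unclass(coef)), c(3L, 6L)))
    stop("configuration error: coef must be a 3 x 6 kt_coefficients matrix")
  X <- vapply(BAND_ROLES, function(b) as.vector(s$bands[[b]]),
              numeric(length(s$bands$red)))
  out <- X %*% t(unclass(coef))
  dims <- dim(s$bands$red)
  list(brightness = matrix(out[, 1], dims[1], dims[2]),
       greenness = matrix(out[, 2], dims[1], dims[2]),
       wetness = matrix(out[, 3], dims[1], dims[2]))
}

FEATURE_NAMES <- c("b1", "g1", "w1", "db", "dg", "dw")

#' Multi-temporal Kauth-Thomas feature stack
#'
#' Six planes in fixed order: the early date's brightness, greenness and
#' wetness, then the change components (late minus early) delta-B,
#' delta-G, delta-W. The early-date planes anchor the pre-disturbance
#' condition of forest; the deltas carry the change signal, so clearing
#' shows falling wetness (delta-W < 0). Swapping the dates negates the
#' delta planes exactly.
#'
#' @param p A `scene_pair`.
#' @param coef A [kt_coefficients()] matrix.
#' @return Object of class `feature_stack`: list of matrices
#'   `b1, g1, w1, db, dg, dw`.
#' @export
mkt_stack <- function(p, coef = kt_coefficients("TM")) {
  stopifnot(inherits(p, "scene_pair"))
  kt1 <- kt_transform(p$early, coef)
  kt2 <- kt_transform(p$late, coef)
  structure(list(b1 = kt1$brightness, g1 = kt1$greenness, w1 = kt1$wetness,
                 db = kt2$brightness - kt1$brightness,
                 dg = kt2$greenness - kt1$greenness,
                 dw = kt2$wetness - kt1$wetness),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack %d x %d px, planes: %s>\n", nrow(x$b1),
              ncol(x$b1), paste(FEATURE_NAMES, collapse = " ")))
  invisible(x)
}

#' SWIR difference image
#'
#' `early - late` SWIR reflectance (band configurable through
#' `cfg$diff_band`). Forest clearing raises SWIR at the second date, so
#' disturbance sits in the large-negative tail of this image; regrowth in
#' the positive tail.
#'
#' @param p A `scene_pair`.
#' @param cfg A [pipeline_config()] (only `diff_band` is used).
#' @return Numeric matrix (reflectance fraction difference).
#' @export
swir_difference <- function(p, cfg = pipeline_config()) {
  stopifnot(inherits(p, "scene_pair"))
  band <- cfg$diff_band
  p$early$bands[[band]] - p$late$bands[[band]]
}
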