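#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

BAND_ROLES <- c("blue", "green", "red", "nir", "swir1", "swir2")
THERMAL_SCALE <- 1000  # Kelvin stored as K/1000 in float TIFF

# Map category codes of the final six-category product.
CHANGE_CODES <- c(nodata = 0L, disturbed = 1L, stable_forest = 2L,
                  stable_nonforest = 3L, water = 4L, cloud = 5L,
                  cloud_shadow = 6L)

#' Construct a single-date scene
#'
#' A scene is six co-registered reflective planes (top-of-atmosphere
#' reflectance fractions in `[0, 1]`), an optional thermal plane
#' (brightness temperature, Kelvin), a nodata mask, the solar geometry and
#' the grid (geotransform + CRS). All algorithms in the package work in
#' pixel space; the geotransform is used only at I/O boundaries.
#'
#' @param bands Named list of numeric matrices; names must be exactly
#'   `blue, green, red, nir, swir1, swir2`.
#' @param date Acquisition date (`Date` or coercible).
#' @param thermal Brightness-temperature matrix in Kelvin, or `NULL`.
#' @param nodata_mask Logical matrix, `TRUE` where no data; defaults to
#'   non-finite pixels in any band.
#' @param sun_zenith,sun_azimuth Solar geometry in degrees
#'   (`0 <= zenith < 90`, `0 <= azimuth < 360`).
#' @param grid List with elements `origin_x`, `origin_y`, `pixel_size`
#'   (metres), `crs` (character); defaults to a 30 m grid at the origin.
#' @return An object of class `scene`.
#' @export
new_scene <- function(bands, date, thermal = NULL, nodata_mask = NULL,
                      sun_zenith = 30, sun_azimuth = 135, grid = NULL) {
  if (!setequal(names(bands), BAND_ROLES))
    stop("bands must be named exactly: ", paste(BAND_ROLES, collapse = ", "))
  bands <- lapply(bands[BAND_ROLES], function(b) {
    b <- as.matrix(b); storage.mode(b) <- "double"; b
  })
  dims <- dim(bands[[1]])
  for (nm in BAND_ROLES)
    if (!identical(dim(bands[[nm]]), dims))
      stop("registration error: band '", nm, "' dimensions differ")
  if (!is.null(thermal)) {
    thermal <- as.matrix(thermal); storage.mode(thermal) <- "double"
    if (!identical(dim(thermal), dims))
      stop("registration error: thermal plane dimensions differ")
  }
  if (is.null(nodata_mask)) {
    nodata_mask <- Reduce(`|`, lapply(bands, function(b) !is.finite(b)))
  } else {
    nodata_mask <- as.matrix(nodata_mask)
    storage.mode(nodata_mask) <- "logical"
    if (!identical(dim(nodata_mask), dims))
      stop("registration error: nodata mask dimensions differ")
  }
  if (sun_zenith < 0 || sun_zenith >= 90) stop("sun_zenith must be in [0, 90)")
  if (sun_azimuth < 0 || sun_azimuth >= 360) stop("sun_azimuth must be in [0, 360)")
  if (is.null(grid))
    grid <- list(origin_x = 0, origin_y = 0, pixel_size = 30, crs = "local")
  ok <- !nodata_mask
  for (nm in BAND_ROLES) {
    v <- bands[[nm]][ok]
    if (length(v) && (anyNA(v) || min(v) < -1e-9 || max(v) > 1 + 1e-9))
      stop("reflectance outside [0, 1] on valid pixels in band '", nm, "'")
  }
  structure(list(bands = bands, thermal = thermal, nodata_mask = nodata_mask,
                 date = as.Date(date), sun_zenith = sun_zenith,
                 sun_azimuth = sun_azimuth, grid = grid,
                 dims = dims),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene %s  %d x %d px  %s  zen %.1f az %.1f>\n",
              format(x$date), x$dims[1], x$dims[2],
              if (is.null(x$thermal)) "no thermal" else "thermal",
              x$sun_zenith, x$sun_azimuth))
  invisible(x)
}

#' @export
dim.scene <- function(x) x$dims

same_grid <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$grid$origin_x, b$grid$origin_x)) &&
    isTRUE(all.equal(a$grid$origin_y, b$grid$origin_y)) &&
    isTRUE(all.equal(a$grid$pixel_size, b$grid$pixel_size)) &&
    identical(a$grid$crs, b$grid$crs)
}

#' Pair two scenes chronologically
#'
#' Scenes must share an identical grid (pairwise change detection relies on
#' good geometric correction); the result is ordered early/late regardless
#' of argument order.
#'
#' @param a,b `scene` objects on the same grid with distinct dates.
#' @return An object of class `scene_pair` with elements `early` and `late`.
#' @export
pair_scenes <- function(a, b) {
  stopifnot(inherits(a, "scene"), inherits(b, "scene"))
  if (!same_grid(a, b))
    stop("registration error: scenes are not on an identical grid")
  if (a$date == b$date) stop("scenes must have distinct acquisition dates")
  if (a$date > b$date) { tmp <- a; a <- b; b <- tmp }
  structure(list(early = a, late = b), class = "scene_pair")
}

#' @export
print.scene_pair <- function(x, ...) {
  cat(sprintf("<scene_pair %s -> %s  %d x %d px>\n", format(x$early$date),
              format(x$late$date), x$early$dims[1], x$early$dims[2]))
  invisible(x)
}

scene_sidecar <- function(scene, band_files, thermal_file) {
  list(date = format(scene$date),
       sun_zenith = scene$sun_zenith, sun_azimuth = scene$sun_azimuth,
       grid = scene$grid,
       reflectance_scale = 1,
       thermal_scale = THERMAL_SCALE,
       bands = as.list(stats::setNames(band_files, BAND_ROLES)),
       thermal = thermal_file)
}

write_plane_tiff <- function(m, path, bits = 32) {
  m2 <- m
  m2[!is.finite(m2)] <- 0
  tiff::writeTIFF(m2, path, bits.per.sample = bits)
}

#' Write a scene to single-band TIFFs plus a YAML sidecar
#'
#' Reflective bands are written as 32-bit float TIFFs holding reflectance
#' fractions; thermal is scaled by the factor recorded in the sidecar; the
#' nodata mask is an 8-bit 0/1 TIFF. Georeferencing, the acquisition date
#' and the solar geometry travel in the YAML sidecar (plain TIFF container,
#' no embedded geotags).
#'
#' @param scene A `scene`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Path of the YAML sidecar, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  band_files <- paste0(prefix, "_", BAND_ROLES, ".tif")
  for (i in seq_along(BAND_ROLES))
    write_plane_tiff(scene$bands[[BAND_ROLES[i]]], file.path(dir, band_files[i]))
  thermal_file <- NULL
  if (!is.null(scene$thermal)) {
    thermal_file <- paste0(prefix, "_thermal.tif")
    write_plane_tiff(scene$thermal / THERMAL_SCALE, file.path(dir, thermal_file))
  }
  mask_file <- paste0(prefix, "_nodata.tif")
  write_plane_tiff(scene$nodata_mask * 1, file.path(dir, mask_file), bits = 8)
  meta <- scene_sidecar(scene, band_files, thermal_file)
  meta$nodata <- mask_file
  sidecar <- file.path(dir, paste0(prefix, ".yaml"))
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}

#' Read a scene from band files and a metadata sidecar
#'
#' `read_scene(sidecar)` reads the YAML written by [write_scene()].
#' Alternatively pass `band_paths` (named by role) and `metadata` directly.
#' All bands must share identical dimensions; nodata is propagated from the
#' mask file and from non-finite pixels of any band.
#'
#' @param sidecar Path to a YAML sidecar.
#' @param band_paths Optional named character vector of TIFF paths
#'   (overrides the sidecar's `bands` entry).
#' @param metadata Optional list overriding sidecar fields.
#' @return A `scene`.
#' @export
read_scene <- function(sidecar, band_paths = NULL, metadata = NULL) {
  meta <- yaml::read_yaml(sidecar)
  if (!is.null(metadata)) meta[names(metadata)] <- metadata
  dir <- dirname(sidecar)
  paths <- if (is.null(band_paths)) unlist(meta$bands) else band_paths
  bands <- lapply(BAND_ROLES, function(r) {
    p <- paths[[r]]
    if (!file.exists(p)) p <- file.path(dir, p)
    tiff::readTIFF(p) * (meta$reflectance_scale %||% 1)
  })
  names(bands) <- BAND_ROLES
  dims <- dim(bands[[1]])
  for (r in BAND_ROLES)
    if (!identical(dim(bands[[r]]), dims))
      stop("registration error: band '", r, "' grid mismatch")
  thermal <- NULL
  if (!is.null(meta$thermal)) {
    p <- meta$thermal
    if (!file.exists(p)) p <- file.path(dir, p)
    thermal <- tiff::readTIFF(p) * (meta$thermal_scale %||% THERMAL_SCALE)
  }
  nodata <- NULL
  if (!is.null(meta$nodata)) {
    p <- meta$nodata
    if (!file.exists(p)) p <- file.path(dir, p)
    nodata <- round(tiff::readTIFF(p) * 255) > 0 |
      Reduce(`|`, lapply(bands, function(b) !is.finite(b)))
  }
  new_scene(bands, date = meta$date, thermal = thermal, nodata_mask = nodata,
            sun_zenith = meta$sun_zenith %||% 30,
            sun_azimuth = meta$sun_azimuth %||% 135,
            grid = meta$grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a change map
#'
#' @param codes Integer matrix of category codes: 0 nodata, 1 disturbed,
#'   2 stable forest, 3 stable non-forest, 4 water, 5 cloud,
#'   6 cloud shadow.
#' @param grid Grid list as in [new_scene()].
#' @param polygons Optional polygon tibble from [polygonize()]; built
#'   automatically when omitted.
#' @return An object of class `change_map` with fields `codes`, `grid`,
#'   `polygons` (tibble: `polygon_id, class_code, class, n_pixels, pixels`).
#' @export
new_change_map <- function(codes, grid = NULL, polygons = NULL) {
  codes <- as.matrix(codes); storage.mode(codes) <- "integer"
  if (!all(codes %in% 0:6)) stop("change-map codes must lie in 0..6")
  if (is.null(grid))
    grid <- list(origin_x = 0, origin_y = 0, pixel_size = 30, crs = "local")
  if (is.null(polygons)) polygons <- polygonize(codes)
  structure(list(codes = codes, grid = grid, polygons = polygons),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  tab <- table(factor(x$codes, levels = 0:6,
                      labels = names(sort(CHANGE_CODES))))
  cat(sprintf("<change_map %d x %d px, %d polygons>\n", nrow(x$codes),
              ncol(x$codes), nrow(x$polygons)))
  print(tab)
  invisible(x)
}

#' Vectorize a categorical raster into a polygon table
#'
#' Connected components (8-connectivity, matching the segmenter) of equal
#' code become one polygon each; nodata (code 0) is not vectorized. The
#' geometry is kept as pixel indices; [write_change_map()] expands it to
#' GeoJSON rings of row-run rectangles, which tile the classified area
#' exactly.
#'
#' @param codes Integer matrix of category codes.
#' @return Tibble with `polygon_id`, `class_code`, `class`, `n_pixels`,
#'   and a list-column `pixels` of (row, col) matrices.
#' @export
polygonize <- function(codes) {
  codes <- as.matrix(codes); storage.mode(codes) <- "integer"
  lab <- label_components(codes, background = 0L)
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) {
    return(tibble(polygon_id = integer(), class_code = integer(),
                  class = character(), n_pixels = integer(),
                  pixels = list()))
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  lb <- lab[lab > 0L]
  ord <- order(lb)
  idx <- idx[ord, , drop = FALSE]
  lb <- lb[ord]
  splits <- split(seq_len(nrow(idx)), lb)
  code_of <- vapply(splits, function(s) codes[idx[s[1], 1], idx[s[1], 2]], 0L)
  nm <- names(CHANGE_CODES)
  tibble(
    polygon_id = as.integer(names(splits)),
    class_code = as.integer(code_of),
    class = nm[match(code_of, CHANGE_CODES)],
    n_pixels = vapply(splits, length, 0L),
    pixels = lapply(splits, function(s) idx[s, , drop = FALSE])
  )
}

# row/col (1-based, row 1 = top) -> map x/y of pixel corners
pixel_rect_ring <- function(row, col, grid) {
  px <- grid$pixel_size
  x0 <- grid$origin_x + (col - 1) * px
  y0 <- grid$origin_y - (row - 1) * px
  list(c(x0, y0), c(x0 + px, y0), c(x0 + px, y0 - px), c(x0, y0 - px),
       c(x0, y0))
}

run_rect_ring <- function(row, col_start, col_end, grid) {
  px <- grid$pixel_size
  x0 <- grid$origin_x + (col_start - 1) * px
  x1 <- grid$origin_x + col_end * px
  y0 <- grid$origin_y - (row - 1) * px
  y1 <- y0 - px
  lapply(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)),
         as.numeric)
}

polygon_multi_rings <- function(pix, grid) {
  # one rectangle per horizontal run of pixels; the union tiles the polygon
  rows <- split(pix[, 2], pix[, 1])
  rings <- list()
  for (r in names(rows)) {
    cols <- sort(rows[[r]])
    breaks <- c(0, which(diff(cols) > 1), length(cols))
    for (k in seq_len(length(breaks) - 1)) {
      cs <- cols[breaks[k] + 1]; ce <- cols[breaks[k + 1]]
      rings[[length(rings) + 1]] <-
        list(run_rect_ring(as.integer(r), cs, ce, grid))
    }
  }
  rings
}

#' Write a change map as a class TIFF and a GeoJSON polygon layer
#'
#' The raster holds the integer category codes (8-bit, lossless round
#' trip); the code table and grid are written to a YAML sidecar next to
#' it. Polygons are written as a GeoJSON FeatureCollection of MultiPolygon
#' features (row-run rectangles) with `class`, `class_code` and
#' `n_pixels` attributes; their pixel areas sum to the classified pixel
#' count.
#'
#' @param m A `change_map`.
#' @param raster_path Output TIFF path.
#' @param vector_path Output GeoJSON path.
#' @return Invisibly, a list of the two paths.
#' @export
write_change_map <- function(m, raster_path, vector_path) {
  stopifnot(inherits(m, "change_map"))
  for (p in c(raster_path, vector_path)) {
    d <- dirname(p)
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  ok <- tryCatch(tiff::writeTIFF(m$codes / 255, raster_path,
                                 bits.per.sample = 8),
                 error = function(e) stop("I/O error writing ", raster_path,
                                          ": ", conditionMessage(e),
                                          call. = FALSE))
  yaml::write_yaml(list(codes = as.list(CHANGE_CODES), grid = m$grid),
                   paste0(raster_path, ".yaml"))
  feats <- purrr::pmap(
    list(m$polygons$polygon_id, m$polygons$class,
         m$polygons$class_code, m$polygons$n_pixels, m$polygons$pixels),
    function(id, cls, code, n, pix) {
      list(type = "Feature",
           properties = list(polygon_id = id, class = cls,
                             class_code = code, n_pixels = n),
           geometry = list(type = "MultiPolygon",
                           coordinates = polygon_multi_rings(pix, m$grid)))
    })
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA),
             vector_path)
  invisible(list(raster = raster_path, vector = vector_path))
}

#' Read a change map written by [write_change_map()]
#'
#' @param raster_path Path of the class TIFF (its YAML sidecar must sit
#'   next to it).
#' @return A `change_map`; codes round-trip losslessly.
#' @export
read_change_map <- function(raster_path) {
  codes <- round(tiff::readTIFF(raster_path) * 255)
  storage.mode(codes) <- "integer"
  meta_path <- paste0(raster_path, ".yaml")
  grid <- if (file.exists(meta_path)) yaml::read_yaml(meta_path)$grid else NULL
  new_change_map(codes, grid = grid)
}
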