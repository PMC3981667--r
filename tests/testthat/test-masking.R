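random_scene <- function(dims, seed) {
  set.seed(seed)
  bands <- lapply(band_vals(), function(v)
    matrix(runif(prod(dims), 0, 0.6), dims[1], dims[2]))
  new_scene(bands, date = "2000-06-01")
}

test_that("water mask applies the printed thresholds", {
  w <- water_mask(uniform_scene(band_vals(red = 0.06, nir = 0.04,
                                          swir1 = 0.02)))
  expect_true(all(w))  # decreasing trend, low NDVI, low SWIR
  w <- water_mask(uniform_scene(band_vals(red = 0.06, nir = 0.04,
                                          swir1 = 0.30)))
  expect_false(any(w))  # SWIR at 30% can never be water
  # NDVI exactly at the cutoff with a non-decreasing trend is not water
  # (nir - red)/(nir + red) = 0.3 with red = 0.07, nir = 0.13
  w <- water_mask(uniform_scene(band_vals(red = 0.07, nir = 0.13,
                                          swir1 = 0.10)))
  expect_false(any(w))
})

test_that("water mask equals the exhaustive rule oracle on random rasters", {
  cfg <- pipeline_config()
  for (seed in 1:3) {
    s <- random_scene(c(24, 24), seed)
    expect_identical(water_mask(s, cfg), water_oracle(s, cfg))
  }
})

test_that("water mask is idempotent and ignores nodata", {
  s <- random_scene(c(16, 16), 7)
  s$nodata_mask[1:4, 1:4] <- TRUE
  w1 <- water_mask(s); w2 <- water_mask(s)
  expect_identical(w1, w2)
  expect_false(any(w1[1:4, 1:4]))
})

test_that("forest mask thresholds a two-level window between the modes", {
  set.seed(31)
  red <- matrix(0.15, 40, 40)
  dark <- sample.int(1600, 960)  # 60% dark forest mode
  red[dark] <- 0.03
  s <- uniform_scene(band_vals(), dims = c(40, 40))
  s$bands$red <- red
  cfg <- pipeline_config(window_size = 40)
  fm <- forest_mask(s, cfg)
  expect_identical(fm, red == 0.03)
})

test_that("a unimodal bright window yields no forest", {
  s <- uniform_scene(band_vals(red = 0.20), dims = c(32, 32))
  expect_false(any(forest_mask(s, pipeline_config(window_size = 32))))
})

test_that("noisy bimodal windows recover the dark population", {
  set.seed(12)
  n <- 64
  truth <- matrix(runif(n * n) < 0.55, n, n)
  red <- matrix(rnorm(n * n, 0.12, 0.01), n, n)
  red[truth] <- rnorm(sum(truth), 0.03, 0.01)
  s <- uniform_scene(band_vals(), dims = c(n, n))
  s$bands$red <- pmin(pmax(red, 0), 1)
  fm <- forest_mask(s, pipeline_config(window_size = 64))
  expect_gte(mean(fm == truth), 0.99)
})

test_that("cloud screen finds bright cold blocks and projects shadows", {
  n <- 96
  bands <- lapply(band_vals(red = 0.03, nir = 0.30), function(v)
    matrix(v, n, n))
  th <- matrix(295, n, n)
  block <- list(rows = 20:35, cols = 30:45)
  for (b in names(bands)) bands[[b]][block$rows, block$cols] <- 0.6
  th[block$rows, block$cols] <- 275
  s <- new_scene(bands, date = "2000-06-01", thermal = th,
                 sun_zenith = 30, sun_azimuth = 135,
                 grid = list(origin_x = 0, origin_y = 0, pixel_size = 30,
                             crs = "local"))
  cfg <- pipeline_config()
  cs <- cloud_shadow_mask(s, cfg)
  truth_cloud <- matrix(FALSE, n, n)
  truth_cloud[block$rows, block$cols] <- TRUE
  # cloud plane covers the block with spill at most the morph radius
  expect_true(all(cs$cloud[truth_cloud]))
  spill <- cs$cloud & !truth_cloud
  expect_true(all(which(spill, arr.ind = TRUE)[, 1] %in%
                    (min(block$rows) - 1):(max(block$rows) + 1)))
  expect_lte(sum(spill), 2 * (16 + 16 + 2) * cfg$morph_radius)
  # no bright pixels at all -> both planes empty
  s2 <- uniform_scene(band_vals(), dims = c(16, 16), thermal = 295)
  cs2 <- cloud_shadow_mask(s2, pipeline_config())
  expect_false(any(cs2$cloud)); expect_false(any(cs2$shadow))
})

test_that("shadow projection recovers the geometric displacement", {
  n <- 128
  h_true <- 1200; zen <- 35; az <- 135
  bands <- lapply(band_vals(red = 0.03, nir = 0.30), function(v)
    matrix(v, n, n))
  th <- matrix(295, n, n)
  cloud_rows <- 30:45; cloud_cols <- 40:55
  for (b in names(bands)) bands[[b]][cloud_rows, cloud_cols] <- 0.6
  th[cloud_rows, cloud_cols] <- 275
  # paint the true shadow: dark NIR at the projected location
  d_px <- h_true * tan(zen * pi / 180) / 30
  anti <- (az + 180) * pi / 180
  drow <- round(-cos(anti) * d_px); dcol <- round(sin(anti) * d_px)
  bands$nir[cloud_rows + drow, cloud_cols + dcol] <- 0.05
  s <- new_scene(bands, date = "2000-06-01", thermal = th,
                 sun_zenith = zen, sun_azimuth = az,
                 grid = list(origin_x = 0, origin_y = 0, pixel_size = 30,
                             crs = "local"))
  cs <- cloud_shadow_mask(s, pipeline_config())
  expect_gt(sum(cs$shadow), 0)
  sc <- colMeans(which(cs$shadow, arr.ind = TRUE))
  cc <- c(mean(cloud_rows), mean(cloud_cols))
  # recovered centroid within the height-sweep quantization of the truth
  expect_lt(sqrt(sum((sc - cc - c(drow, dcol))^2)), 5)
})

test_that("a scene without thermal degrades to a spectral-only screen", {
  s <- uniform_scene(band_vals(), dims = c(16, 16))
  expect_warning(cloud_shadow_mask(s, pipeline_config()), "thermal")
})

test_that("combined valid plane follows the set-arithmetic contract", {
  dims <- c(8, 8)
  s1 <- uniform_scene(band_vals(), dims = dims, date = "2000-06-01")
  s2 <- uniform_scene(band_vals(), dims = dims, date = "2005-06-01")
  p <- pair_scenes(s1, s2)
  set.seed(42)
  rnd <- function() matrix(runif(prod(dims)) < 0.2, dims[1], dims[2])
  masks <- list(cloud1 = rnd(), shadow1 = rnd(), cloud2 = rnd(),
                shadow2 = rnd(), water1 = rnd(), water2 = rnd(),
                forest1 = matrix(runif(prod(dims)) < 0.7, dims[1], dims[2]),
                forest2 = rnd())
  ms <- combine_masks(p, pipeline_config(), masks = masks)
  # brute-force set arithmetic oracle
  expected <- matrix(NA, dims[1], dims[2])
  for (i in 1:dims[1]) for (j in 1:dims[2]) {
    excluded <- masks$cloud1[i, j] || masks$cloud2[i, j] ||
      masks$shadow1[i, j] || masks$shadow2[i, j] ||
      masks$water1[i, j] || masks$water2[i, j]
    expected[i, j] <- !excluded && masks$forest1[i, j]
  }
  expect_identical(ms$valid, expected)
  # all-clear, all-forest -> everything valid
  clear <- lapply(masks, function(m) matrix(FALSE, dims[1], dims[2]))
  clear$forest1 <- clear$forest2 <- matrix(TRUE, dims[1], dims[2])
  expect_true(all(combine_masks(p, pipeline_config(), masks = clear)$valid))
  # cloudy at date 2 only -> invalid
  one <- clear; one$cloud2[3, 3] <- TRUE
  expect_false(combine_masks(p, pipeline_config(), masks = one)$valid[3, 3])
})
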