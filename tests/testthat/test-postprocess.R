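test_that("opening removes speckle and preserves solid blocks", {
  cfg <- pipeline_config()
  lab <- matrix(3L, 20, 20)
  expect_identical(morphological_clean(lab, cfg), lab)  # nothing disturbed

  lab1 <- lab; lab1[10, 10] <- 1L  # isolated disturbed pixel
  out <- morphological_clean(lab1, cfg)
  expect_equal(out[10, 10], 3L)
  expect_false(any(out == 1L))

  lab2 <- lab; lab2[5:14, 5:14] <- 1L  # solid 10x10 block
  out2 <- morphological_clean(lab2, cfg)
  expect_identical(out2, lab2)
  # opening is idempotent on the cleaned result
  expect_identical(morphological_clean(out2, cfg), out2)
  # non-disturbed labels are never altered
  lab3 <- lab; lab3[2, 2] <- 2L; lab3[3, 3] <- 1L
  out3 <- morphological_clean(lab3, cfg)
  expect_equal(out3[2, 2], 2L)
})

segment_fixture_pair <- function(vals_early, vals_late, dims) {
  s1 <- uniform_scene(band_vals(), dims = dims, date = "2000-06-01")
  s2 <- uniform_scene(band_vals(), dims = dims, date = "2005-06-01")
  for (b in names(vals_early)) s1$bands[[b]] <- vals_early[[b]]
  for (b in names(vals_late)) s2$bands[[b]] <- vals_late[[b]]
  pair_scenes(s1, s2)
}

test_that("homogeneous imagery yields one segment, a sharp gap yields two", {
  dims <- c(16, 16)
  p <- segment_fixture_pair(list(), list(), dims)
  m <- all_valid_masks(dims)
  seg <- segment_pair(p, m, pipeline_config())
  expect_equal(nrow(seg$segments), 1L)
  expect_true(all(seg$ids == 1L))

  # two homogeneous halves separated by a spectral gap >> merge threshold
  left <- matrix(0.05, dims[1], dims[2]); left[, 9:16] <- 0.45
  p2 <- segment_fixture_pair(list(red = left, nir = left, swir1 = left),
                             list(), dims)
  seg2 <- segment_pair(p2, m, pipeline_config())
  expect_equal(nrow(seg2$segments), 2L)
  expect_equal(length(unique(as.vector(seg2$ids[, 1:8]))), 1L)
  expect_equal(length(unique(as.vector(seg2$ids[, 9:16]))), 1L)
})

test_that("every segment respects the minimum mapping unit", {
  dims <- c(48, 48)
  set.seed(23)
  noise <- function() matrix(runif(prod(dims), 0, 1), dims[1], dims[2])
  p <- segment_fixture_pair(list(red = noise(), nir = noise(),
                                 swir1 = noise()),
                            list(red = noise(), nir = noise(),
                                 swir1 = noise()), dims)
  m <- all_valid_masks(dims)
  cfg <- pipeline_config()
  seg <- segment_pair(p, m, cfg)
  expect_gte(min(seg$segments$n_pixels), cfg$mmu)
  # ids partition the valid region
  expect_equal(sum(seg$ids > 0), sum(m$valid))
  expect_setequal(unique(seg$ids[seg$ids > 0]), seg$segments$segment_id)
  # deterministic
  seg2 <- segment_pair(p, m, cfg)
  expect_identical(seg$ids, seg2$ids)
})

test_that("segmentation covers only the valid region and handles empties", {
  dims <- c(12, 12)
  p <- segment_fixture_pair(list(), list(), dims)
  m <- all_valid_masks(dims)
  m$valid[, 1:6] <- FALSE
  seg <- segment_pair(p, m, pipeline_config())
  expect_true(all(seg$ids[, 1:6] == 0L))
  m0 <- all_valid_masks(dims); m0$valid[] <- FALSE
  seg0 <- segment_pair(p, m0, pipeline_config())
  expect_equal(nrow(seg0$segments), 0L)
  expect_true(all(seg0$ids == 0L))
})

test_that("plurality labelling counts pixels and breaks ties conservatively", {
  ids <- matrix(0L, 4, 6)
  ids[1:2, 1:3] <- 1L   # uniform disturbed
  ids[3:4, 1:3] <- 2L   # 4 disturbed / 2 no-change
  ids[1:2, 4:6] <- 3L   # 3-3 tie
  ids[3:4, 4:6] <- 4L   # uniform no-change
  labels <- matrix(3L, 4, 6)
  labels[ids == 1L] <- 1L
  labels[3, 1:3] <- 1L; labels[4, 1] <- 1L; labels[4, 2:3] <- 3L
  labels[1, 4:6] <- 1L; labels[2, 4:6] <- 3L
  seg <- structure(list(
    ids = ids,
    segments = tibble::tibble(segment_id = 1:4,
                              n_pixels = as.integer(table(ids[ids > 0])))),
    class = "segment_map")
  pl <- plurality_label(seg, labels)
  expect_equal(pl$label[pl$segment_id == 1], "disturbed")
  expect_equal(pl$label[pl$segment_id == 2], "disturbed")  # 4 vs 2
  expect_equal(pl$label[pl$segment_id == 3], "no-change")  # tie
  expect_equal(pl$label[pl$segment_id == 4], "no-change")
  expect_equal(pl$n_disturbed[pl$segment_id == 2], 4L)
  expect_equal(pl$n_nochange[pl$segment_id == 2], 2L)
})

test_that("composition applies the documented precedence and codes", {
  dims <- c(16, 16)
  m <- all_valid_masks(dims)
  m$water1[1:4, 1:4] <- TRUE
  m$cloud2[1:2, 1:8] <- TRUE       # overlaps the water corner
  m$shadow2[5:6, 1:4] <- TRUE
  m$nodata[16, 16] <- TRUE
  m$forest1[9:16, 9:16] <- FALSE   # never-forest quadrant
  m$valid <- !(m$cloud1 | m$cloud2 | m$shadow1 | m$shadow2 |
                 m$water1 | m$water2 | m$nodata) & m$forest1

  ids <- matrix(0L, dims[1], dims[2])
  ids[m$valid] <- 1L
  ids[m$valid & row(ids) <= 8 & col(ids) >= 9] <- 2L
  seg <- structure(list(
    ids = ids,
    segments = tibble::tibble(segment_id = 1:2,
                              n_pixels = c(sum(ids == 1L), sum(ids == 2L)))),
    class = "segment_map")
  seg_labels <- tibble::tibble(segment_id = 1:2, label_code = c(3L, 1L),
                               label = c("no-change", "disturbed"))
  map <- compose_final(seg_labels, seg, m)

  # hand-built expectation raster
  expected <- matrix(3L, dims[1], dims[2])          # stable non-forest
  expected[ids == 1L] <- 2L                         # stable forest
  expected[ids == 2L] <- 1L                         # disturbed
  expected[m$water1] <- 4L
  expected[m$shadow2] <- 6L
  expected[m$cloud2] <- 5L                          # cloud beats water
  expected[m$nodata] <- 0L
  expect_identical(map$codes, expected)
  # partition: every non-nodata pixel carries exactly one code in 1..6
  expect_true(all(map$codes[!m$nodata] %in% 1:6))
  expect_equal(map$codes[1, 1], 5L)  # cloud > water precedence
})
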