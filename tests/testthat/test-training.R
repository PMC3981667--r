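# build a difference image with engineered tails and extract from it
toy_diff <- function(dims = c(64, 64), seed = 2, tail_frac = 0.06,
                     tail_value = -0.2, pos_frac = 0.05, pos_value = 0.2,
                     noise = 0.01) {
  set.seed(seed)
  d <- matrix(rnorm(prod(dims), 0, noise), dims[1], dims[2])
  n <- prod(dims)
  neg <- sample.int(n, round(tail_frac * n))
  d[neg] <- tail_value + rnorm(length(neg), 0, noise)
  pos <- setdiff(sample.int(n, round(pos_frac * n) + length(neg)), neg)
  pos <- pos[seq_len(round(pos_frac * n))]
  d[pos] <- pos_value + rnorm(length(pos), 0, noise)
  d
}

test_that("window labels equal the exhaustive threshold oracle", {
  dims <- c(64, 64)
  d <- toy_diff(dims)
  m <- all_valid_masks(dims)
  f <- index_feature_stack(dims)
  cfg <- pipeline_config(window_size = 64, min_tail_count = 5)
  tr <- extract_training(d, m, f, cfg)

  # brute-force oracle over the single 64x64 window
  mu <- mean(d); sigma <- sd(as.vector(d))
  k <- cfg$threshold_multiplier
  exp_dist <- which(d < mu - k * sigma)
  exp_regr <- which(d > mu + k * sigma)
  got_dist <- sort(as.integer((tr$col[tr$label == "disturbed"] - 1) *
                                dims[1] + tr$row[tr$label == "disturbed"]))
  got_regr <- sort(as.integer((tr$col[tr$label == "regrowth"] - 1) *
                                dims[1] + tr$row[tr$label == "regrowth"]))
  expect_identical(got_dist, sort(exp_dist))
  expect_identical(got_regr, sort(exp_regr))
  # no-change samples all lie inside the band, subsampled to the big tail
  noch <- tr[tr$label == "no-change", ]
  expect_true(all(abs(d[cbind(noch$row, noch$col)] - mu) <
                    cfg$no_change_band * sigma))
  expect_lte(nrow(noch), max(length(exp_dist), length(exp_regr)))
  # features attached from the stack, pixel for pixel
  expect_equal(tr$b1, f$b1[cbind(tr$row, tr$col)])
  expect_equal(tr$dw, f$dw[cbind(tr$row, tr$col)])
})

test_that("thresholds sit exactly k sigma from the window mean", {
  d <- toy_diff(c(64, 64), seed = 9)
  cfg <- pipeline_config(window_size = 32, min_tail_count = 1)
  tr <- extract_training(d, all_valid_masks(c(64, 64)),
                         index_feature_stack(c(64, 64)), cfg)
  w <- training_windows(tr)
  w <- w[w$sigma > 0, ]
  expect_equal((w$mu - w$threshold_low) / w$sigma,
               rep(1.5, nrow(w)), tolerance = 1e-12)
  expect_equal((w$threshold_high - w$mu) / w$sigma,
               rep(1.5, nrow(w)), tolerance = 1e-12)
})

test_that("degenerate and insufficient windows contribute nothing", {
  dims <- c(32, 32)
  m <- all_valid_masks(dims)
  f <- index_feature_stack(dims)
  cfg <- pipeline_config(window_size = 32, min_tail_count = 5)
  # constant difference image: sigma = 0, no tails anywhere
  expect_error(extract_training(matrix(0.1, 32, 32), m, f, cfg),
               "no training extractable")
  # a window whose valid fraction is below the cutoff contributes nothing
  d <- toy_diff(dims, seed = 3)
  m2 <- all_valid_masks(dims)
  m2$valid[] <- FALSE
  m2$valid[1:5, 1:5] <- TRUE  # 2.4% valid
  expect_error(extract_training(d, m2, f, cfg), "no training extractable")
})

test_that("masked pixels never become samples", {
  dims <- c(64, 64)
  d <- toy_diff(dims, seed = 5)
  m <- all_valid_masks(dims)
  set.seed(8)
  m$valid <- matrix(runif(prod(dims)) < 0.7, dims[1], dims[2])
  tr <- extract_training(d, m, index_feature_stack(dims),
                         pipeline_config(window_size = 64,
                                         min_tail_count = 5))
  expect_true(all(m$valid[cbind(tr$row, tr$col)]))
})

test_that("the regrowth tail is optional unless both tails are required", {
  dims <- c(64, 64)
  d <- toy_diff(dims, seed = 4, pos_frac = 0)  # clearing only
  m <- all_valid_masks(dims)
  f <- index_feature_stack(dims)
  tr <- extract_training(d, m, f, pipeline_config(window_size = 64,
                                                  min_tail_count = 5))
  expect_gt(sum(tr$label == "disturbed"), 0)
  expect_equal(sum(tr$label == "regrowth"), 0L)
  expect_error(
    extract_training(d, m, f,
                     pipeline_config(window_size = 64, min_tail_count = 5,
                                     require_both_tails = TRUE)),
    "no training extractable")
})

test_that("clean separable training is left nearly untouched by the filter", {
  tr <- blob_training_set(n = 600, flip_frac = 0, seed = 3)
  fl <- consensus_filter(tr, pipeline_config(rng_seed = 11L))
  expect_lt(fl$report$removal_fraction, 0.02)
})

test_that("scattered label flips are removed, clean samples are kept", {
  tr <- blob_training_set(n = 900, flip_frac = 0.1, seed = 5)
  flipped <- attr(tr, "flipped")
  fl <- consensus_filter(tr, pipeline_config(rng_seed = 12L))
  removed <- fl$report$removed_ids
  expect_gte(mean(flipped %in% removed), 0.8)
  clean <- setdiff(seq_len(nrow(tr)), flipped)
  expect_lte(mean(clean %in% removed), 0.05)
})

test_that("filtering is removal-only, deterministic, and well-reported", {
  tr <- blob_training_set(n = 400, flip_frac = 0.08, seed = 6)
  cfg <- pipeline_config(rng_seed = 31L)
  fl1 <- consensus_filter(tr, cfg)
  fl2 <- consensus_filter(tr, cfg)
  expect_identical(fl1$report$removed_ids, fl2$report$removed_ids)
  expect_equal(nrow(fl1$training) + fl1$report$n_removed, nrow(tr))
  expect_equal(fl1$report$removal_fraction,
               fl1$report$n_removed / fl1$report$n_original)
  # filtered set is a subset of the original rows
  key <- function(t) paste(t$b1, t$g1, t$w1, t$db, t$dg, t$dw, t$label)
  expect_true(all(key(fl1$training) %in% key(tr)))
  # tidy/glance accessors agree with the report
  expect_equal(sum(tidy(fl1$report)$removed), fl1$report$n_removed)
  expect_equal(glance(fl1$report)$removal_fraction,
               fl1$report$removal_fraction)
})

test_that("classes smaller than the fold count are exempt from removal", {
  tr <- blob_training_set(n = 300, flip_frac = 0, seed = 7)
  # shrink one class below n_folds and flip its labels to make it noisy
  keep <- c(which(tr$label != "regrowth"),
            which(tr$label == "regrowth")[1:5])
  tr2 <- tr[sort(keep), ]
  class(tr2) <- class(tr)
  expect_warning(fl <- consensus_filter(tr2, pipeline_config(rng_seed = 2L)),
                 "exempt")
  small_ids <- which(tr2$label == "regrowth")
  expect_false(any(small_ids %in% fl$report$removed_ids))
})

test_that("single-class training sets are rejected", {
  tr <- blob_training_set(n = 100, seed = 8)
  tr1 <- tr[tr$label == "disturbed", ]
  class(tr1) <- class(tr)
  expect_error(consensus_filter(tr1, pipeline_config()), "two classes")
})

test_that("training sets serialize to CSV and reports to JSON", {
  tr <- blob_training_set(n = 120, seed = 9)
  fl <- consensus_filter(tr, pipeline_config(rng_seed = 3L))
  dir <- withr::local_tempdir()
  write_training_set(tr, file.path(dir, "t.csv"))
  back <- utils::read.csv(file.path(dir, "t.csv"))
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$b1, tr$b1)
  write_filter_report(fl$report, file.path(dir, "r.json"))
  rep <- jsonlite::fromJSON(file.path(dir, "r.json"))
  expect_equal(rep$n_original, nrow(tr))
})
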