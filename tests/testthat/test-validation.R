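toy_map_with_polygons <- function(n_disturbed, n_stable) {
  # build a change map whose polygons are isolated 2x2 blocks
  per_row <- 20
  need <- n_disturbed + n_stable
  rows <- ceiling(need / per_row)
  codes <- matrix(3L, rows * 3 + 1, per_row * 3 + 1)
  k <- 0
  for (i in seq_len(need)) {
    r <- ((i - 1) %/% per_row) * 3 + 1
    c <- ((i - 1) %% per_row) * 3 + 1
    codes[r:(r + 1), c:(c + 1)] <- if (i <= n_disturbed) 1L else 2L
    k <- k + 1
  }
  new_change_map(codes)
}

test_that("stratified sampling draws the configured number per stratum", {
  map <- toy_map_with_polygons(150, 250)
  cfg <- pipeline_config(rng_seed = 3L)
  s <- stratified_sample(map, cfg)
  expect_equal(sum(s$stratum == "disturbed"), 100L)
  expect_equal(sum(s$stratum == "stable_forest"), 100L)
  expect_false(any(duplicated(s$polygon_id)))  # without replacement
  # determinism
  s2 <- stratified_sample(map, cfg)
  expect_identical(s$polygon_id, s2$polygon_id)
})

test_that("small strata are exhausted with a warning", {
  map <- toy_map_with_polygons(40, 120)
  expect_warning(s <- stratified_sample(map, pipeline_config(rng_seed = 1L)),
                 "only 40")
  expect_equal(sum(s$stratum == "disturbed"), 40L)
})

test_that("an empty stratum warns and contributes nothing", {
  map <- toy_map_with_polygons(0, 30)
  expect_warning(
    expect_warning(
      s <- stratified_sample(map, pipeline_config(rng_seed = 1L)),
      "empty stratum"),
    "only 30")  # the other stratum is exhausted as well
  expect_false(any(s$stratum == "disturbed"))
  expect_equal(sum(s$stratum == "stable_forest"), 30L)
})

test_that("the hand-computed confusion arithmetic is reproduced", {
  # 100 polygons: rows = map (disturbed, stable), confusion [[45,5],[10,40]]
  sample <- tibble::tibble(
    polygon_id = 1:100,
    class = rep(c("disturbed", "stable_forest"), c(50, 50)),
    n_pixels = 4L,
    pixels = replicate(100, cbind(1L, 1L), simplify = FALSE))
  reference <- c(rep("disturbed", 45), rep("stable_forest", 5),
                 rep("disturbed", 10), rep("stable_forest", 40))
  rep <- assess(sample, reference)
  expect_equal(rep$overall, 0.85)
  expect_equal(rep$users[["disturbed"]], 45 / 50)
  expect_equal(rep$producers[["disturbed"]], 45 / 55)
  expect_equal(rep$users[["stable_forest"]], 40 / 50)
  expect_equal(rep$tpr, 45 / 55)
  expect_equal(rep$fpr, 5 / 45)
})

test_that("report metrics equal an independent recomputation", {
  set.seed(33)
  sample <- tibble::tibble(
    polygon_id = 1:80,
    class = sample(c("disturbed", "stable_forest"), 80, replace = TRUE),
    n_pixels = 4L,
    pixels = replicate(80, cbind(1L, 1L), simplify = FALSE))
  reference <- sample(c("disturbed", "stable_forest"), 80, replace = TRUE)
  rep <- assess(sample, reference)
  cm <- rep$confusion
  expect_equal(rep$overall, sum(diag(cm)) / sum(cm))
  expect_equal(as.numeric(rep$users), unname(diag(cm) / rowSums(cm)))
  expect_equal(as.numeric(rep$producers), unname(diag(cm) / colSums(cm)))
  expect_equal(rep$tpr, cm[1, 1] / sum(cm[, 1]))
  expect_equal(rep$fpr, cm[1, 2] / sum(cm[, 2]))
  expect_true(all(unlist(rep[c("overall", "tpr", "fpr")]) >= 0))
  expect_true(all(unlist(rep[c("overall", "tpr", "fpr")]) <= 1))
  # tidy/glance agree with the stored matrix
  expect_equal(tidy(rep)$n_map, rowSums(cm))
  expect_equal(glance(rep)$overall, rep$overall)
})

test_that("a perfect map scores perfectly", {
  sample <- tibble::tibble(
    polygon_id = 1:60,
    class = rep(c("disturbed", "stable_forest"), 30),
    n_pixels = 4L,
    pixels = replicate(60, cbind(1L, 1L), simplify = FALSE))
  rep <- assess(sample, sample$class)
  expect_equal(rep$overall, 1)
  expect_equal(rep$tpr, 1)
  expect_equal(rep$fpr, 0)
})

test_that("vocabulary mismatches are rejected", {
  sample <- tibble::tibble(
    polygon_id = 1:2, class = c("disturbed", "stable_forest"),
    n_pixels = 4L, pixels = replicate(2, cbind(1L, 1L), simplify = FALSE))
  expect_error(assess(sample, c("disturbed", "wetland")), "vocabulary")
  expect_error(assess(sample, "disturbed"), "one reference label")
})

test_that("reference labels derive from truth-pixel pluralities", {
  truth <- structure(list(change = matrix("none", 6, 6)),
                     class = "truth_maps")
  truth$change[1:3, 1:3] <- "disturbed"
  sample <- tibble::tibble(
    polygon_id = 1:2, class = c("disturbed", "stable_forest"),
    n_pixels = c(9L, 4L),
    pixels = list(as.matrix(expand.grid(1:3, 1:3)),
                  as.matrix(expand.grid(5:6, 5:6))))
  expect_equal(reference_labels(sample, truth),
               c("disturbed", "stable_forest"))
})
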