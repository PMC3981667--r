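# Shared fixtures, built in code. Heavy objects are memoised so several
# test files can reuse one computation.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = fixture_cache))
    assign(key, build(), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

# a scene with spatially constant bands (plus optional thermal)
uniform_scene <- function(vals, dims = c(8, 8), date = "2000-07-01",
                          thermal = NULL, ...) {
  bands <- lapply(vals, function(v) matrix(v, dims[1], dims[2]))
  th <- if (!is.null(thermal)) matrix(thermal, dims[1], dims[2])
  new_scene(bands, date = date, thermal = th, ...)
}

band_vals <- function(blue = 0.05, green = 0.06, red = 0.04, nir = 0.3,
                      swir1 = 0.1, swir2 = 0.05) {
  list(blue = blue, green = green, red = red, nir = nir,
       swir1 = swir1, swir2 = swir2)
}

# a fully-valid mask set over a given grid (list contract of combine_masks)
all_valid_masks <- function(dims) {
  f <- matrix(FALSE, dims[1], dims[2])
  t_ <- matrix(TRUE, dims[1], dims[2])
  structure(list(cloud1 = f, shadow1 = f, cloud2 = f, shadow2 = f,
                 water1 = f, water2 = f, forest1 = t_, forest2 = t_,
                 nodata = f, valid = t_),
            class = "mask_set")
}

# a feature stack whose planes are simple deterministic functions of the
# pixel index, adequate wherever tests need features attached to samples
index_feature_stack <- function(dims) {
  n <- prod(dims)
  base <- matrix(seq_len(n) / n, dims[1], dims[2])
  structure(list(b1 = base, g1 = base * 2, w1 = base - 0.5,
                 db = -base, dg = base / 2, dw = 0.1 - base),
            class = "feature_stack")
}

# three separable Gaussian blobs in feature space with optional label flips
blob_training_set <- function(n = 600, flip_frac = 0, sd = 0.35, seed = 1) {
  set.seed(seed)
  centers <- list("disturbed" = c(2, 0, 0, 1, -1, 0),
                  "regrowth" = c(-2, 1, 0, -1, 1, 0),
                  "no-change" = c(0, -2, 1, 0, 0, 1))
  lab <- sample(names(centers), n, replace = TRUE)
  X <- t(vapply(lab, function(l) centers[[l]] + stats::rnorm(6, 0, sd),
                numeric(6)))
  colnames(X) <- c("b1", "g1", "w1", "db", "dg", "dw")
  flipped <- integer(0)
  noisy <- lab
  if (flip_frac > 0) {
    flipped <- sample.int(n, round(flip_frac * n))
    for (i in flipped)
      noisy[i] <- sample(setdiff(names(centers), lab[i]), 1)
  }
  t <- tibble::tibble(row = 1L, col = 1L, tibble::as_tibble(X),
                      label = factor(noisy,
                                     levels = c("disturbed", "regrowth",
                                                "no-change")),
                      window_id = 1L)
  attr(t, "true_label") <- lab
  attr(t, "flipped") <- flipped
  class(t) <- c("training_set", class(t))
  t
}

# small, fast pipeline configuration for unit tests
fast_cfg <- function(...) {
  pipeline_config(window_size = 96,
                  svm_c_exponents = c(-1, 3, 7),
                  svm_gamma_exponents = c(-7, -3, 1),
                  max_samples_per_class = 300,
                  grid_subsample = 300,
                  min_tail_count = 10,
                  ...)
}

# one shared small synthetic scene + pipeline run for pipeline-level tests
small_run <- function() {
  memo("small_run", function() {
    sp <- scene_spec(width = 96, height = 96, seed = 21)
    g <- generate_scene_pair(sp)
    cfg <- fast_cfg(rng_seed = 21L)
    res <- run_pipeline(g$pair, cfg)
    list(gen = g, cfg = cfg, res = res)
  })
}

# the default-condition 512 x 512 end-to-end run used by the acceptance
# tests (default configuration, default generator)
default_run <- function() {
  memo("default_run", function() {
    sp <- scene_spec(width = 512, height = 512, seed = 1)
    g <- generate_scene_pair(sp)
    cfg <- pipeline_config(rng_seed = 1L)
    res <- run_pipeline(g$pair, cfg)
    report <- run_validation(res$change_map, g$truth, cfg)
    list(gen = g, cfg = cfg, res = res, report = report)
  })
}
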