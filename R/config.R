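#' Pipeline configuration
#'
#' Central container for every tunable constant used anywhere in the
#' disturbance-mapping pipeline. All stages take a `pipeline_config` (or use
#' [pipeline_config()] defaults), so there are no hidden numeric literals:
#' changing a field here changes the behaviour of the corresponding stage.
#'
#' @param threshold_multiplier Number of standard deviations away from the
#'   local-window mean of the SWIR difference image beyond which a pixel is
#'   labelled disturbed (negative tail) or regrowth (positive tail).
#'   Unitless; default 1.5. Fixed across all windows and scenes.
#' @param window_size Side length, in pixels, of the square local windows
#'   used for training-data extraction and forest-peak detection.
#'   Default 400 (a 12 km Landsat window).
#' @param window_stride Step between window origins in pixels. `NULL` (the
#'   default) means `window_size`, i.e. non-overlapping tiling.
#' @param no_change_band Half-width, in sigma-multiples, of the band around
#'   the window mean from which no-change training pixels are drawn.
#'   Default 0.5.
#' @param min_tail_count Minimum number of disturbed-tail pixels a window
#'   must contain to contribute training samples. Default 25.
#' @param window_min_valid_frac Minimum fraction of a window's pixels that
#'   must be valid (unmasked) for the window to contribute samples.
#'   Default 0.25.
#' @param require_both_tails If `TRUE`, a window must also contain at least
#'   `min_tail_count` regrowth-tail pixels to contribute any samples; by
#'   default only the disturbed tail is required and the regrowth tail is
#'   used opportunistically (see the methods vignette).
#' @param water_swir_max SWIR-1 reflectance (fraction) below which a pixel
#'   can be water. Default 0.25.
#' @param water_ndvi_max NDVI below which a low-SWIR pixel is water even
#'   without a decreasing visible-to-infrared trend. Default 0.3.
#' @param forest_red_max Maximum red reflectance at which a local histogram
#'   mode still qualifies as the forest dark peak. Default 0.10.
#' @param forest_bin_width Red-band histogram bin width (reflectance
#'   fraction) for forest-peak detection. Default 0.005.
#' @param forest_smooth_bins Moving-average length (bins) applied to the
#'   histogram before peak finding. Default 3.
#' @param forest_peak_prominence Minimum smoothed bin count, as a fraction
#'   of the window's valid pixels, for a mode to count as prominent.
#'   Default 0.05.
#' @param cloud_blue_min,cloud_swir_min Brightness test: a cloud candidate
#'   must exceed both thresholds (blue and SWIR-1 reflectance).
#'   Defaults 0.20 and 0.10.
#' @param cloud_whiteness_max Whiteness test: mean absolute deviation of
#'   the visible bands from their mean, divided by that mean, must be below
#'   this value. Default 0.7.
#' @param cloud_bt_margin Coldness test: brightness temperature must be at
#'   least this many Kelvin below the scene median. Default 4.
#' @param shadow_nir_max NIR reflectance below which a pixel is dark enough
#'   to be candidate cloud shadow. Default 0.10.
#' @param cloud_height_min,cloud_height_max,cloud_height_step Sweep of
#'   candidate cloud-base heights (metres) used when projecting shadows
#'   along the anti-solar azimuth. Defaults 200, 3000, 200.
#' @param mmu Minimum mapping unit in pixels: no final-map segment is
#'   smaller. Default 6 (roughly 0.5 ha at 30 m).
#' @param n_folds Number of cross-validation folds in the consensus label
#'   filter. Default 10.
#' @param filter_train_frac Fraction of the training folds each filter
#'   classifier is fitted on (stratified, without replacement).
#'   Default 0.70.
#' @param filter_enabled Run the consensus filter at all. Default `TRUE`.
#' @param filter_rule `"consensus"` (default: remove a sample only when all
#'   classifiers misclassify it) or `"majority"`.
#' @param svm_c_exponents,svm_gamma_exponents Grid-search exponents: the
#'   candidate cost and kernel-width values are `2^exponents`.
#'   Defaults `seq(-5, 15, 2)` and `seq(-15, 3, 2)`.
#' @param svm_cv_folds Folds for grid-search cross-validation. Default 5.
#' @param morph_radius Radius (pixels) of the square structuring element
#'   used to open the disturbed layer; 1 means 3x3. Default 1.
#' @param merge_threshold Maximum Euclidean distance between segment mean
#'   vectors (reflectance units on the six-band stack) at which the
#'   region-merging segmenter still merges. Default 0.05.
#' @param n_samples_per_stratum Accuracy-assessment polygons drawn per
#'   stratum. Default 100.
#' @param max_samples_per_class Computational cap on extracted training
#'   samples per class (stratified, seeded subsample after extraction);
#'   `Inf` disables. Default 2000.
#' @param grid_subsample Cap on the number of samples used inside the
#'   hyperparameter grid search only. Default 1500.
#' @param knn_k,tree_maxdepth,nnet_size Fixed hyperparameters of the three
#'   auxiliary filter classifiers (nearest neighbours, depth-limited tree,
#'   single-hidden-layer network). Defaults 5, 8, 16.
#' @param sensor Tasseled-cap coefficient set to use: `"TM"`, `"ETM+"`, or
#'   `"synthetic"`. Default `"TM"`.
#' @param diff_band Band used for the difference image, `"swir1"` (default)
#'   or `"swir2"`.
#' @param rng_seed Single integer seed governing every stochastic stage
#'   (sampling, folds, subsampling) for end-to-end determinism. Default 42.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @seealso [load_config()], [save_config()]
#' @export
#' @examples
#' cfg <- pipeline_config(mmu = 8)
#' cfg$mmu
pipeline_config <- function(threshold_multiplier = 1.5,
                            window_size = 400,
                            window_stride = NULL,
                            no_change_band = 0.5,
                            min_tail_count = 25,
                            window_min_valid_frac = 0.25,
                            require_both_tails = FALSE,
                            water_swir_max = 0.25,
                            water_ndvi_max = 0.3,
                            forest_red_max = 0.10,
                            forest_bin_width = 0.005,
                            forest_smooth_bins = 3,
                            forest_peak_prominence = 0.05,
                            cloud_blue_min = 0.20,
                            cloud_swir_min = 0.10,
                            cloud_whiteness_max = 0.7,
                            cloud_bt_margin = 4,
                            shadow_nir_max = 0.10,
                            cloud_height_min = 200,
                            cloud_height_max = 3000,
                            cloud_height_step = 200,
                            mmu = 6,
                            n_folds = 10,
                            filter_train_frac = 0.70,
                            filter_enabled = TRUE,
                            filter_rule = c("consensus", "majority"),
                            svm_c_exponents = seq(-5, 15, 2),
                            svm_gamma_exponents = seq(-15, 3, 2),
                            svm_cv_folds = 5,
                            morph_radius = 1,
                            merge_threshold = 0.05,
                            n_samples_per_stratum = 100,
                            max_samples_per_class = 2000,
                            grid_subsample = 1500,
                            knn_k = 5,
                            tree_maxdepth = 8,
                            nnet_size = 16,
                            sensor = c("TM", "ETM+", "synthetic"),
                            diff_band = c("swir1", "swir2"),
                            rng_seed = 42L) {
  cfg <- list(
    threshold_multiplier = threshold_multiplier,
    window_size = as.integer(window_size),
    window_stride = if (is.null(window_stride)) as.integer(window_size)
                    else as.integer(window_stride),
    no_change_band = no_change_band,
    min_tail_count = as.integer(min_tail_count),
    window_min_valid_frac = window_min_valid_frac,
    require_both_tails = isTRUE(require_both_tails),
    water_swir_max = water_swir_max,
    water_ndvi_max = water_ndvi_max,
    forest_red_max = forest_red_max,
    forest_bin_width = forest_bin_width,
    forest_smooth_bins = as.integer(forest_smooth_bins),
    forest_peak_prominence = forest_peak_prominence,
    cloud_blue_min = cloud_blue_min,
    cloud_swir_min = cloud_swir_min,
    cloud_whiteness_max = cloud_whiteness_max,
    cloud_bt_margin = cloud_bt_margin,
    shadow_nir_max = shadow_nir_max,
    cloud_height_min = cloud_height_min,
    cloud_height_max = cloud_height_max,
    cloud_height_step = cloud_height_step,
    mmu = as.integer(mmu),
    n_folds = as.integer(n_folds),
    filter_train_frac = filter_train_frac,
    filter_enabled = isTRUE(filter_enabled),
    filter_rule = match.arg(filter_rule),
    svm_c_exponents = as.numeric(svm_c_exponents),
    svm_gamma_exponents = as.numeric(svm_gamma_exponents),
    svm_cv_folds = as.integer(svm_cv_folds),
    morph_radius = as.integer(morph_radius),
    merge_threshold = merge_threshold,
    n_samples_per_stratum = as.integer(n_samples_per_stratum),
    max_samples_per_class = max_samples_per_class,
    grid_subsample = grid_subsample,
    knn_k = as.integer(knn_k),
    tree_maxdepth = as.integer(tree_maxdepth),
    nnet_size = as.integer(nnet_size),
    sensor = match.arg(sensor),
    diff_band = match.arg(diff_band),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stop_cfg <- function(msg) stop("configuration error: ", msg, call. = FALSE)
  if (!is.numeric(cfg$threshold_multiplier) || cfg$threshold_multiplier <= 0)
    stop_cfg("threshold_multiplier must be > 0")
  if (cfg$window_size < 16) stop_cfg("window_size must be >= 16")
  if (cfg$window_stride < 1) stop_cfg("window_stride must be >= 1")
  if (cfg$filter_train_frac <= 0 || cfg$filter_train_frac >= 1)
    stop_cfg("filter_train_frac must lie strictly between 0 and 1")
  if (cfg$mmu < 1) stop_cfg("mmu must be >= 1")
  if (cfg$n_folds < 2) stop_cfg("n_folds must be >= 2")
  if (cfg$no_change_band <= 0) stop_cfg("no_change_band must be > 0")
  if (cfg$window_min_valid_frac < 0 || cfg$window_min_valid_frac > 1)
    stop_cfg("window_min_valid_frac must lie in [0, 1]")
  if (cfg$merge_threshold <= 0) stop_cfg("merge_threshold must be > 0")
  if (cfg$morph_radius < 0) stop_cfg("morph_radius must be >= 0")
  if (!length(cfg$svm_c_exponents) || !length(cfg$svm_gamma_exponents))
    stop_cfg("svm grid exponent ranges must be non-empty")
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Unspecified fields take the documented [pipeline_config()] defaults.
#' An empty file therefore yields the all-defaults configuration.
#'
#' @param path Path to a YAML file whose top-level keys name
#'   `pipeline_config` fields.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("configuration error: cannot parse ",
                                           path, ": ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("configuration error: top level of ", path, " is not a mapping",
         call. = FALSE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("configuration error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Save a pipeline configuration to YAML
#'
#' `save_config()` followed by [load_config()] reproduces the configuration
#' field for field.
#'
#' @param cfg A `pipeline_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- unclass(cfg)
  # yaml scalars round-trip; keep vector fields as sequences
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}
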