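#' Run the full disturbance-mapping pipeline on a scene pair
#'
#' Executes mask -> features -> training extraction -> consensus filter
#' -> grid search -> SVM training -> per-pixel prediction ->
#' morphological cleaning -> segmentation -> plurality labelling ->
#' six-category composition, and assembles a run manifest (config
#' snapshot, seed, per-stage timings and record counts). Fully
#' deterministic given the configuration's `rng_seed`.
#'
#' @param pair A `scene_pair` (e.g. from [generate_scene_pair()] or
#'   [read_scene()] + [pair_scenes()]).
#' @param cfg A [pipeline_config()].
#' @param output_dir Optional directory; when given, the change map
#'   (TIFF + GeoJSON), the training CSV, the filter report and the
#'   manifest JSON are written there.
#' @param verbose Print per-stage progress.
#' @return List with `change_map`, `manifest` (class `run_manifest`),
#'   and intermediates: `masks`, `features`, `diff`, `training_raw`,
#'   `training`, `filter_report`, `params`, `model`, `labels`,
#'   `segments`, `segment_labels`.
#' @export
run_pipeline <- function(pair, cfg = pipeline_config(), output_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(pair, "scene_pair"))
  timings <- c(); counts <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  masks <- stage("mask", combine_masks(pair, cfg))
  counts$valid_pixels <- sum(masks$valid)
  say("mask: %d valid pixels (%.1f%%)", counts$valid_pixels,
      100 * mean(masks$valid))

  coef <- kt_coefficients(cfg$sensor)
  feats <- stage("features", mkt_stack(pair, coef))
  diff <- stage("difference", swir_difference(pair, cfg))

  training_raw <- stage("extract", extract_training(diff, masks, feats, cfg))
  counts$samples_extracted <- nrow(training_raw)
  say("extract: %d samples", counts$samples_extracted)

  if (cfg$filter_enabled) {
    flt <- stage("filter", consensus_filter(training_raw, cfg))
    training <- flt$training
    filter_report <- flt$report
  } else {
    training <- training_raw
    filter_report <- NULL
  }
  counts$samples_removed <- if (is.null(filter_report)) 0L
                            else filter_report$n_removed
  say("filter: removed %d samples", counts$samples_removed)

  params <- stage("grid_search", svm_grid_search(training, cfg))
  say("grid search: C = %g, gamma = %g (CV acc %.3f)",
      params$C, params$gamma, params$cv_accuracy)
  model <- stage("train", train_classifier(training, params, cfg))
  labels <- stage("predict", predict_map(model, feats, masks))
  labels <- stage("clean", morphological_clean(labels, cfg))

  segs <- stage("segment", segment_pair(pair, masks, cfg))
  counts$segments <- nrow(segs$segments)
  say("segment: %d segments", counts$segments)
  seg_labels <- stage("plurality", plurality_label(segs, labels))
  map <- stage("compose", compose_final(seg_labels, segs, masks,
                                        grid = pair$early$grid))

  manifest <- structure(list(
    config = unclass(cfg),
    seed = cfg$rng_seed,
    dates = c(early = format(pair$early$date), late = format(pair$late$date)),
    dims = dim(pair$early$bands$red),
    timings = timings,
    counts = counts,
    filter = if (is.null(filter_report)) NULL else
      list(n_removed = filter_report$n_removed,
           removal_fraction = filter_report$removal_fraction),
    svm = list(C = params$C, gamma = params$gamma,
               cv_accuracy = params$cv_accuracy),
    outputs = NULL
  ), class = "run_manifest")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      raster = file.path(output_dir, "change_map.tif"),
      vector = file.path(output_dir, "change_map.geojson"),
      training = file.path(output_dir, "training.csv"),
      manifest = file.path(output_dir, "manifest.json"))
    write_change_map(map, paths$raster, paths$vector)
    write_training_set(training, paths$training)
    if (!is.null(filter_report))
      write_filter_report(filter_report,
                          file.path(output_dir, "filter_report.json"))
    manifest$outputs <- paths
    writeLines(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                                digits = NA, null = "null", force = TRUE),
               paths$manifest)
  }

  list(change_map = map, manifest = manifest, masks = masks,
       features = feats, diff = diff, training_raw = training_raw,
       training = training, filter_report = filter_report,
       params = params, model = model, labels = labels,
       segments = segs, segment_labels = seg_labels)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest %s -> %s, %d x %d px, seed %d>\n",
              x$dates[["early"]], x$dates[["late"]], x$dims[1], x$dims[2],
              x$seed))
  cat("timings (s):\n"); print(round(unlist(x$timings), 2))
  cat("counts:\n"); print(unlist(x$counts))
  invisible(x)
}

#' Validate a change map against reference truth
#'
#' Draws the stratified polygon sample from the map and assesses it
#' against per-pixel truth (or precomputed reference labels).
#'
#' @param map A `change_map`.
#' @param truth A `truth_maps` object or a character vector of reference
#'   labels aligned with the sample.
#' @param cfg A [pipeline_config()].
#' @return An `accuracy_report` with the sampled polygons attached as
#'   attribute `"sample"`.
#' @export
run_validation <- function(map, truth, cfg = pipeline_config()) {
  if (is.null(truth)) stop("reference truth is required", call. = FALSE)
  if (inherits(truth, "truth_maps") &&
      !identical(dim(truth$change), dim(map$codes)))
    stop("registration error: truth grid does not match the map")
  sample <- stratified_sample(map, cfg)
  if (!nrow(sample)) {
    warning("no polygons sampled; degenerate report")
    rep <- structure(list(
      confusion = matrix(0L, 2, 2, dimnames = list(map = ASSESS_STRATA,
                                                   reference = ASSESS_STRATA)),
      overall = NA_real_,
      users = c(disturbed = NA_real_, stable_forest = NA_real_),
      producers = c(disturbed = NA_real_, stable_forest = NA_real_),
      tpr = NA_real_, fpr = NA_real_, n = 0L), class = "accuracy_report")
    attr(rep, "sample") <- sample
    return(rep)
  }
  rep <- assess(sample, truth)
  attr(rep, "sample") <- sample
  rep
}
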