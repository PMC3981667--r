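ASSESS_STRATA <- c("disturbed", "stable_forest")

#' Stratified random sample of assessment polygons
#'
#' Draws up to `cfg$n_samples_per_stratum` polygons uniformly without
#' replacement from each of the two assessed strata of the final map,
#' forest disturbance and stable forest. Deterministic given
#' `cfg$rng_seed`. A stratum with fewer polygons than requested is
#' exhausted with a warning; an empty stratum contributes none.
#'
#' @param m A `change_map`.
#' @param cfg A [pipeline_config()].
#' @return Tibble of sampled polygons (columns of `m$polygons` plus
#'   `stratum`), ordered by stratum then polygon id.
#' @export
stratified_sample <- function(m, cfg = pipeline_config()) {
  stopifnot(inherits(m, "change_map"))
  with_local_seed(cfg$rng_seed + 4L, {
    out <- list()
    for (st in ASSESS_STRATA) {
      pool <- m$polygons[m$polygons$class == st, , drop = FALSE]
      n <- nrow(pool)
      if (n == 0) {
        warning("empty stratum: ", st)
        next
      }
      if (n < cfg$n_samples_per_stratum)
        warning(sprintf("stratum '%s' has only %d polygons (requested %d)",
                        st, n, cfg$n_samples_per_stratum))
      take <- min(n, cfg$n_samples_per_stratum)
      sel <- sort(sample.int(n, take))
      smp <- pool[sel, , drop = FALSE]
      smp$stratum <- st
      out[[st]] <- smp
    }
    dplyr::bind_rows(out)
  })
}

#' Reference labels for sampled polygons from synthetic truth
#'
#' The reference label of a polygon is the plurality of true change
#' labels over its pixels: `disturbed` if true disturbance covers a
#' plurality, otherwise `stable_forest`.
#'
#' @param sample Tibble from [stratified_sample()].
#' @param truth A `truth_maps` object from [generate_scene_pair()].
#' @return Character vector of reference labels aligned with `sample`.
#' @export
reference_labels <- function(sample, truth) {
  stopifnot(inherits(truth, "truth_maps"))
  vapply(sample$pixels, function(pix) {
    ch <- truth$change[pix]
    if (sum(ch == "disturbed") > length(ch) / 2) "disturbed"
    else "stable_forest"
  }, character(1))
}

#' Accuracy assessment of sampled polygons
#'
#' Builds the map-by-reference confusion matrix over the sampled
#' polygons (each polygon one unit) and derives overall accuracy,
#' per-class user's and producer's accuracy, and the true/false positive
#' rates of the disturbance class.
#'
#' @param sample Tibble from [stratified_sample()].
#' @param reference Either a `truth_maps` object (reference labels are
#'   derived with [reference_labels()]) or a character vector of labels
#'   drawn from `disturbed` / `stable_forest`, aligned with `sample`.
#' @return Object of class `accuracy_report`: `confusion` (matrix, rows
#'   = map class, cols = reference class), `overall`, `users`,
#'   `producers` (named vectors), `tpr`, `fpr`, `n`.
#' @export
assess <- function(sample, reference) {
  if (inherits(reference, "truth_maps"))
    reference <- reference_labels(sample, reference)
  if (length(reference) != nrow(sample))
    stop("one reference label per sampled polygon is required")
  if (!all(reference %in% ASSESS_STRATA))
    stop("label vocabulary mismatch: reference labels must be among: ",
         paste(ASSESS_STRATA, collapse = ", "))
  map_lab <- factor(sample$class, levels = ASSESS_STRATA)
  ref_lab <- factor(reference, levels = ASSESS_STRATA)
  cm <- table(map = map_lab, reference = ref_lab)
  cm <- matrix(as.integer(cm), 2, 2,
               dimnames = list(map = ASSESS_STRATA,
                               reference = ASSESS_STRATA))
  total <- sum(cm)
  overall <- if (total) sum(diag(cm)) / total else NA_real_
  users <- diag(cm) / rowSums(cm)
  producers <- diag(cm) / colSums(cm)
  # positives = disturbance
  tp <- cm["disturbed", "disturbed"]
  fn <- cm["stable_forest", "disturbed"]
  fp <- cm["disturbed", "stable_forest"]
  tn <- cm["stable_forest", "stable_forest"]
  structure(list(confusion = cm, overall = overall,
                 users = users, producers = producers,
                 tpr = tp / (tp + fn), fpr = fp / (fp + tn),
                 n = total),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  print(x$confusion)
  cat(sprintf("overall %.3f | TPR %.3f FPR %.3f | n = %d\n",
              x$overall, x$tpr, x$fpr, x$n))
  cat(sprintf("user's:     disturbed %.3f  stable_forest %.3f\n",
              x$users[["disturbed"]], x$users[["stable_forest"]]))
  cat(sprintf("producer's: disturbed %.3f  stable_forest %.3f\n",
              x$producers[["disturbed"]], x$producers[["stable_forest"]]))
  invisible(x)
}

#' @describeIn assess Per-class accuracy table.
#' @param x An `accuracy_report`.
#' @param ... Unused.
#' @export
tidy.accuracy_report <- function(x, ...) {
  tibble(class = ASSESS_STRATA,
         n_map = rowSums(x$confusion),
         n_reference = colSums(x$confusion),
         users_accuracy = as.numeric(x$users),
         producers_accuracy = as.numeric(x$producers))
}

#' @describeIn assess One-row report summary.
#' @export
glance.accuracy_report <- function(x, ...) {
  tibble(overall = x$overall, tpr = x$tpr, fpr = x$fpr, n = x$n)
}

#' Write an accuracy report to JSON
#'
#' @param report An `accuracy_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_report <- function(report, path) {
  out <- list(confusion = unclass(report$confusion),
              overall = report$overall,
              users = as.list(report$users),
              producers = as.list(report$producers),
              tpr = report$tpr, fpr = report$fpr, n = report$n)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
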