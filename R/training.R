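LABEL_LEVELS <- c("disturbed", "regrowth", "no-change")

#' Extract labelled training samples by local-window thresholding
#'
#' The SWIR difference image is tiled into square local windows
#' (`cfg$window_size`, step `cfg$window_stride`). In each window the mean
#' `mu` and standard deviation `sigma` of the valid difference values are
#' computed; pixels below `mu - k * sigma` are labelled `disturbed`,
#' pixels above `mu + k * sigma` are labelled `regrowth`
#' (`k = cfg$threshold_multiplier`, fixed across all windows and scenes),
#' and pixels within `cfg$no_change_band * sigma` of `mu` are candidate
#' `no-change` samples, randomly subsampled to at most the size of the
#' larger tail. A window contributes samples only when at least
#' `cfg$window_min_valid_frac` of its pixels are valid and its disturbed
#' tail holds at least `cfg$min_tail_count` pixels (the regrowth tail is
#' used when it also reaches `cfg$min_tail_count`; set
#' `cfg$require_both_tails = TRUE` to demand both). Labels are attached
#' to the six multi-temporal tasseled-cap features.
#'
#' @param d SWIR difference matrix from [swir_difference()].
#' @param m A `mask_set` from [combine_masks()].
#' @param f A `feature_stack` from [mkt_stack()].
#' @param cfg A [pipeline_config()].
#' @return A `training_set`: a tibble with columns `row`, `col`, the six
#'   features `b1 ... dw`, `label` (factor) and `window_id`, plus a
#'   `windows` attribute (tibble of per-window statistics and pass/fail).
#' @export
extract_training <- function(d, m, f, cfg = pipeline_config()) {
  stopifnot(inherits(m, "mask_set"), inherits(f, "feature_stack"))
  d <- as.matrix(d)
  if (!identical(dim(d), dim(m$valid)))
    stop("registration error: difference image is not on the mask grid")
  nr <- nrow(d); nc <- ncol(d)
  k <- cfg$threshold_multiplier
  with_local_seed(cfg$rng_seed, {
    win_rows <- list(); samp_rows <- list(); wid <- 0L
    for (r0 in seq(1, nr, by = cfg$window_stride)) {
      for (c0 in seq(1, nc, by = cfg$window_stride)) {
        wid <- wid + 1L
        rs <- r0:min(nr, r0 + cfg$window_size - 1)
        cs <- c0:min(nc, c0 + cfg$window_size - 1)
        vm <- m$valid[rs, cs, drop = FALSE]
        dv <- d[rs, cs, drop = FALSE]
        n_all <- length(vm); n_valid <- sum(vm)
        valid_frac <- n_valid / n_all
        mu <- if (n_valid) mean(dv[vm]) else NA_real_
        sigma <- if (n_valid > 1) stats::sd(dv[vm]) else 0
        dist_sel <- vm & dv < mu - k * sigma & sigma > 0
        regr_sel <- vm & dv > mu + k * sigma & sigma > 0
        noch_sel <- vm & abs(dv - mu) < cfg$no_change_band * sigma
        n_dist <- sum(dist_sel); n_regr <- sum(regr_sel)
        pass <- valid_frac >= cfg$window_min_valid_frac &&
          n_dist >= cfg$min_tail_count &&
          (!cfg$require_both_tails || n_regr >= cfg$min_tail_count)
        use_regr <- pass && n_regr >= cfg$min_tail_count
        win_rows[[wid]] <- tibble(
          window_id = wid, row0 = r0, col0 = c0,
          n_valid = n_valid, valid_frac = valid_frac,
          mu = mu, sigma = sigma,
          threshold_low = mu - k * sigma,
          threshold_high = mu + k * sigma,
          n_disturbed = n_dist, n_regrowth = n_regr,
          passed = pass)
        if (!pass) next
        take <- function(sel, label) {
          ix <- which(sel, arr.ind = TRUE)
          if (!nrow(ix)) return(NULL)
          tibble(row = rs[ix[, 1]], col = cs[ix[, 2]], label = label,
                 window_id = wid)
        }
        tail_sz <- max(n_dist, if (use_regr) n_regr else 0L)
        noch <- which(noch_sel, arr.ind = TRUE)
        if (nrow(noch) > tail_sz)
          noch <- noch[sample.int(nrow(noch), tail_sz), , drop = FALSE]
        samp_rows[[length(samp_rows) + 1L]] <- dplyr::bind_rows(
          take(dist_sel, "disturbed"),
          if (use_regr) take(regr_sel, "regrowth"),
          if (nrow(noch)) tibble(row = rs[noch[, 1]], col = cs[noch[, 2]],
                                 label = "no-change", window_id = wid))
      }
    }
    windows <- dplyr::bind_rows(win_rows)
    if (!length(samp_rows) || !nrow(dplyr::bind_rows(samp_rows)))
      stop("no training extractable: no window passed the sufficiency rules",
           call. = FALSE)
    samples <- dplyr::bind_rows(samp_rows)
    # cap per-class sample counts (stratified, seeded) for tractability
    if (is.finite(cfg$max_samples_per_class)) {
      samples <- samples |>
        dplyr::group_by(.data$label) |>
        dplyr::slice_sample(n = as.integer(cfg$max_samples_per_class)) |>
        dplyr::ungroup()
    }
    ij <- cbind(samples$row, samples$col)
    for (nm in FEATURE_NAMES) samples[[nm]] <- f[[nm]][ij]
    samples <- samples[, c("row", "col", FEATURE_NAMES, "label", "window_id")]
    samples$label <- factor(samples$label, levels = LABEL_LEVELS)
    new_training_set(samples, windows)
  })
}

new_training_set <- function(samples, windows = NULL) {
  out <- as_tibble(samples)
  attr(out, "windows") <- windows
  class(out) <- c("training_set", class(out))
  out
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set> class counts:\n")
  print(table(x$label))
  NextMethod()
}

#' Per-window provenance of a training set
#'
#' @param t A `training_set`.
#' @return Tibble of per-window statistics (`mu`, `sigma`, tail counts,
#'   sufficiency outcome) recorded at extraction time.
#' @export
training_windows <- function(t) attr(t, "windows")

# --- the four filter classifier families -------------------------------

fit_predict_family <- function(family, x_train, y_train, x_test, cfg) {
  y_train <- droplevels(y_train)
  if (nlevels(y_train) < 2)
    return(factor(rep(levels(y_train)[1], nrow(x_test)),
                  levels = levels(y_train)))
  switch(family,
    svm = {
      fit <- e1071::svm(x = x_train, y = y_train, kernel = "radial",
                        scale = FALSE)
      stats::predict(fit, x_test)
    },
    tree = {
      df <- data.frame(x_train, label = y_train)
      fit <- rpart::rpart(label ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = cfg$tree_maxdepth, cp = 0.001,
                            xval = 0))
      stats::predict(fit, data.frame(x_test), type = "class")
    },
    knn = {
      k <- min(cfg$knn_k, nrow(x_train))
      class::knn(x_train, x_test, y_train, k = k)
    },
    nnet = {
      fit <- nnet::nnet(x = x_train, y = stats::model.matrix(~ y_train - 1),
                        size = cfg$nnet_size, maxit = 200, trace = FALSE,
                        decay = 5e-4, MaxNWts = 10000, softmax = TRUE)
      pr <- stats::predict(fit, x_test)
      factor(levels(y_train)[max.col(pr)], levels = levels(y_train))
    })
}

FILTER_FAMILIES <- c("svm", "tree", "knn", "nnet")

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    ix <- which(y == lv)
    fold[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
  }
  fold
}

stratified_subsample <- function(y, frac) {
  sel <- integer(0)
  for (lv in levels(droplevels(y))) {
    ix <- which(y == lv)
    n <- max(1L, ceiling(frac * length(ix)))
    sel <- c(sel, sample(ix, n))
  }
  sort(sel)
}

#' Consensus filtering of mislabelled training samples
#'
#' Removes samples that every classifier in a four-family ensemble
#' (max-margin SVM, depth-limited decision tree, k-nearest-neighbour,
#' single-hidden-layer neural network) misclassifies under stratified
#' `cfg$n_folds`-fold cross-validation. For each fold, each family is
#' trained on a stratified `cfg$filter_train_frac` subsample (without
#' replacement, forced to reflect the class distribution of the whole
#' set) of the remaining folds and predicts the held-out fold. With
#' `cfg$filter_rule = "majority"`, a strict majority of wrong votes
#' (3 of 4) suffices for removal instead of unanimity.
#'
#' Classes with fewer than `cfg$n_folds` samples are exempted from
#' removal (with a warning). Deterministic given `cfg$rng_seed`.
#'
#' @param t A `training_set` (or tibble with the six feature columns and
#'   a `label` factor) with at least two classes.
#' @param cfg A [pipeline_config()].
#' @return List with elements `training` (the filtered `training_set`)
#'   and `report` (class `filter_report`: removed row ids, removal
#'   fraction, per-family misclassification tallies).
#' @export
consensus_filter <- function(t, cfg = pipeline_config()) {
  y <- droplevels(factor(t$label))
  if (nlevels(y) < 2)
    stop("consensus filter needs at least two classes", call. = FALSE)
  n <- nrow(t)
  X <- as.matrix(t[, FEATURE_NAMES])
  # z-score once over the whole set; distance-based families need it
  ctr <- colMeans(X); scl <- pmax(apply(X, 2, stats::sd), 1e-9)
  Xs <- scale(X, ctr, scl)
  colnames(Xs) <- FEATURE_NAMES
  small <- names(which(table(y) < cfg$n_folds))
  if (length(small))
    warning("class(es) exempt from removal (fewer than n_folds samples): ",
            paste(small, collapse = ", "))
  with_local_seed(cfg$rng_seed + 1L, {
    fold <- stratified_folds(y, cfg$n_folds)
    wrong <- matrix(FALSE, n, length(FILTER_FAMILIES),
                    dimnames = list(NULL, FILTER_FAMILIES))
    for (fd in seq_len(cfg$n_folds)) {
      hold <- which(fold == fd)
      pool <- which(fold != fd)
      if (!length(hold) || !length(pool)) next
      for (fam in FILTER_FAMILIES) {
        sub <- pool[stratified_subsample(y[pool], cfg$filter_train_frac)]
        pred <- fit_predict_family(fam, Xs[sub, , drop = FALSE], y[sub],
                                   Xs[hold, , drop = FALSE], cfg)
        wrong[hold, fam] <- as.character(pred) != as.character(y[hold])
      }
    }
    n_wrong <- rowSums(wrong)
    removed <- if (cfg$filter_rule == "consensus")
      n_wrong == length(FILTER_FAMILIES) else n_wrong >= 3
    removed[y %in% small] <- FALSE
    report <- structure(list(
      removed_ids = which(removed),
      n_original = n,
      n_removed = sum(removed),
      removal_fraction = sum(removed) / n,
      per_family_misclassified = colSums(wrong),
      rule = cfg$filter_rule,
      by_class_removed = table(y[removed])
    ), class = "filter_report")
    kept <- t[!removed, , drop = FALSE]
    list(training = new_training_set(kept, training_windows(t)),
         report = report)
  })
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> removed %d / %d samples (%.1f%%), rule = %s\n",
              x$n_removed, x$n_original, 100 * x$removal_fraction, x$rule))
  cat("per-family misclassification tallies:\n")
  print(x$per_family_misclassified)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn consensus_filter Tidy per-sample removal table of a
#'   `filter_report`.
#' @param x A `filter_report`.
#' @param ... Unused.
#' @export
tidy.filter_report <- function(x, ...) {
  tibble(sample_id = seq_len(x$n_original),
         removed = seq_len(x$n_original) %in% x$removed_ids)
}

#' @describeIn consensus_filter One-row summary of a `filter_report`.
#' @export
glance.filter_report <- function(x, ...) {
  tibble(n_original = x$n_original, n_removed = x$n_removed,
         removal_fraction = x$removal_fraction, rule = x$rule)
}

#' Serialize a training set to CSV / a filter report to JSON
#'
#' @param t A `training_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_set <- function(t, path) {
  utils::write.csv(as.data.frame(t), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_set
#' @param report A `filter_report`.
#' @export
write_filter_report <- function(report, path) {
  out <- report
  out$by_class_removed <- as.list(out$by_class_removed)
  out$per_family_misclassified <- as.list(out$per_family_misclassified)
  class(out) <- NULL
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
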