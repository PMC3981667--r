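#' Grid search for the RBF-kernel SVM hyperparameters
#'
#' Evaluates every grid point `(C, gamma) = (2^i, 2^j)` for
#' `i in cfg$svm_c_exponents` and `j in cfg$svm_gamma_exponents` by
#' stratified `cfg$svm_cv_folds`-fold cross-validation accuracy on the
#' (standardized) training features, and returns the maximizing point.
#' Ties are broken toward smaller `C`, then smaller `gamma`. When the
#' training set exceeds `cfg$grid_subsample` rows, a stratified seeded
#' subsample of that size is used inside the search only. Deterministic
#' given `cfg$rng_seed`.
#'
#' @param t A `training_set` with at least two classes.
#' @param cfg A [pipeline_config()].
#' @return Object of class `svm_params`: list with `C`, `gamma`,
#'   `cv_accuracy`, and the searched `grid` (tibble of all points and
#'   their accuracies).
#' @export
svm_grid_search <- function(t, cfg = pipeline_config()) {
  y <- droplevels(factor(t$label))
  if (nlevels(y) < 2)
    stop("grid search needs at least two classes", call. = FALSE)
  X <- as.matrix(t[, FEATURE_NAMES])
  ctr <- colMeans(X); scl <- pmax(apply(X, 2, stats::sd), 1e-9)
  Xs <- scale(X, ctr, scl)
  with_local_seed(cfg$rng_seed + 2L, {
    if (is.finite(cfg$grid_subsample) && nrow(Xs) > cfg$grid_subsample) {
      frac <- cfg$grid_subsample / nrow(Xs)
      sel <- stratified_subsample(y, frac)
      Xs <- Xs[sel, , drop = FALSE]; y <- droplevels(y[sel])
    }
    fold <- stratified_folds(y, cfg$svm_cv_folds)
    grid <- expand.grid(c_exp = cfg$svm_c_exponents,
                        gamma_exp = cfg$svm_gamma_exponents)
    acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      C <- 2^grid$c_exp[g]; gamma <- 2^grid$gamma_exp[g]
      correct <- 0L
      for (fd in seq_len(cfg$svm_cv_folds)) {
        hold <- fold == fd
        if (!any(hold) || nlevels(droplevels(y[!hold])) < 2) next
        fit <- e1071::svm(x = Xs[!hold, , drop = FALSE],
                          y = droplevels(y[!hold]),
                          kernel = "radial", cost = C, gamma = gamma,
                          scale = FALSE)
        pred <- stats::predict(fit, Xs[hold, , drop = FALSE])
        correct <- correct + sum(as.character(pred) == as.character(y[hold]))
      }
      acc[g] <- correct / length(y)
    }
    grid$accuracy <- acc
    best <- order(-grid$accuracy, grid$c_exp, grid$gamma_exp)[1]
    structure(list(C = 2^grid$c_exp[best], gamma = 2^grid$gamma_exp[best],
                   cv_accuracy = grid$accuracy[best],
                   grid = as_tibble(grid)),
              class = "svm_params")
  })
}

#' @export
print.svm_params <- function(x, ...) {
  cat(sprintf("<svm_params C = 2^%g, gamma = 2^%g, CV accuracy %.3f>\n",
              log2(x$C), log2(x$gamma), x$cv_accuracy))
  invisible(x)
}

#' Train the final RBF-kernel SVM
#'
#' Fits a multi-class (one-vs-one) C-classification SVM with a radial
#' basis kernel on the six multi-temporal tasseled-cap features,
#' standardized per feature with training statistics that are stored in
#' the model and re-applied at prediction time.
#'
#' @param t A `training_set` with at least two classes.
#' @param params An `svm_params` from [svm_grid_search()], or a list with
#'   `C` and `gamma`.
#' @param cfg A [pipeline_config()].
#' @return Object of class `disturbance_model`.
#' @export
train_classifier <- function(t, params, cfg = pipeline_config()) {
  y <- droplevels(factor(t$label))
  if (nrow(t) == 0) stop("empty training set", call. = FALSE)
  if (nlevels(y) < 2)
    stop("training requires at least two classes", call. = FALSE)
  X <- as.matrix(t[, FEATURE_NAMES])
  ctr <- colMeans(X); scl <- pmax(apply(X, 2, stats::sd), 1e-9)
  Xs <- scale(X, ctr, scl)
  with_local_seed(cfg$rng_seed + 3L, {
    fit <- e1071::svm(x = Xs, y = y, kernel = "radial",
                      cost = params$C, gamma = params$gamma, scale = FALSE)
    structure(list(svm = fit, center = ctr, scale = scl,
                   classes = levels(y),
                   params = list(C = params$C, gamma = params$gamma),
                   n_train = nrow(Xs), seed = cfg$rng_seed),
              class = "disturbance_model")
  })
}

#' @export
print.disturbance_model <- function(x, ...) {
  cat(sprintf(
    "<disturbance_model RBF SVM: %d samples, classes [%s], C = %g, gamma = %g>\n",
    x$n_train, paste(x$classes, collapse = ", "),
    x$params$C, x$params$gamma))
  invisible(x)
}

#' @describeIn train_classifier One-row model summary.
#' @param x A `disturbance_model`.
#' @param ... Unused.
#' @export
glance.disturbance_model <- function(x, ...) {
  tibble(n_train = x$n_train, n_support_vectors = nrow(x$svm$SV),
         C = x$params$C, gamma = x$params$gamma,
         n_classes = length(x$classes))
}

#' @describeIn train_classifier Per-class support-vector counts.
#' @export
tidy.disturbance_model <- function(x, ...) {
  tibble(class = x$classes,
         n_support_vectors = as.integer(x$svm$nSV))
}

#' Predict a per-pixel label plane
#'
#' Classifies every valid pixel of the feature stack with a trained
#' model; invalid pixels receive the sentinel 0. Prediction is pure:
#' the same model and stack always give the identical plane.
#'
#' @param model A `disturbance_model`.
#' @param f A `feature_stack`.
#' @param m A `mask_set`.
#' @param chunk Pixels classified per batch.
#' @return Integer matrix: 1 disturbed, 2 regrowth, 3 no-change,
#'   0 sentinel (invalid).
#' @export
predict_map <- function(model, f, m, chunk = 100000L) {
  stopifnot(inherits(model, "disturbance_model"),
            inherits(f, "feature_stack"), inherits(m, "mask_set"))
  valid_ix <- which(m$valid)
  out <- matrix(0L, nrow(m$valid), ncol(m$valid))
  if (!length(valid_ix)) return(out)
  X <- vapply(FEATURE_NAMES, function(nm) f[[nm]][valid_ix],
              numeric(length(valid_ix)))
  if (ncol(X) != length(model$center))
    stop("feature-dimension mismatch between model and stack")
  Xs <- scale(X, model$center, model$scale)
  colnames(Xs) <- FEATURE_NAMES
  codes <- integer(length(valid_ix))
  for (start in seq(1, length(valid_ix), by = chunk)) {
    ix <- start:min(length(valid_ix), start + chunk - 1)
    pred <- stats::predict(model$svm, Xs[ix, , drop = FALSE])
    codes[ix] <- match(as.character(pred), LABEL_LEVELS)
  }
  out[valid_ix] <- codes
  out
}
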