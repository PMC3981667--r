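#' Morphological cleaning of the per-pixel classification
#'
#' Applies a binary opening (erosion then dilation with a square
#' structuring element of radius `cfg$morph_radius`) to the disturbed
#' layer of the label plane; disturbed pixels opened away revert to
#' no-change. Other labels are untouched.
#'
#' @param labels Integer label plane from [predict_map()].
#' @param cfg A [pipeline_config()].
#' @return Cleaned integer label plane.
#' @export
morphological_clean <- function(labels, cfg = pipeline_config()) {
  labels <- as.matrix(labels); storage.mode(labels) <- "integer"
  dist <- labels == 1L
  opened <- open_binary(dist, cfg$morph_radius)
  out <- labels
  out[dist & !opened] <- 3L  # removed disturbance reverts to no-change
  out
}

#' Region-merging segmentation of the two-date spectral stack
#'
#' Segments the valid region of the pair on six bands (red, NIR, SWIR-1
#' at both dates): every valid pixel starts as its own segment and the
#' 8-connected pair of segments with the smallest Euclidean distance
#' between mean vectors is merged repeatedly while that distance is below
#' `cfg$merge_threshold`; afterwards every segment smaller than
#' `cfg$mmu` pixels is force-merged into its spectrally nearest
#' neighbour. Isolated valid components smaller than the minimum mapping
#' unit have no neighbour to merge into and are dropped from the segment
#' map (they fall back to stable non-forest at composition).
#' Deterministic.
#'
#' @param p A `scene_pair`.
#' @param m A `mask_set` (segmentation covers `m$valid`).
#' @param cfg A [pipeline_config()].
#' @return Object of class `segment_map`: `ids` (integer matrix, 0
#'   outside the valid region) and `segments` (tibble with `segment_id`,
#'   `n_pixels` and the six mean spectral values).
#' @export
segment_pair <- function(p, m, cfg = pipeline_config()) {
  stopifnot(inherits(p, "scene_pair"), inherits(m, "mask_set"))
  valid <- m$valid
  planes <- list(p$early$bands$red, p$early$bands$nir, p$early$bands$swir1,
                 p$late$bands$red, p$late$bands$nir, p$late$bands$swir1)
  ix <- which(valid)
  feats <- vapply(planes, function(pl) pl[ix], numeric(length(ix)))
  if (!length(ix)) feats <- matrix(numeric(0), 0, 6)
  ids <- .segment_cpp(feats, valid, cfg$merge_threshold, cfg$mmu)
  lab <- ids[ix]
  keep <- lab > 0L  # isolated sub-MMU components are dropped by the MMU pass
  ix <- ix[keep]; feats <- feats[keep, , drop = FALSE]
  seg_tbl <- if (length(ix)) {
    lab <- lab[keep]
    means <- apply(feats, 2, function(col) tapply(col, lab, mean))
    if (is.null(dim(means))) means <- matrix(means, nrow = 1)
    tibble(segment_id = as.integer(sort(unique(lab))),
           n_pixels = as.integer(table(lab)),
           red1 = means[, 1], nir1 = means[, 2], swir11 = means[, 3],
           red2 = means[, 4], nir2 = means[, 5], swir12 = means[, 6])
  } else {
    tibble(segment_id = integer(), n_pixels = integer(),
           red1 = numeric(), nir1 = numeric(), swir11 = numeric(),
           red2 = numeric(), nir2 = numeric(), swir12 = numeric())
  }
  structure(list(ids = ids, segments = seg_tbl), class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map %d segments over %d valid px>\n",
              nrow(x$segments), sum(x$ids > 0)))
  invisible(x)
}

#' Plurality labelling of segments
#'
#' Each segment receives the most frequent per-pixel label among its
#' pixels; ties break toward no-change (the conservative choice for the
#' disturbance class, whose dominant error mode is commission).
#'
#' @param seg A `segment_map`.
#' @param labels Integer label plane (1 disturbed, 2 regrowth,
#'   3 no-change, 0 sentinel; sentinel pixels are not counted).
#' @return Tibble with `segment_id`, `label_code`, `label`, and the
#'   per-label pixel counts `n_disturbed`, `n_regrowth`, `n_nochange`.
#' @export
plurality_label <- function(seg, labels) {
  stopifnot(inherits(seg, "segment_map"))
  labels <- as.matrix(labels)
  if (!identical(dim(labels), dim(seg$ids)))
    stop("registration error: label plane is not on the segment grid")
  in_seg <- seg$ids > 0L & labels > 0L
  ids <- seg$ids[in_seg]; lab <- labels[in_seg]
  counts <- matrix(0L, nrow = nrow(seg$segments), ncol = 3)
  if (length(ids)) {
    tb <- table(factor(ids, levels = seg$segments$segment_id),
                factor(lab, levels = 1:3))
    counts <- matrix(as.integer(tb), ncol = 3)
  }
  # plurality with ties -> no-change (code 3)
  pick <- apply(counts, 1, function(cnt) {
    mx <- max(cnt)
    if (mx == 0L) return(3L)
    winners <- which(cnt == mx)
    if (length(winners) > 1L) 3L else winners
  })
  tibble(segment_id = seg$segments$segment_id,
         label_code = as.integer(pick),
         label = LABEL_LEVELS[pick],
         n_disturbed = counts[, 1], n_regrowth = counts[, 2],
         n_nochange = counts[, 3])
}

#' Compose the final six-category change map
#'
#' Combines the segment labels with the masks under the precedence
#' cloud > shadow > water > stable non-forest > classified labels:
#' disturbed segments become code 1; no-change and regrowth segments
#' become stable forest (code 2; the product carries no regrowth class);
#' valid-data pixels outside the analysis region become stable non-forest
#' (code 3); water at either date code 4, cloud code 5, cloud shadow
#' code 6; nodata code 0.
#'
#' @param seg_labels Tibble from [plurality_label()].
#' @param seg The `segment_map` the labels refer to.
#' @param m The `mask_set`.
#' @param grid Grid list for the output map.
#' @return A `change_map`.
#' @export
compose_final <- function(seg_labels, seg, m, grid = NULL) {
  stopifnot(inherits(seg, "segment_map"), inherits(m, "mask_set"))
  dims <- dim(m$valid)
  codes <- matrix(CHANGE_CODES[["stable_nonforest"]], dims[1], dims[2])
  # classified labels inside the analysis region
  lab_of_seg <- integer(max(seg$segments$segment_id, 0L))
  lab_of_seg[seg_labels$segment_id] <- seg_labels$label_code
  in_seg <- seg$ids > 0L
  seg_class <- ifelse(lab_of_seg[seg$ids[in_seg]] == 1L,
                      CHANGE_CODES[["disturbed"]],
                      CHANGE_CODES[["stable_forest"]])
  codes[in_seg] <- seg_class
  # valid pixels dropped by the MMU pass stay stable non-forest
  codes[m$water1 | m$water2] <- CHANGE_CODES[["water"]]
  codes[m$shadow1 | m$shadow2] <- CHANGE_CODES[["cloud_shadow"]]
  codes[m$cloud1 | m$cloud2] <- CHANGE_CODES[["cloud"]]
  codes[m$nodata] <- CHANGE_CODES[["nodata"]]
  new_change_map(codes, grid = grid)
}
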