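#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point
#'   scale_fill_manual coord_equal theme_minimal labs facet_wrap
NULL

#' @export
ggplot2::autoplot

CHANGE_PALETTE <- c(
  nodata = "grey90", disturbed = "#d7301f", stable_forest = "#1a9850",
  stable_nonforest = "#d9b365", water = "#4575b4", cloud = "white",
  cloud_shadow = "grey40")

map_to_long <- function(codes) {
  nm <- names(CHANGE_CODES)
  tibble(
    row = as.vector(row(codes)),
    col = as.vector(col(codes)),
    class = factor(nm[match(as.vector(codes), CHANGE_CODES)], levels = nm))
}

#' Plot a change map
#'
#' Renders the six-category raster with the package's standard palette.
#'
#' @param object A `change_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.change_map <- function(object, ...) {
  df <- map_to_long(object$codes)
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$class)) +
    geom_raster() +
    scale_fill_manual(values = CHANGE_PALETTE, drop = FALSE) +
    coord_equal() +
    theme_minimal() +
    labs(x = NULL, y = NULL, fill = "category")
}

#' Plot a training set in feature space
#'
#' Scatter of the early-date brightness change against wetness change,
#' coloured by label; useful for eyeballing class separability before
#' and after filtering.
#'
#' @param object A `training_set`.
#' @param x,y Feature columns to plot (defaults `db`, `dw`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.training_set <- function(object, x = "db", y = "dw", ...) {
  ggplot(object, aes(x = .data[[x]], y = .data[[y]],
                     colour = .data$label)) +
    geom_point(alpha = 0.5, size = 0.8) +
    theme_minimal() +
    labs(colour = "label")
}
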