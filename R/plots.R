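#' Tidy an MI curve into a tibble
#'
#' @param x An `mi_curve` from [estimate_alpha()].
#' @param ... Unused.
#' @return A tibble with columns `alpha` and `mi`.
#' @exportS3Method generics::tidy
tidy.mi_curve <- function(x, ...) {
  tibble::tibble(alpha = x$alphas, mi = x$mi)
}

#' One-row summary of an MI curve
#'
#' @inheritParams tidy.mi_curve
#' @return A tibble with `argmin_alpha`, `grid_argmin`, `mi_min`,
#'   `n_candidates`.
#' @exportS3Method generics::glance
glance.mi_curve <- function(x, ...) {
  tibble::tibble(argmin_alpha = x$argmin_alpha,
                 grid_argmin = x$grid_argmin,
                 mi_min = min(x$mi),
                 n_candidates = length(x$alphas))
}

#' Tidy a mixing estimate into long form
#'
#' @param x A [mixing_estimate()].
#' @param ... Unused.
#' @return A tibble with one row per ordered channel pair: `i`, `j`,
#'   `alpha`.
#' @exportS3Method generics::tidy
tidy.mixing_estimate <- function(x, ...) {
  n <- nrow(x$alpha)
  idx <- which(row(x$alpha) != col(x$alpha))
  tibble::tibble(i = row(x$alpha)[idx], j = col(x$alpha)[idx],
                 alpha = x$alpha[idx])
}

#' Tidy a mosaic grid into a tibble of tiles
#'
#' @param x A [tile_pair()] result.
#' @param ... Unused.
#' @return The tile tibble with a logical `selected` column.
#' @exportS3Method generics::tidy
tidy.mosaic_grid <- function(x, ...) {
  out <- x$tiles
  out$selected <- out$tile %in% x$selected
  out
}

#' Plot an MI curve against the candidate mixing ratio
#'
#' @param object An `mi_curve`.
#' @param ... Unused.
#' @return A ggplot: MI versus candidate ratio with the minimizer marked.
#' @exportS3Method ggplot2::autoplot
autoplot.mi_curve <- function(object, ...) {
  df <- tidy.mi_curve(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$mi)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$argmin_alpha,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "candidate mixing ratio",
                  y = "normalized mutual information",
                  title = sprintf("MI minimum at alpha = %.3f",
                                  object$argmin_alpha))
}

#' Plot a mosaic grid as a similarity heat map
#'
#' @param object A `mosaic_grid`; selected tiles are outlined.
#' @param ... Unused.
#' @return A ggplot of per-tile similarity scores.
#' @exportS3Method ggplot2::autoplot
autoplot.mosaic_grid <- function(object, ...) {
  df <- tidy.mosaic_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$score)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_tile(data = df[df$selected, , drop = FALSE],
                       fill = NA, colour = "red", linewidth = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "tile column", y = "tile row",
                  fill = object$metric,
                  title = "Per-tile inter-channel similarity")
}
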