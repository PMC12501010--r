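# Plot helpers: ternary bias plots, coverage tracks, metamodule heatmaps.

#' Ternary plot of triad relative expression
#'
#' Projects (rA, rB, rD) points into the ternary triangle, colored by
#' bias category, with the seven centroids overlaid.
#'
#' @param bias tibble with `rA`, `rB`, `rD`, `category` (e.g. from
#'   [nlet_bias()]).
#' @return A ggplot object.
#' @export
plot_ternary <- function(bias) {
  tern_xy <- function(a, b, d) {
    tibble(x = b + d / 2, y = d * sqrt(3) / 2)
  }
  pts <- bind_cols(bias, tern_xy(bias$rA, bias$rB, bias$rD))
  cen <- as_tibble(bias_centroids(), rownames = "category")
  cen <- bind_cols(cen, tern_xy(cen$A, cen$B, cen$D))
  tri <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$category),
                        size = 0.8, alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_point(data = cen, shape = 4, size = 3, stroke = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(color = "category")
}

#' Coverage track plot
#'
#' @param track output of [region_profile()] (optionally with a
#'   `chromosome` column for faceting).
#' @param candidates optional [call_candidates()] table to shade.
#' @return A ggplot object.
#' @export
plot_coverage_track <- function(track, candidates = NULL) {
  p <- ggplot2::ggplot(track,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$mean_score)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (bp)", y = "mean coverage score") +
    ggplot2::theme_minimal()
  if (!is.null(candidates) && nrow(candidates) > 0) {
    p <- p + ggplot2::geom_rect(
      data = candidates,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "firebrick",
      inherit.aes = FALSE)
  }
  if ("chromosome" %in% names(track))
    p <- p + ggplot2::facet_wrap(~chromosome, ncol = 1)
  p
}

#' @export
autoplot.stability_partition <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "n-lets") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.metamodule_result <- function(object, ...) {
  ord <- object$tree$order
  labs <- rownames(object$diss)[ord]
  df <- as_tibble(object$diss[ord, ord], rownames = "m1") |>
    pivot_longer(-"m1", names_to = "m2", values_to = "d") |>
    mutate(m1 = factor(.data$m1, levels = labs),
           m2 = factor(.data$m2, levels = labs))
  ggplot2::ggplot(df, ggplot2::aes(.data$m1, .data$m2, fill = .data$d)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - r")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
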