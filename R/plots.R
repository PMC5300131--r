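#' Plot a network configuration
#'
#' Draws unbroken springs as segments coloured by tension magnitude; fixed
#' nodes are marked.
#'
#' @param object An `lvr_network`.
#' @param colour_by `"tension"` (default) or `"none"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lvr_network <- function(object, colour_by = c("tension", "none"),
                                 ...) {
  colour_by <- match.arg(colour_by)
  sp <- filter(object$springs, !.data$broken)
  nd <- object$nodes
  ia <- match(sp$a, nd$id); ib <- match(sp$b, nd$id)
  seg <- tibble(x = nd$x[ia], y = nd$y[ia], xend = nd$x[ib], yend = nd$y[ib],
                tension = abs(sp$k * (sqrt((nd$x[ia] - nd$x[ib])^2 +
                                           (nd$y[ia] - nd$y[ib])^2) - sp$l0)))
  p <- ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                         xend = .data$xend,
                                         yend = .data$yend))
  p <- if (colour_by == "tension") {
    p + ggplot2::geom_segment(ggplot2::aes(colour = .data$tension),
                              linewidth = 0.3) +
      ggplot2::scale_colour_viridis_c(name = "|tension|")
  } else {
    p + ggplot2::geom_segment(linewidth = 0.3)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a disease / treatment trajectory
#'
#' Compliance change and structural heterogeneity against cumulative broken
#' elements.
#'
#' @param object An `lvr_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lvr_trajectory <- function(object, ...) {
  d <- tidyr::pivot_longer(
    select(object$stages, "cumulative_broken", "C_pct", "cv_area"),
    c("C_pct", "cv_area"), names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$cumulative_broken, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "cumulative broken elements", y = NULL)
}

#' Plot study compliance trajectories by arm
#'
#' @param study An `lvr_study`.
#' @return A ggplot of `C_pct` against the broken-element percentage, one
#'   line per network, faceted by arm.
#' @export
plot_study_trajectories <- function(study) {
  ggplot2::ggplot(study$trajectories,
                  ggplot2::aes(.data$cumulative_broken, .data$C_pct,
                                  group = .data$network)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~arm) + ggplot2::theme_minimal() +
    ggplot2::labs(x = "cumulative broken elements", y = "ΔC (%)")
}
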