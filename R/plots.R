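# ggplot2 displays for images, lane profiles and clustering results.

#' @export
autoplot.gel_image <- function(object, ...) {
  px <- object$pixels
  df <- tibble(row = rep(seq_len(nrow(px)), times = ncol(px)),
               col = rep(seq_len(ncol(px)), each = nrow(px)),
               intensity = as.vector(px))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::labs(x = "column (px)", y = "migration row (px)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a lane profile with optional marker and smear annotations
#'
#' @param profile A profile tibble.
#' @param markers Optional [detect_marker_bands()] result.
#' @param region Optional `smear_region`.
#' @return A ggplot.
#' @export
plot_lane_profile <- function(profile, markers = NULL, region = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$row,
                                             y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "migration row (px)", y = "corrected intensity") +
    ggplot2::theme_minimal()
  if (!is.null(region)) {
    p <- p + ggplot2::annotate("rect", xmin = region$start_row,
                               xmax = region$end_row - 1L,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "steelblue")
  }
  if (!is.null(markers)) {
    p <- p + ggplot2::geom_vline(xintercept = markers$center_row,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @export
autoplot.telka_clust <- function(object, ...) {
  kin <- object$kinetics
  long <- tidyr::pivot_longer(kin, dplyr::starts_with("streak_"),
                              names_to = "streak",
                              values_to = "rel_length")
  long$streak <- as.integer(sub("streak_", "", long$streak))
  long <- dplyr::left_join(long, object$labels, by = "mutant")
  means <- group_mean_profiles(kin, object$labels$cluster)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$streak, y = .data$rel_length,
                                     group = .data$mutant,
                                     colour = factor(.data$cluster))) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(x = .data$streak,
                                    y = .data$mean_rel_length,
                                    group = factor(.data$cluster)),
                       linewidth = 1.1) +
    ggplot2::labs(x = "streak (~25 generations)",
                  y = "telomere length relative to wild type",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}
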