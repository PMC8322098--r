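#' @export
ggplot2::autoplot

#' PCA scatter of individuals colored by colony
#'
#' @param object a `gl_pca`.
#' @param ... unused.
#' @export
autoplot.gl_pca <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$colony)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Stacked ancestry bar plot
#'
#' @param object a `qmatrix` or `qmatrix_avg`.
#' @param ... unused.
#' @export
autoplot.qmatrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$id, .data$ancestry,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~colony, scales = "free_x", space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines")) +
    ggplot2::labs(x = NULL, y = "ancestry fraction")
}

#' @export
autoplot.qmatrix_avg <- autoplot.qmatrix

#' R-squared trajectory of the progressive colony removal
#'
#' @param object a `removal_trajectory`.
#' @param ... unused.
#' @export
autoplot.removal_trajectory <- function(object, ...) {
  df <- object$trajectory
  df$label <- ifelse(is.na(df$removed), "none", df$removed)
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$r_squared)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8,
                       size = 3) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "colonies removed", y = expression(R^2))
}

#' Heterozygosity track along the genome for one or more individuals
#'
#' @param tracks tibble from [window_het_tracks()].
#' @param cutoff optional horizontal line marking the RoH cutoff.
#' @export
plot_het_track <- function(tracks, cutoff = NULL) {
  p <- ggplot2::ggplot(tracks[tracks$usable, ],
                       ggplot2::aes((.data$start + .data$end) / 2e6,
                                    .data$het,
                                    colour = .data$individual)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "position (Mb)", y = "window heterozygosity")
  if (!is.null(cutoff))
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = 2)
  p
}

#' Isolation-by-distance scatter with the fitted MRM line
#'
#' @param genetic,geographic distance matrices (same labels).
#' @param fit optional `mrm_result` whose line is overlaid.
#' @export
plot_ibd <- function(genetic, geographic, fit = NULL) {
  df <- tibble(geo = lower_tri(geographic), gen = lower_tri(genetic))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$geo, .data$gen)) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "geographic distance (km)",
                  y = "linearized genetic distance")
  if (!is.null(fit)) {
    b <- fit$coefficients$estimate
    p <- p + ggplot2::geom_abline(intercept = b[1], slope = b[2],
                                  linetype = 2)
  }
  p
}
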