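# ggplot2 presentation methods for the main result types.

#' @describeIn fit_ld_decay plot the r2-vs-distance cloud with the fitted
#'   OLS line and Hill-Weir curve.
#' @param object A `cg_ld_decay` fit.
#' @param ... Unused.
#' @export
autoplot.cg_ld_decay <- function(object, ...) {
  df <- object$data
  rng <- range(df$distance_bp)
  grid <- tibble::tibble(distance_bp = seq(rng[1], rng[2], length.out = 200))
  grid$hill_weir <- hill_weir_expectation(
    object$hill_weir["rho"] * grid$distance_bp, object$n_chromosomes)
  grid$linear <- object$ols["intercept"] + object$ols["slope"] * grid$distance_bp
  grid_long <- tidyr::pivot_longer(grid, c("hill_weir", "linear"),
                                   names_to = "model", values_to = "r2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_bp, y = .data$r2)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = grid_long,
                       ggplot2::aes(colour = .data$model)) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "distance (bp)", y = expression(r^2),
                  colour = "decay model") +
    ggplot2::theme_minimal()
}

#' Plot an association scan
#'
#' Marker p-values by SNP for each trait, with the significance threshold
#' implied by the scan's FDR flag.
#'
#' @param object A `cg_scan` tibble from [association_scan()].
#' @param ... Unused.
#' @export
autoplot.cg_scan <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$p_value))
  df$snp_index <- as.integer(factor(df$snp_id, levels = unique(df$snp_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp_index,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "SNP (map order)", y = expression(-log[10](p)),
                  colour = "q < threshold") +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise r-squared
#'
#' @param pairs A [pairwise_r2()] tibble.
#' @param blocks Optional [detect_blocks()] result drawn as outlines.
#' @return A ggplot.
#' @export
plot_ld_heatmap <- function(pairs, blocks = NULL) {
  df <- tibble::as_tibble(pairs)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                        fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "SNP index", y = "SNP index",
                  fill = expression(r^2)) +
    ggplot2::theme_minimal()
  if (!is.null(blocks) && nrow(blocks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = blocks, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_snp_index - 0.5,
                   xmax = .data$end_snp_index + 0.5,
                   ymin = .data$start_snp_index - 0.5,
                   ymax = .data$end_snp_index + 0.5),
      colour = "red", fill = NA)
  }
  p
}

#' Bar plot of per-region diversity
#'
#' @param div A [diversity_table()] result.
#' @param statistic `"pi"` or `"theta_w"`.
#' @return A ggplot.
#' @export
plot_diversity <- function(div, statistic = c("pi", "theta_w")) {
  statistic <- match.arg(statistic)
  df <- dplyr::filter(tibble::as_tibble(div), .data$partition == "all",
                      !.data$region %in% c("total", "total_silent"))
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region,
                                   y = .data[[statistic]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = statistic) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
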