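#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an averaged aggregation curve
#'
#' Mean fraction of flies on the food over time with a +/- 1 SEM ribbon.
#'
#' @param object An `aggregation_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot aggregation_curve
#' @export
autoplot.aggregation_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min,
                                            y = .data$mean_fraction_on))
  if (any(!is.na(object$sem_fraction_on))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_fraction_on - .data$sem_fraction_on,
                   ymax = .data$mean_fraction_on + .data$sem_fraction_on),
      alpha = 0.25)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "fraction on food",
                  title = "Aggregation kinetics (mean ± 1 SEM)")
}

#' Plot T-40 against density with the cooperativity regression
#'
#' @param object A `coop_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coop_fit
#' @export
autoplot.coop_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$density,
                                            y = .data$t40_min)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "flies in chamber", y = "T-40 (min)",
      title = sprintf("Cooperativity coefficient %.3g min/fly (R² = %.2f)",
                      object$slope, object$r_squared))
}

#' Plot the density-binned social-space profile
#'
#' @param object A `social_space_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot social_space_profile
#' @export
autoplot.social_space_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_lo,
                                       y = .data$mean_normalized_px)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_normalized_px - .data$sem_normalized_px,
                   ymax = .data$mean_normalized_px + .data$sem_normalized_px)) +
    ggplot2::labs(x = "flies in frame (bin)",
                  y = "normalized social space (px)",
                  title = "Social space by fly density")
}

#' Plot Z-score positioning distributions per painted fly
#'
#' @param object A `zscore_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zscore_series
#' @export
autoplot.zscore_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, fill = .data$fly_label)) +
    ggplot2::geom_histogram(bins = 20, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~fly_label) +
    ggplot2::labs(x = "Z-score of nearest-neighbor distance", y = "frames",
                  title = "Relative positioning of painted flies")
}

#' Plot the per-frame food-preference scatter
#'
#' Points on the diagonal's y-intercept 1 mean every fly in the frame was
#' on the food.
#'
#' @param object A `food_preference`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot food_preference
#' @export
autoplot.food_preference <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction_near,
                                       y = .data$fraction_on)) +
    ggplot2::geom_abline(slope = -1, intercept = 1, color = "red") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "fraction near food", y = "fraction on food",
                  title = "On-food vs near-food occupancy per frame")
}

#' Plot the T-40 density sweep of the search simulation
#'
#' Mean +/- SD of T-40 against density for the cooperative and diffusive
#' conditions.
#'
#' @param object A `density_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot density_sweep
#' @export
autoplot.density_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$density, y = .data$mean_t40,
                                       color = .data$condition)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_t40 - .data$sd_t40,
                   ymax = .data$mean_t40 + .data$sd_t40)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "flies", y = "T-40 (ticks)",
                  title = "Cooperative vs diffusive food search")
}

#' Plot the pairwise expression R-squared heatmap
#'
#' @param object An `expr_clust`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot expr_clust
#' @export
autoplot.expr_clust <- function(object, ...) {
  ord <- object$hclust$order
  m <- object$r_squared[ord, ord]
  df <- tidyr::expand_grid(a = rownames(m), b = colnames(m))
  df$r2 <- as.vector(t(m))
  df$a <- factor(df$a, levels = rownames(m))
  df$b <- factor(df$b, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "R²",
                  title = "Pairwise expression R² (dendrogram order)")
}
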