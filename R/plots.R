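# ggplot2 visualizations.

#' Plot a pool design as a target-by-well incidence grid
#'
#' @param object A `pool_design`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pool_design <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$well),
                                  y = factor(.data$target_id,
                                             levels = rev(object$target_ids)))) +
    ggplot2::geom_tile(fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "Well", y = "Target",
                  title = sprintf("%d targets in %d wells (pairwise co-occurrence ≤ 1)",
                                  object$n_targets, object$n_wells)) +
    ggplot2::theme_minimal()
}

#' Plot screen scores and the positivity threshold
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_result <- function(object, ...) {
  s <- mutate(object$score_by_pool,
              positive = .data$pool_index %in% object$positive_pools)
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$pool_index), y = .data$score,
                                  fill = .data$positive)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$z_threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65", `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "Pool", y = "Replicate-aggregated Z score",
                  title = "Pool scores and positivity threshold") +
    ggplot2::theme_minimal()
}

#' Plot an Overton histogram pair
#'
#' Overlays the normalized sample and control histograms and shades the
#' sample-only excess that the Overton statistic integrates.
#'
#' @param h A [histogram_pair()].
#' @return A ggplot.
#' @export
plot_overton <- function(h) {
  stopifnot(inherits(h, "histogram_pair"))
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  fs <- h$sample_counts / sum(h$sample_counts)
  fc <- h$control_counts / sum(h$control_counts)
  d <- tibble(mid = rep(mids, 2),
              freq = c(fs, fc),
              population = rep(c("sample", "control"), each = length(mids)))
  excess <- tibble(mid = mids, freq = pmax(fs - fc, 0))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$freq,
                                  colour = .data$population)) +
    ggplot2::geom_step() +
    ggplot2::geom_col(data = excess, ggplot2::aes(x = .data$mid, y = .data$freq),
                      inherit.aes = FALSE, fill = "firebrick", alpha = 0.4) +
    ggplot2::labs(x = "Intensity", y = "Relative frequency",
                  title = sprintf("Overton percent positive: %.1f%%",
                                  overton_percent_positive(h))) +
    ggplot2::theme_minimal()
}
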