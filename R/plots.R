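#' Plot an SNR time course
#'
#' SNR versus time with a reference line at 1 (no signal beyond replicate
#' noise); BH-significant timepoints (Mann-Whitney by default) are filled.
#'
#' @param object A `snr_timecourse` tibble.
#' @param test Which adjusted p-value marks significance: `"w"`
#'   (Mann-Whitney) or `"t"` (Welch).
#' @param alpha Significance cutoff.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snr_timecourse
#' @export
autoplot.snr_timecourse <- function(object, test = c("w", "t"),
                                    alpha = 0.05, ...) {
  test <- match.arg(test)
  df <- dplyr::filter(object, is.na(.data$skipped_reason))
  df$significant <- df[[paste0("padj_", test)]] < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$snr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "white"),
                               name = paste0("BH p < ", alpha)) +
    ggplot2::labs(x = "Time (h)", y = "SNR (mean CT / mean CC)") +
    ggplot2::theme_minimal()
}

#' Plot distance partitions (CC vs CT bars)
#'
#' Mean control-control and control-treatment Bray-Curtis distances per
#' timepoint, the bar view that complements the SNR trend.
#'
#' @param object A `snr_timecourse` (must carry its `"partitions"`
#'   attribute).
#' @return A ggplot object.
#' @export
plot_distance_partitions <- function(object) {
  parts <- attr(object, "partitions")
  if (is.null(parts) || !length(parts)) stop("no partitions attached", call. = FALSE)
  df <- purrr::map_dfr(parts, function(p) {
    tibble::tibble(
      time_h = p$time_h,
      set = c(rep("CC", p$n_cc), rep("CT", p$n_ct)),
      distance = c(p$cc, p$ct)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$time_h), y = .data$distance,
                                   fill = .data$set)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge(width = 0.8),
                          width = 0.7) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.8),
                        alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "Time (h)", y = "Bray-Curtis distance", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot clustered log2FC trajectories
#'
#' One facet per cluster: member trajectories coloured by their SSE from the
#' cluster median line, the median line itself in black.
#'
#' @param object A `trajectory_clusters` object.
#' @param traj The `trajectory_set` that was clustered.
#' @param max_lines Per cluster, at most this many member lines are drawn
#'   (lowest-SSE first) to keep plots of large tables readable.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trajectory_clusters
#' @export
autoplot.trajectory_clusters <- function(object, traj, max_lines = 200, ...) {
  long <- dplyr::inner_join(
    tidyr::pivot_longer(traj, -"feature", names_to = "time_h",
                        values_to = "lfc"),
    object$assignments, by = "feature"
  )
  long$time_h <- as.numeric(sub("^t", "", long$time_h))
  keep <- dplyr::slice_min(object$assignments, .data$sse, n = max_lines,
                           by = "cluster", with_ties = FALSE)$feature
  long <- long[long$feature %in% keep, ]
  med <- cluster_medians(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$lfc)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$feature, colour = .data$sse),
                       alpha = 0.5) +
    ggplot2::geom_line(data = med, ggplot2::aes(y = .data$median_lfc),
                       colour = "black", linewidth = 1) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_viridis_c(name = "SSE") +
    ggplot2::labs(x = "Time (h)", y = "log2 fold change (treatment / control)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
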