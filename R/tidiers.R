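#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a differential-abundance fit
#'
#' @param x A `da_fit` from [fit_feature_models()].
#' @param ... Unused.
#' @return The per-feature results tibble: `feature`, `base_mean`,
#'   `lfc_treatment`, `p_treatment`, `padj_treatment`, `p_interaction`,
#'   `padj_interaction`, `dispersion`, `flag`.
#' @method tidy da_fit
#' @export
tidy.da_fit <- function(x, ...) x$results

#' @rdname tidy.da_fit
#' @param alpha Significance cutoff used in the summary counts.
#' @return For `glance()`: a one-row model summary.
#' @method glance da_fit
#' @export
glance.da_fit <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_features = nrow(x$results),
    n_samples = x$n_samples,
    n_sig_treatment = length(filter_significant(x, "treatment", alpha)),
    n_sig_interaction = length(filter_significant(x, "interaction", alpha)),
    n_flagged = sum(x$results$flag != "ok"),
    median_dispersion = stats::median(x$results$dispersion, na.rm = TRUE)
  )
}

#' Tidy trajectory clustering results
#'
#' `tidy()` returns one row per cluster (size and the median line in long
#' form is available via `medians`); `augment()` returns the per-feature
#' assignments with SSE; `glance()` a one-row summary.
#'
#' @param x A `trajectory_clusters` from [cluster_trajectories()].
#' @param ... Unused.
#' @method tidy trajectory_clusters
#' @export
tidy.trajectory_clusters <- function(x, ...) {
  med <- tibble::as_tibble(x$medians)
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$k) - 1L, size = x$sizes),
    med
  )
}

#' @rdname tidy.trajectory_clusters
#' @method augment trajectory_clusters
#' @export
augment.trajectory_clusters <- function(x, ...) x$assignments

#' @rdname tidy.trajectory_clusters
#' @method glance trajectory_clusters
#' @export
glance.trajectory_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_features = nrow(x$assignments),
    total_sse = sum(x$assignments$sse),
    seed = x$seed
  )
}

#' Median lines of a clustering in long format
#'
#' @param x A `trajectory_clusters`.
#' @return Tibble `cluster`, `time_h`, `median_lfc`.
#' @export
cluster_medians <- function(x) {
  stopifnot(inherits(x, "trajectory_clusters"))
  med <- tibble::as_tibble(x$medians)
  med$cluster <- seq_len(x$k) - 1L
  tidyr::pivot_longer(med, -"cluster", names_to = "time_h",
                      values_to = "median_lfc") |>
    dplyr::mutate(time_h = as.numeric(sub("^t", "", .data$time_h)))
}
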