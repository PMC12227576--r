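#' Per-timepoint log2 fold-change trajectories
#'
#' For each feature and timepoint t:
#' `log2((mean normalized treatment count at t + pseudocount) /
#'        (mean normalized control count at t + pseudocount))`.
#'
#' @param tbl Normalized feature table.
#' @param metadata Sample metadata; both conditions must be present at every
#'   timepoint.
#' @param pseudocount Added to both means to stabilise zeros (default 1).
#' @return A tibble of class `trajectory_set`: `feature` plus one `t<hours>`
#'   column per timepoint, in design time order. Attributes `timepoints` and
#'   `pseudocount` record the grid.
#' @examples
#' # treatment mean 15 vs control mean 3 with pseudocount 1 -> log2(16/4) = 2
#' @export
log2fc_trajectories <- function(tbl, metadata, pseudocount = 1) {
  validate_metadata(metadata)
  samples <- matched_samples(tbl, metadata)
  md <- metadata[match(samples, metadata$sample), ]
  timepoints <- sort(unique(md$time_h))
  by_tp <- split(md, md$time_h)
  missing <- timepoints[!purrr::map_lgl(
    by_tp[as.character(timepoints)],
    ~ all(c("control", "treatment") %in% .x$condition))]
  if (length(missing)) {
    stop("missing a condition at timepoint(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- feature_matrix(tbl)[, samples, drop = FALSE]
  lfc <- sapply(timepoints, function(tp) {
    ctrl <- md$sample[md$time_h == tp & md$condition == "control"]
    trt <- md$sample[md$time_h == tp & md$condition == "treatment"]
    log2((rowMeans(m[, trt, drop = FALSE]) + pseudocount) /
           (rowMeans(m[, ctrl, drop = FALSE]) + pseudocount))
  })
  colnames(lfc) <- paste0("t", timepoints)
  out <- dplyr::bind_cols(tibble::tibble(feature = rownames(m)),
                          tibble::as_tibble(lfc))
  attr(out, "timepoints") <- timepoints
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("trajectory_set", class(out))
  out
}

# trajectory tibble -> plain matrix (features x timepoints)
trajectory_matrix <- function(traj) {
  m <- as.matrix(traj[, setdiff(names(traj), "feature"), drop = FALSE])
  rownames(m) <- traj$feature
  m
}

trajectory_timepoints <- function(traj) {
  tps <- attr(traj, "timepoints")
  if (is.null(tps)) {
    tps <- as.numeric(sub("^t", "", setdiff(names(traj), "feature")))
  }
  tps
}

#' Cluster log2FC trajectories
#'
#' k-means on the raw (unscaled) log2FC row vectors with many random restarts
#' at a fixed seed. Cluster labels are renumbered 0..K-1 deterministically by
#' descending cluster size (ties broken by the median line content), so the
#' labelling is independent of the initialisation order. For each cluster the
#' per-timepoint median line is computed over its members, and each feature's
#' SSE is the sum over timepoints of its squared deviation from that line.
#'
#' @param traj A `trajectory_set` (or tibble with `feature` + timepoint
#'   columns).
#' @param k Number of clusters (>= 2; defaults: 6 for orthologs, 7 for
#'   pathways).
#' @param seed RNG seed for the restarts.
#' @param nstart Number of random restarts (>= 10 recommended).
#' @return An object of class `trajectory_clusters`: `assignments` tibble
#'   (`feature`, `cluster`, `sse`), `medians` matrix (cluster x timepoint),
#'   `sizes`, `k`, `seed`, `timepoints`.
#' @export
cluster_trajectories <- function(traj, k, seed = 1L, nstart = 10L) {
  m <- trajectory_matrix(traj)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > nrow(m)) stop("k exceeds the number of features", call. = FALSE)
  if (anyNA(m) || any(!is.finite(m))) stop("non-finite trajectory values", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100)

  sizes <- as.vector(table(factor(km$cluster, levels = seq_len(k))))
  med0 <- t(sapply(seq_len(k), function(i) {
    apply(m[km$cluster == i, , drop = FALSE], 2, stats::median)
  }))
  # deterministic content-based relabeling: size desc, then median line
  ord <- do.call(order, c(list(-sizes), as.data.frame(-med0)))
  relabel <- match(seq_len(k), ord) - 1L
  cluster <- relabel[km$cluster]
  medians <- med0[ord, , drop = FALSE]
  rownames(medians) <- paste0("cluster_", seq_len(k) - 1L)
  colnames(medians) <- colnames(m)

  sse <- rowSums((m - medians[cluster + 1L, , drop = FALSE])^2)
  structure(
    list(
      assignments = tibble::tibble(feature = rownames(m),
                                   cluster = cluster, sse = unname(sse)),
      medians = medians,
      sizes = sizes[ord],
      k = as.integer(k),
      seed = as.integer(seed),
      timepoints = trajectory_timepoints(traj)
    ),
    class = "trajectory_clusters"
  )
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat("Trajectory clustering: k =", x$k, "over",
      nrow(x$assignments), "features\n")
  cat("  cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Overlay significant-feature subsets on clusters
#'
#' Cross-tabulates cluster membership with the treatment-effect (TE) and
#' interaction-effect (IE) significant sets from [filter_significant()].
#'
#' @param clusters A `trajectory_clusters` object.
#' @param te_features Feature ids significant for the treatment contrast.
#' @param ie_features Feature ids significant for the interaction contrast.
#' @return A tibble with one row per cluster: `cluster`, `n`, `n_te`, `n_ie`,
#'   and list-columns `members`, `te_members`, `ie_members`.
#' @export
overlay_subsets <- function(clusters, te_features = character(),
                            ie_features = character()) {
  asg <- clusters$assignments
  check_subset <- function(ids, label) {
    unknown <- setdiff(ids, asg$feature)
    if (length(unknown)) {
      warning(length(unknown), " ", label,
              " id(s) absent from the trajectories; ignored", call. = FALSE)
    }
    intersect(ids, asg$feature)
  }
  te <- check_subset(te_features, "TE")
  ie <- check_subset(ie_features, "IE")
  dplyr::summarise(
    asg,
    n = dplyr::n(),
    n_te = sum(.data$feature %in% te),
    n_ie = sum(.data$feature %in% ie),
    members = list(.data$feature),
    te_members = list(intersect(.data$feature, te)),
    ie_members = list(intersect(.data$feature, ie)),
    .by = "cluster"
  ) |> dplyr::arrange(.data$cluster)
}

#' Correlate OTU trajectories with cluster median lines
#'
#' Pearson correlation (two-sided t-based p, df = T - 2) of each OTU's log2FC
#' trajectory against each cluster median line; an OTU is `selected` for a
#' cluster iff r > 0 and p < 0.05 (positive association only). Zero-variance
#' trajectories are flagged and excluded from testing.
#'
#' @param otu_traj A `trajectory_set` for the OTU table (same timepoint
#'   grid).
#' @param clusters A `trajectory_clusters` object, or a medians matrix
#'   (clusters x timepoints).
#' @param alpha Selection cutoff on the p-value.
#' @return A tibble: `otu`, `cluster`, `r`, `p`, `selected`, `flag`.
#' @export
correlate_taxa <- function(otu_traj, clusters, alpha = 0.05) {
  medians <- if (inherits(clusters, "trajectory_clusters")) clusters$medians
             else as.matrix(clusters)
  m <- trajectory_matrix(otu_traj)
  if (ncol(m) != ncol(medians)) {
    stop("OTU trajectories and cluster medians are on different grids", call. = FALSE)
  }
  if (is.null(rownames(medians))) {
    rownames(medians) <- paste0("cluster_", seq_len(nrow(medians)) - 1L)
  }
  grid <- tidyr::expand_grid(otu = rownames(m), cluster = rownames(medians))
  purrr::pmap_dfr(grid, function(otu, cluster) {
    x <- m[otu, ]; y <- medians[cluster, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(otu = otu, cluster = cluster, r = NA_real_,
                            p = NA_real_, selected = NA,
                            flag = "zero_variance"))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble::tibble(otu = otu, cluster = cluster,
                   r = unname(ct$estimate), p = ct$p.value,
                   selected = unname(ct$estimate) > 0 & ct$p.value < alpha,
                   flag = "ok")
  })
}
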