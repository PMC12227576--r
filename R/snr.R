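#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|u - v|) / sum(u + v)`: 0 for identical profiles, 1 for disjoint
#' support.
#'
#' @param u,v Equal-length non-negative vectors, not both all-zero.
#' @return The dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(1, 2, 3), c(3, 2, 1)) # 1/3
#' @export
bray_curtis <- function(u, v) {
  stopifnot(length(u) == length(v))
  if (any(u < 0) || any(v < 0)) stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(u) + sum(v)
  if (tot == 0) stop("undefined distance: both vectors are all-zero", call. = FALSE)
  sum(abs(u - v)) / tot
}

#' All pairwise Bray-Curtis distances between samples
#'
#' Samples are the columns of the feature table, which should be
#' prevalence-filtered and normalized first.
#'
#' @param tbl Feature table (>= 2 samples, no all-zero sample).
#' @return A `dist` object labelled by sample id.
#' @export
distance_matrix <- function(tbl) {
  m <- feature_matrix(tbl)
  if (ncol(m) < 2) stop("need >= 2 samples for a distance matrix", call. = FALSE)
  zero <- colSums(m) == 0
  if (any(zero)) stop("all-zero sample(s): ",
                      paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  vegan::vegdist(t(m), method = "bray")
}

#' Partition distances at a timepoint into CC and CT sets
#'
#' At one timepoint, control-control (CC) distances quantify replicate noise
#' and control-treatment (CT) distances the treatment signal;
#' treatment-treatment pairs are unused. With a controls and b treatments,
#' |CC| = a(a-1)/2 and |CT| = a*b.
#'
#' @param dm `dist` from [distance_matrix()] (or a symmetric matrix).
#' @param metadata Sample metadata.
#' @param timepoint The `time_h` value to partition at.
#' @param excluded_samples Sample ids to drop first (e.g. discarded outlier
#'   replicates).
#' @return A list of class `distance_partition` with elements `time_h`, `cc`,
#'   `ct`, `n_cc`, `n_ct`.
#' @export
partition_distances <- function(dm, metadata, timepoint,
                                excluded_samples = character()) {
  validate_metadata(metadata)
  d <- as.matrix(dm)
  md <- metadata[metadata$time_h == timepoint &
                   !metadata$sample %in% excluded_samples, ]
  md <- md[md$sample %in% rownames(d), ]
  ctrl <- md$sample[md$condition == "control"]
  trt <- md$sample[md$condition == "treatment"]
  if (length(ctrl) < 2) {
    stop("fewer than 2 control samples at ", timepoint, " h", call. = FALSE)
  }
  if (length(trt) < 1) stop("no CT pairs at ", timepoint, " h", call. = FALSE)
  cc <- d[ctrl, ctrl][upper.tri(diag(length(ctrl)))]
  ct <- as.vector(d[ctrl, trt, drop = FALSE])
  structure(
    list(time_h = timepoint, cc = cc, ct = ct,
         n_cc = length(cc), n_ct = length(ct)),
    class = "distance_partition"
  )
}

#' Signal-to-noise ratio of a distance partition
#'
#' mean(CT) / mean(CC): values above 1 mean the treatment signal exceeds
#' replicate noise; values below 1 are meaningful too (the control signal is
#' the stronger one).
#'
#' @param partition A `distance_partition`.
#' @param summary `"mean"` (arithmetic, default) or `"median"`.
#' @return A positive number.
#' @export
snr <- function(partition, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  f <- if (summary == "mean") mean else stats::median
  noise <- f(partition$cc)
  if (noise == 0) stop("degenerate control replicates: mean CC distance is 0",
                       call. = FALSE)
  f(partition$ct) / noise
}

#' Tests for a CC-vs-CT difference
#'
#' Two-sided Welch (unequal-variance) t-test and two-sided Mann-Whitney
#' (exact when sample sizes permit and there are no ties) comparing the CC
#' and CT distance sets. Note the distances share samples and are therefore
#' not independent observations; p-values are reported in the conventional
#' way but should be read with that caveat.
#'
#' @param partition A `distance_partition` with >= 2 distances per set.
#' @return A list with `p_t` and `p_w`.
#' @export
snr_significance <- function(partition) {
  cc <- partition$cc; ct <- partition$ct
  stopifnot(length(cc) >= 2, length(ct) >= 2)
  if (stats::var(cc) == 0 && stats::var(ct) == 0) {
    p <- if (isTRUE(all.equal(mean(cc), mean(ct)))) 1 else 0
    return(list(p_t = p, p_w = if (p == 1) 1 else
      suppressWarnings(stats::wilcox.test(cc, ct)$p.value)))
  }
  p_t <- tryCatch(stats::t.test(cc, ct, var.equal = FALSE)$p.value,
                  error = function(e) 1)
  exact <- length(cc) < 50 && length(ct) < 50 &&
    !any(duplicated(c(cc, ct)))
  p_w <- suppressWarnings(stats::wilcox.test(cc, ct, exact = exact)$p.value)
  list(p_t = p_t, p_w = p_w)
}

#' SNR time course over all design timepoints
#'
#' Computes the Bray-Curtis distance matrix once on the supplied
#' (prevalence-filtered, normalized) table, partitions distances per
#' timepoint, and reports the SNR with Welch-t and Mann-Whitney p-values,
#' BH-adjusted across the timepoints of the dataset. Timepoints failing their
#' preconditions (e.g. < 2 controls after exclusions) are recorded as skips
#' with the reason, not errors.
#'
#' @param tbl Feature table (normalized; see [normalize_counts()]).
#' @param metadata Sample metadata.
#' @param exclude_samples Sample ids to discard before partitioning.
#' @param summary Passed to [snr()].
#' @return A tibble of class `snr_timecourse` with columns `time_h`, `snr`,
#'   `n_cc`, `n_ct`, `p_t`, `padj_t`, `p_w`, `padj_w`, `skipped_reason`; the
#'   per-timepoint partitions are attached as attribute `"partitions"` for
#'   plotting.
#' @export
snr_timecourse <- function(tbl, metadata, exclude_samples = character(),
                           summary = "mean") {
  validate_metadata(metadata)
  keep <- setdiff(matched_samples(tbl, metadata), exclude_samples)
  dm <- distance_matrix(tbl[, c("feature", keep)])
  timepoints <- sort(unique(metadata$time_h))

  rows <- purrr::map(timepoints, function(tp) {
    part <- tryCatch(
      partition_distances(dm, metadata, tp, excluded_samples = exclude_samples),
      error = function(e) conditionMessage(e)
    )
    if (is.character(part)) {
      return(list(row = tibble::tibble(
        time_h = tp, snr = NA_real_, n_cc = NA_integer_, n_ct = NA_integer_,
        p_t = NA_real_, p_w = NA_real_, skipped_reason = part
      ), part = NULL))
    }
    sig <- snr_significance(part)
    list(row = tibble::tibble(
      time_h = tp, snr = snr(part, summary = summary),
      n_cc = part$n_cc, n_ct = part$n_ct,
      p_t = sig$p_t, p_w = sig$p_w, skipped_reason = NA_character_
    ), part = part)
  })
  out <- dplyr::bind_rows(purrr::map(rows, "row"))
  ok <- is.na(out$skipped_reason)
  out$padj_t <- out$padj_w <- NA_real_
  out$padj_t[ok] <- bh_adjust(out$p_t[ok])
  out$padj_w[ok] <- bh_adjust(out$p_w[ok])
  out <- out[, c("time_h", "snr", "n_cc", "n_ct",
                 "p_t", "padj_t", "p_w", "padj_w", "skipped_reason")]
  attr(out, "partitions") <- purrr::compact(purrr::map(rows, "part"))
  class(out) <- c("snr_timecourse", class(out))
  out
}

# pseudo-F from the standard distance-based sum-of-squares partition
pseudo_f <- function(d2, grp) {
  n <- length(grp)
  g <- length(unique(grp))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lv in unique(grp)) {
    idx <- grp == lv
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / sum(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

#' Pairwise PERMANOVA (Adonis) at a timepoint
#'
#' Control-vs-treatment permutational multivariate ANOVA on the distance
#' matrix: pseudo-F from the distance-based sum-of-squares partition, p from
#' seeded label permutations, `p = (1 + #permuted F >= observed) /
#' (1 + n_permutations)`. With `exhaustive = TRUE` all label assignments are
#' enumerated instead and `p = #(F >= observed) / #assignments` (feasible for
#' small designs, e.g. 3-vs-3).
#'
#' @param dm `dist` or symmetric distance matrix.
#' @param metadata Sample metadata.
#' @param timepoint The `time_h` value to test at.
#' @param n_permutations Number of random label permutations.
#' @param seed RNG seed for the permutations.
#' @param exhaustive Enumerate all label assignments instead of sampling.
#' @param excluded_samples Sample ids to drop first.
#' @return A one-row tibble: `time_h`, `f`, `p`, `n_permutations`, `method`.
#' @export
permanova_pairwise <- function(dm, metadata, timepoint, n_permutations = 999,
                               seed = 1L, exhaustive = FALSE,
                               excluded_samples = character()) {
  validate_metadata(metadata)
  d <- as.matrix(dm)
  md <- metadata[metadata$time_h == timepoint &
                   !metadata$sample %in% excluded_samples, ]
  md <- md[md$sample %in% rownames(d), ]
  grp <- md$condition
  if (length(unique(grp)) != 2 || any(table(grp) < 2)) {
    stop("need two groups with >= 2 samples each", call. = FALSE)
  }
  d2 <- d[md$sample, md$sample]^2
  f_obs <- pseudo_f(d2, grp)
  tol <- 1e-12

  if (exhaustive) {
    n1 <- sum(grp == grp[1])
    combs <- utils::combn(length(grp), n1)
    f_all <- apply(combs, 2, function(idx) {
      g <- rep("b", length(grp)); g[idx] <- "a"
      pseudo_f(d2, g)
    })
    p <- mean(f_all >= f_obs - tol)
    n_used <- ncol(combs)
    method <- "exhaustive"
  } else {
    if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
    set.seed(seed)
    f_perm <- replicate(n_permutations, pseudo_f(d2, sample(grp)))
    p <- (1 + sum(f_perm >= f_obs - tol)) / (1 + n_permutations)
    n_used <- n_permutations
    method <- "permutation"
  }
  tibble::tibble(time_h = timepoint, f = f_obs, p = p,
                 n_permutations = n_used, method = method)
}
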