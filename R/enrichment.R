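#' Candidate KO sets for enrichment at a timepoint
#'
#' A KO qualifies at timepoint t iff (i) its absolute log2 fold change
#' (group means with pseudocount) is at least `lfc_min` (fold change >= 2 by
#' default), (ii) it is detected (nonzero) in at least `occ_min` of the
#' samples of at least one group, and (iii) it has a nonzero total count in
#' both groups ("present in both"). Qualifying KOs with log2FC >= +`lfc_min`
#' form the treatment set, those with log2FC <= -`lfc_min` the control set.
#'
#' @param tbl Normalized KO feature table.
#' @param metadata Sample metadata.
#' @param timepoint The `time_h` value.
#' @param lfc_min Minimum |log2FC| (1 = two-fold).
#' @param occ_min Minimum detection prevalence within a group.
#' @param pseudocount Added to group means for the fold change.
#' @return A list with character vectors `treatment` and `control`.
#' @export
candidate_kos <- function(tbl, metadata, timepoint, lfc_min = 1,
                          occ_min = 0.10, pseudocount = 1) {
  validate_metadata(metadata)
  samples <- matched_samples(tbl, metadata)
  md <- metadata[match(samples, metadata$sample), ]
  ctrl <- md$sample[md$time_h == timepoint & md$condition == "control"]
  trt <- md$sample[md$time_h == timepoint & md$condition == "treatment"]
  if (!length(ctrl) || !length(trt)) {
    stop("both groups required at ", timepoint, " h", call. = FALSE)
  }
  m <- feature_matrix(tbl)
  mc <- m[, ctrl, drop = FALSE]
  mt <- m[, trt, drop = FALSE]
  lfc <- log2((rowMeans(mt) + pseudocount) / (rowMeans(mc) + pseudocount))
  occ_ok <- rowMeans(mc > 0) >= occ_min | rowMeans(mt > 0) >= occ_min
  present_both <- rowSums(mc) > 0 & rowSums(mt) > 0
  qualifies <- abs(lfc) >= lfc_min & occ_ok & present_both
  list(
    treatment = rownames(m)[qualifies & lfc >= lfc_min],
    control = rownames(m)[qualifies & lfc <= -lfc_min]
  )
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for X ~ Hypergeometric with `N` background KOs of which `K`
#' are annotated to the pathway, drawing the `n` test-set KOs.
#'
#' @param x Observed overlap between test set and pathway.
#' @param K Pathway KOs in the background.
#' @param n Test set size.
#' @param N Background size.
#' @return The exact upper-tail probability.
#' @examples
#' hypergeom_upper(4, K = 5, n = 4, N = 10) # choose(5,4)/choose(10,4)
#' @export
hypergeom_upper <- function(x, K, n, N) {
  stopifnot(length(x) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (x < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N || x > min(n, K)) {
    stop("invalid hypergeometric configuration", call. = FALSE)
  }
  if (x == 0) return(1)
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric pathway over-representation
#'
#' Tests each pathway with at least one background KO for over-representation
#' of the test set, using the upper-tail hypergeometric probability. The
#' background is the union of KOs identified in any sample at any timepoint.
#'
#' @param test_set Candidate KO ids (a subset of `background`; ids outside it
#'   are dropped with a warning).
#' @param background Background KO ids.
#' @param map KO-pathway map tibble (`ko`, `pathway`).
#' @param alpha Enrichment cutoff on the raw p-value (no multiplicity
#'   correction; the conventional raw p < 0.01 rule).
#' @return A tibble sorted by p: `pathway`, `x`, `K`, `n`, `N`, `p`,
#'   `enriched`. Empty (zero-row) when the test set is empty.
#' @export
enrich_pathways <- function(test_set, background, map, alpha = 0.01) {
  background <- unique(background)
  stray <- setdiff(test_set, background)
  if (length(stray)) {
    warning(length(stray), " test-set KO(s) outside the background dropped",
            call. = FALSE)
    test_set <- intersect(test_set, background)
  }
  test_set <- unique(test_set)
  empty <- tibble::tibble(pathway = character(), x = integer(), K = integer(),
                          n = integer(), N = integer(), p = double(),
                          enriched = logical())
  if (!length(test_set)) return(empty)
  map <- map[map$ko %in% background, c("ko", "pathway")]
  if (!nrow(map)) return(empty)
  N <- length(background)
  n <- length(test_set)
  res <- dplyr::summarise(
    map,
    K = dplyr::n_distinct(.data$ko),
    x = dplyr::n_distinct(.data$ko[.data$ko %in% test_set]),
    .by = "pathway"
  )
  res$n <- n
  res$N <- N
  res$p <- purrr::pmap_dbl(res[, c("x", "K", "n", "N")],
                           function(x, K, n, N) hypergeom_upper(x, K, n, N))
  res$enriched <- res$p < alpha
  dplyr::arrange(res[, c("pathway", "x", "K", "n", "N", "p", "enriched")],
                 .data$p)
}

#' Enrichment time course (wide incidence matrix)
#'
#' Runs [candidate_kos()] and [enrich_pathways()] at every timepoint for both
#' directions and assembles a pathway-by-(direction x timepoint) incidence
#' matrix with `"*"` marking significant enrichment, the layout used to
#' summarise which pathways are enriched in treatment or control over time.
#'
#' @inheritParams candidate_kos
#' @param map KO-pathway map tibble.
#' @param alpha Enrichment cutoff.
#' @param background Background KO set (default: all KOs in the table).
#' @return A list of class `enrichment_timecourse`: `results` (long tibble
#'   with `time_h`, `direction`, and the [enrich_pathways()] columns) and
#'   `matrix` (wide tibble, one row per enriched pathway, one
#'   `<direction>_<time>h` marker column per cell).
#' @export
enrichment_timecourse <- function(tbl, metadata, map, lfc_min = 1,
                                  occ_min = 0.10, alpha = 0.01,
                                  pseudocount = 1, background = NULL) {
  validate_metadata(metadata)
  if (is.null(background)) background <- tbl$feature
  timepoints <- sort(unique(metadata$time_h))
  long <- purrr::map_dfr(timepoints, function(tp) {
    sets <- candidate_kos(tbl, metadata, tp, lfc_min = lfc_min,
                          occ_min = occ_min, pseudocount = pseudocount)
    purrr::map_dfr(c("treatment", "control"), function(dir) {
      res <- enrich_pathways(sets[[dir]], background, map, alpha = alpha)
      if (!nrow(res)) return(res[0, ])
      dplyr::bind_cols(tibble::tibble(time_h = tp, direction = dir,
                                      .rows = nrow(res)), res)
    })
  })
  hits <- long[!is.na(long$enriched) & long$enriched, , drop = FALSE]
  wide <- if (nrow(hits)) {
    tidyr::pivot_wider(
      dplyr::mutate(hits, cell = paste0(.data$direction, "_", .data$time_h, "h"),
                    mark = "*"),
      id_cols = "pathway", names_from = "cell", values_from = "mark",
      values_fill = ""
    )
  } else {
    tibble::tibble(pathway = character())
  }
  structure(list(results = long, matrix = wide, alpha = alpha,
                 timepoints = timepoints),
            class = "enrichment_timecourse")
}

#' @export
print.enrichment_timecourse <- function(x, ...) {
  n_hit <- sum(x$results$enriched, na.rm = TRUE)
  cat("Pathway enrichment over", length(x$timepoints), "timepoints:",
      n_hit, "significant pathway x timepoint x direction cells\n")
  if (nrow(x$matrix)) print(x$matrix)
  invisible(x)
}
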