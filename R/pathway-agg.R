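#' Aggregate KO counts to pathway level
#'
#' Pathway counts are the sums of the counts of the KOs annotated to them. A
#' KO mapping to m pathways contributes its full count to each of the m
#' (standard KEGG practice); set `fractional = TRUE` to split a KO's count
#' evenly across its pathways instead. Unmapped KOs are dropped (with a
#' message).
#'
#' @param ko_table Raw KO feature table.
#' @param map KO-pathway map tibble (`ko`, `pathway`).
#' @param fractional Split multi-mapping KO counts 1/m per pathway.
#' @return A pathway-level feature table.
#' @examples
#' tbl <- as_feature_table(matrix(c(10, 5), 2,
#'   dimnames = list(c("K1", "K2"), "s1")))
#' map <- tibble::tibble(ko = c("K1", "K1", "K2"), pathway = c("P1", "P2", "P1"))
#' aggregate_to_pathways(tbl, map) # P1 = 15, P2 = 10
#' @export
aggregate_to_pathways <- function(ko_table, map, fractional = FALSE) {
  validate_feature_table(ko_table)
  if (nrow(map) == 0L) stop("empty KO-pathway map", call. = FALSE)
  map <- dplyr::distinct(map[, c("ko", "pathway")])

  unmapped <- setdiff(ko_table$feature, map$ko)
  if (length(unmapped)) {
    message(length(unmapped), " KO(s) without pathway annotation dropped")
  }
  long <- dplyr::inner_join(
    tidyr::pivot_longer(ko_table, -"feature",
                        names_to = "sample", values_to = "count"),
    map, by = c(feature = "ko"), relationship = "many-to-many"
  )
  if (nrow(long) == 0L) stop("no KO in the table is covered by the map", call. = FALSE)
  if (fractional) {
    deg <- dplyr::count(map, .data$ko, name = "deg")
    long <- dplyr::left_join(long, deg, by = c(feature = "ko"))
    long$count <- long$count / long$deg
  }
  wide <- tidyr::pivot_wider(
    dplyr::summarise(long, count = sum(.data$count),
                     .by = c("pathway", "sample")),
    names_from = "sample", values_from = "count", values_fill = 0
  )
  names(wide)[1] <- "feature"
  out <- dplyr::arrange(wide, .data$feature)
  # restore original sample order
  out[, c("feature", setdiff(names(ko_table), "feature"))]
}

#' Prevalence filter
#'
#' Keeps features detected (nonzero) in at least `min_samples` samples,
#' applied over the whole table. The default (2) removes features found in
#' only one sample, the rule used before any dissimilarity computation.
#'
#' @param tbl Feature table.
#' @param min_samples Minimum number of samples with a nonzero count.
#' @return The filtered feature table.
#' @export
prevalence_filter <- function(tbl, min_samples = 2) {
  validate_feature_table(tbl)
  stopifnot(min_samples >= 1)
  m <- feature_matrix(tbl)
  keep <- rowSums(m > 0) >= min_samples
  if (!any(keep)) stop("prevalence filter removed every feature", call. = FALSE)
  tbl[keep, , drop = FALSE]
}
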