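#' Read a feature table from TSV
#'
#' The file must be tab-separated with a header row; the first column holds
#' feature ids and every remaining column numeric per-sample counts. Negative
#' values, duplicate feature ids and empty files are rejected.
#'
#' @param path Path to a TSV file.
#' @param integer_counts Require whole-number counts.
#' @return A feature-table tibble (see [validate_feature_table()]).
#' @export
read_feature_table <- function(path, integer_counts = FALSE) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0L || ncol(tbl) < 2L) stop("no features in '", path, "'", call. = FALSE)
  names(tbl)[1] <- "feature"
  tbl$feature <- as.character(tbl$feature)
  validate_feature_table(tbl, integer_counts = integer_counts)
  tbl
}

#' Write a feature table to TSV
#'
#' @param tbl Feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  validate_feature_table(tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample`, `condition` (control/treatment), `tank`,
#' `time_h`.
#'
#' @param path Path to a TSV file.
#' @return A validated metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(md) == 0L) stop("no samples in '", path, "'", call. = FALSE)
  md$sample <- as.character(md$sample)
  if ("tank" %in% names(md)) md$tank <- as.character(md$tank)
  validate_metadata(md)
  md
}

#' @rdname read_sample_metadata
#' @param metadata Metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Read a KO-to-pathway map from TSV
#'
#' Two columns: KO id, pathway id (KEGG "mapXXXXX" style). Duplicate pairs are
#' dropped with a warning; a KO may legitimately be absent (unmapped).
#'
#' @param path Path to a two-column TSV.
#' @return A tibble with columns `ko` and `pathway`.
#' @export
read_ko_pathway_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(map) < 2L) stop("KO-pathway map needs two columns", call. = FALSE)
  names(map)[1:2] <- c("ko", "pathway")
  map <- map[, c("ko", "pathway")]
  map$ko <- as.character(map$ko)
  map$pathway <- as.character(map$pathway)
  if (any(!nzchar(map$ko)) || any(!nzchar(map$pathway))) {
    stop("empty id in KO-pathway map", call. = FALSE)
  }
  ndup <- anyDuplicated(map)
  if (ndup) {
    map <- dplyr::distinct(map)
    warning("duplicate KO-pathway pairs dropped", call. = FALSE)
  }
  map
}

#' @rdname read_ko_pathway_map
#' @param map KO-pathway map tibble.
#' @export
write_ko_pathway_map <- function(map, path) {
  stopifnot(all(c("ko", "pathway") %in% names(map)))
  readr::write_tsv(map[, c("ko", "pathway")], path, progress = FALSE)
  invisible(path)
}
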