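#' Feature tables and their validation
#'
#' A feature table is a tibble whose first column, `feature`, holds unique
#' feature identifiers (KEGG orthologs, pathways, or OTUs) and whose remaining
#' columns are one numeric column per sample. Raw tables hold non-negative
#' integers; normalized tables hold non-negative reals.
#'
#' @name feature-table
#' @keywords internal
NULL

#' Coerce a feature table to a counts matrix
#'
#' @param tbl A feature table (tibble with a `feature` column and numeric
#'   sample columns).
#' @return A numeric matrix, features in rows (rownames), samples in columns.
#' @export
feature_matrix <- function(tbl) {
  validate_feature_table(tbl)
  m <- as.matrix(tbl[, setdiff(names(tbl), "feature"), drop = FALSE])
  rownames(m) <- tbl$feature
  m
}

#' Build a feature table from a matrix
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @return A feature-table tibble.
#' @export
as_feature_table <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(
    tibble::tibble(feature = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

#' Validate a feature table
#'
#' Checks the structural invariants of a feature table: a `feature` id column,
#' at least one numeric sample column, no duplicate feature or sample ids, no
#' negative and no missing values.
#'
#' @param tbl Candidate table.
#' @param integer_counts Require whole-number counts (raw tables).
#' @return `tbl`, invisibly, if valid; otherwise an error.
#' @export
validate_feature_table <- function(tbl, integer_counts = FALSE) {
  if (!is.data.frame(tbl) || !"feature" %in% names(tbl)) {
    stop("a feature table needs a 'feature' id column", call. = FALSE)
  }
  samples <- setdiff(names(tbl), "feature")
  if (length(samples) == 0L) stop("feature table has no sample columns", call. = FALSE)
  if (nrow(tbl) == 0L) stop("feature table has no features", call. = FALSE)
  if (anyDuplicated(tbl$feature)) {
    dup <- unique(tbl$feature[duplicated(tbl$feature)])
    stop("duplicate feature id(s): ", paste(utils::head(dup, 3), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples)) stop("duplicate sample column names", call. = FALSE)
  for (s in samples) {
    v <- tbl[[s]]
    if (!is.numeric(v)) stop("sample column '", s, "' is not numeric", call. = FALSE)
    if (anyNA(v)) stop("missing values in sample column '", s, "'", call. = FALSE)
    if (any(v < 0)) {
      i <- which(v < 0)[1]
      stop("negative count at feature '", tbl$feature[i], "', sample '", s, "'",
           call. = FALSE)
    }
    if (integer_counts && any(v != round(v))) {
      i <- which(v != round(v))[1]
      stop("non-integer count at feature '", tbl$feature[i], "', sample '", s, "'",
           call. = FALSE)
    }
  }
  invisible(tbl)
}

#' Validate sample metadata
#'
#' Sample metadata has one row per sample with columns `sample`, `condition`
#' (control/treatment), `tank` and `time_h`. `(tank, time_h)` pairs must be
#' unique and conditions restricted to the two levels.
#'
#' @param metadata Candidate metadata tibble.
#' @return `metadata`, invisibly, if valid.
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample", "condition", "tank", "time_h")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(metadata$condition), c("control", "treatment"))
  if (length(bad)) stop("condition must be 'control' or 'treatment'; found: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(metadata$sample)) stop("duplicate sample ids in metadata", call. = FALSE)
  if (anyDuplicated(metadata[, c("tank", "time_h")])) {
    stop("duplicate (tank, time_h) pairs in metadata", call. = FALSE)
  }
  if (!is.numeric(metadata$time_h)) stop("time_h must be numeric", call. = FALSE)
  invisible(metadata)
}

# samples shared between a feature table and metadata, in table order
matched_samples <- function(tbl, metadata) {
  samples <- setdiff(names(tbl), "feature")
  missing <- setdiff(samples, metadata$sample)
  if (length(missing)) {
    stop("sample(s) absent from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples
}
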