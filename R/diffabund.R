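#' Median-of-ratios size factors
#'
#' Per-sample scaling constants in the median-of-ratios convention: each
#' sample's factor is the median, over reference features, of the ratio of its
#' count to the feature's geometric mean, then rescaled so the factors have
#' geometric mean 1. Reference features are those with nonzero counts in every
#' sample; if none exists, geometric means over the positive counts only are
#' used, with a warning.
#'
#' @param counts A raw feature table.
#' @return A named numeric vector of positive size factors (geometric mean 1).
#' @examples
#' tbl <- as_feature_table(matrix(c(1, 4, 2, 8), 2,
#'   dimnames = list(c("f1", "f2"), c("a", "b"))))
#' size_factors(tbl) # b has twice a's depth: factors (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  m <- feature_matrix(counts)
  if (all(m == 0)) stop("all-zero count table", call. = FALSE)
  if (ncol(m) == 1L) return(stats::setNames(1, colnames(m)))
  all_pos <- rowSums(m > 0) == ncol(m)
  if (any(all_pos)) {
    ref <- m[all_pos, , drop = FALSE]
    log_geo <- rowMeans(log(ref))
    sf <- apply(ref, 2, function(cnt) exp(stats::median(log(cnt) - log_geo)))
  } else {
    warning("no feature nonzero in all samples; using positive-part geometric means",
            call. = FALSE)
    log_geo <- apply(m, 1, function(r) mean(log(r[r > 0])))
    sf <- apply(m, 2, function(cnt) {
      ok <- cnt > 0 & is.finite(log_geo)
      if (!any(ok)) stop("sample with no usable reference counts", call. = FALSE)
      exp(stats::median(log(cnt[ok]) - log_geo[ok]))
    })
  }
  sf / exp(mean(log(sf)))
}

#' Normalize a count table by its size factors
#'
#' @param counts Raw feature table.
#' @param sf Size factors (computed from `counts` if omitted).
#' @return A feature table of counts divided by their sample's size factor.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  m <- feature_matrix(counts)
  stopifnot(all(colnames(m) %in% names(sf)))
  as_feature_table(sweep(m, 2, sf[colnames(m)], "/"))
}

# pooled method-of-moments NB dispersion from normalized counts within
# condition-by-time cells; var = mu + phi mu^2, Poisson part corrected by the
# mean reciprocal size factor of the cell
mom_dispersion <- function(y, sf, cell) {
  norm <- y / sf
  num <- 0; den <- 0
  for (cl in split(seq_along(y), cell)) {
    if (length(cl) < 2) next
    m <- mean(norm[cl])
    if (m <= 0) next
    v <- stats::var(norm[cl])
    num <- num + (v - m * mean(1 / sf[cl]))
    den <- den + m^2
  }
  if (den <= 0) return(1e-8)
  min(max(num / den, 1e-8), 10)
}

# Wald SE from a glm.fit qr decomposition (family dispersion fixed at 1)
wald_se <- function(fit) {
  p <- fit$rank
  Qr <- fit$qr
  cov <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- rep(NA_real_, length(fit$coefficients))
  se[Qr$pivot[seq_len(p)]] <- sqrt(diag(cov))
  se
}

#' Fit per-feature negative-binomial treatment-by-time models
#'
#' For each feature an NB generalized linear model with log link and
#' log-size-factor offsets is fit under the design
#' `~ condition + time + condition:time` with time as a categorical factor.
#' The treatment main effect is tested by a Wald test on the treatment
#' coefficient (reported on the log2 scale, at the reference time level); the
#' treatment-by-time interaction by a likelihood-ratio test against the
#' reduced `~ condition + time` model. Dispersions are per-feature
#' method-of-moments estimates (variance = mu + phi mu^2, floored at 1e-8).
#' BH adjustment is applied separately per contrast across features. Features
#' with nonzero counts in fewer than 3 samples are flagged and assigned p = 1.
#'
#' @param counts Raw integer feature table.
#' @param metadata Sample metadata covering all table samples.
#' @return An object of class `da_fit`; see [tidy.da_fit()] for the
#'   per-feature results tibble.
#' @export
fit_feature_models <- function(counts, metadata) {
  validate_feature_table(counts, integer_counts = TRUE)
  validate_metadata(metadata)
  samples <- matched_samples(counts, metadata)
  md <- metadata[match(samples, metadata$sample), ]
  if (length(unique(md$condition)) < 2) {
    stop("both conditions required to fit a treatment contrast", call. = FALSE)
  }
  if (length(unique(md$time_h)) < 2) stop(">= 2 timepoints required", call. = FALSE)

  cond <- factor(md$condition, levels = c("control", "treatment"))
  tf <- factor(md$time_h, levels = sort(unique(md$time_h)))
  X_full <- stats::model.matrix(~ cond + tf + cond:tf)
  X_red <- stats::model.matrix(~ cond + tf)
  if (qr(X_full)$rank < ncol(X_full)) stop("singular design matrix", call. = FALSE)
  trt_idx <- which(colnames(X_full) == "condtreatment")
  df_lrt <- ncol(X_full) - ncol(X_red)
  cell <- interaction(cond, tf, drop = TRUE)

  m <- feature_matrix(counts)[, samples, drop = FALSE]
  sf <- size_factors(counts)[samples]
  off <- log(sf)

  fit_one <- function(y) {
    if (sum(y > 0) < 3) {
      return(c(lfc = NA_real_, p_t = 1, p_i = 1, phi = NA_real_, flag = 1))
    }
    phi <- mom_dispersion(y, sf, cell)
    fam <- MASS::negative.binomial(theta = 1 / phi)
    out <- tryCatch({
      full <- suppressWarnings(
        stats::glm.fit(X_full, y, family = fam, offset = off))
      red <- suppressWarnings(
        stats::glm.fit(X_red, y, family = fam, offset = off))
      se <- unname(wald_se(full)[trt_idx])
      b <- unname(full$coefficients[trt_idx])
      z <- b / se
      p_t <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 1
      dd <- max(red$deviance - full$deviance, 0)
      p_i <- stats::pchisq(dd, df = df_lrt, lower.tail = FALSE)
      c(lfc = b / log(2), p_t = p_t, p_i = p_i, phi = phi, flag = 0)
    }, error = function(e) c(lfc = NA_real_, p_t = 1, p_i = 1,
                             phi = phi, flag = 2))
    out
  }

  res <- t(apply(m, 1, fit_one))
  results <- tibble::tibble(
    feature = rownames(m),
    base_mean = unname(rowMeans(sweep(m, 2, sf, "/"))),
    lfc_treatment = unname(res[, "lfc"]),
    p_treatment = unname(res[, "p_t"]),
    padj_treatment = unname(bh_adjust(res[, "p_t"])),
    p_interaction = unname(res[, "p_i"]),
    padj_interaction = unname(bh_adjust(res[, "p_i"])),
    dispersion = unname(res[, "phi"]),
    flag = c("ok", "low_count", "fit_failed")[res[, "flag"] + 1]
  )
  structure(
    list(results = results, size_factors = sf,
         design = "~ condition + time + condition:time",
         n_samples = length(samples), timepoints = sort(unique(md$time_h))),
    class = "da_fit"
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (a thin, input-checked wrapper over
#' `p.adjust(method = "BH")`).
#'
#' @param p Numeric p-values in \[0, 1\]; `NaN` is an error.
#' @return Adjusted p-values, order-preserving, capped at 1.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("NaN/NA p-values", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Select significant features from a differential-abundance fit
#'
#' @param fit A `da_fit` object (or its [tidy.da_fit()] tibble).
#' @param contrast `"treatment"` (main effect) or `"interaction"`.
#' @param alpha BH-adjusted significance cutoff; strict `padj < alpha`.
#' @return Character vector of significant feature ids.
#' @export
filter_significant <- function(fit, contrast = c("treatment", "interaction"),
                               alpha = 0.05) {
  contrast <- match.arg(contrast)
  res <- if (inherits(fit, "da_fit")) fit$results else fit
  padj <- res[[paste0("padj_", contrast)]]
  res$feature[!is.na(padj) & padj < alpha]
}

#' @export
print.da_fit <- function(x, ...) {
  cat("Negative-binomial differential abundance fit\n")
  cat("  design: ", x$design, "\n", sep = "")
  cat("  ", nrow(x$results), " features, ", x$n_samples, " samples\n", sep = "")
  cat("  treatment padj < 0.05: ",
      length(filter_significant(x, "treatment")), "\n", sep = "")
  cat("  interaction padj < 0.05: ",
      length(filter_significant(x, "interaction")), "\n", sep = "")
  invisible(x)
}
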