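#' Temporal effect archetypes
#'
#' Named log2 fold-change trajectories (treatment vs control) emulating the
#' qualitative response shapes seen in perturbed mesocosms: an early induction
#' that decays back to baseline, an early repression that recovers, late-onset
#' responses in either direction, an induction followed by a crash, and a
#' transient dip. Values are defined pointwise at the design timepoints; no
#' interpolation is implied because the study design only observes these
#' hours.
#'
#' @param timepoints_h Sampling times in hours (default the 7-point mesocosm
#'   grid).
#' @return A tibble with columns `template`, `time_h`, `lfc`.
#' @examples
#' archetype_templates()
#' @export
archetype_templates <- function(timepoints_h = c(1, 12, 24, 48, 96, 168, 240)) {
  if (length(timepoints_h) != 7L) {
    stop("archetype templates are defined on the 7-point design grid", call. = FALSE)
  }
  shapes <- list(
    early_up_decay     = c( 2.0,  2.5,  1.5,  0.8,  0.4,  0.1, 0.0),
    early_down_recover = c(-1.0, -0.8, -0.5, -0.3, -0.1,  0.0, 0.0),
    late_down          = c( 0.0,  0.0, -0.3, -0.8, -1.2, -1.5, -1.5),
    late_up            = c( 0.0,  0.0,  0.3,  0.8,  1.2,  1.5,  1.5),
    spike_then_crash   = c( 1.0,  1.0, -2.2, -1.0, -0.4,  0.0, 0.0),
    dip_recover        = c( 0.0, -0.5, -2.0, -1.0, -0.3,  0.0, 0.0)
  )
  purrr::imap_dfr(shapes, function(v, nm) {
    tibble::tibble(template = nm, time_h = timepoints_h, lfc = v)
  })
}

# templates tibble -> matrix template x timepoint
template_matrix <- function(templates, timepoints_h) {
  wide <- tidyr::pivot_wider(templates, names_from = "time_h", values_from = "lfc")
  m <- as.matrix(wide[, as.character(timepoints_h), drop = FALSE])
  if (anyNA(m)) stop("templates must be defined at every design timepoint", call. = FALSE)
  rownames(m) <- wide$template
  m
}

#' Generate a balanced mesocosm sampling design
#'
#' Lays out `tanks_per_arm` control and `tanks_per_arm` treatment tanks, each
#' sampled at every timepoint. Sample ids follow the `C1_S1 ... T3_S7`
#' convention (arm + tank number, then timepoint index).
#'
#' @param tanks_per_arm Replicate tanks per arm (>= 2).
#' @param timepoints_h Strictly increasing sampling times in hours.
#' @return A sample-metadata tibble (`sample`, `condition`, `tank`, `time_h`).
#' @examples
#' generate_design()            # 42 samples: 2 x 3 tanks x 7 timepoints
#' generate_design(2, c(1, 12)) # 8 samples
#' @export
generate_design <- function(tanks_per_arm = 3,
                            timepoints_h = c(1, 12, 24, 48, 96, 168, 240)) {
  if (tanks_per_arm < 2) {
    stop("need >= 2 tanks per arm to form control-control pairs", call. = FALSE)
  }
  if (length(timepoints_h) < 2 || any(diff(timepoints_h) <= 0)) {
    stop("timepoints_h must be >= 2 strictly increasing values", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    condition = c("control", "treatment"),
    tank_no = seq_len(tanks_per_arm),
    tp_idx = seq_along(timepoints_h)
  )
  md <- dplyr::mutate(
    grid,
    tank = paste0(ifelse(.data$condition == "control", "C", "T"), .data$tank_no),
    time_h = timepoints_h[.data$tp_idx],
    sample = paste0(.data$tank, "_S", .data$tp_idx)
  )
  md <- dplyr::select(md, "sample", "condition", "tank", "time_h")
  validate_metadata(md)
  md
}

#' Simulation parameters for the synthetic mesocosm
#'
#' Defaults emulate the scale of a protist mesocosm metatranscriptome: ~5,500
#' KEGG orthologs mapping onto 250 pathways, lognormal feature baselines,
#' negative-binomial counts (variance = mu + phi * mu^2) and lognormal library
#' size factors with CV 0.15.
#'
#' @param n_features Number of simulated features (KOs).
#' @param n_pathways Number of pathways the KOs map onto.
#' @param mean_pathways_per_ko Mean map degree (shifted Poisson, >= 1).
#' @param baseline_log_mean,baseline_log_sd Lognormal parameters (natural log
#'   scale) of per-feature baseline means.
#' @param dispersion NB dispersion phi; 0 gives Poisson counts.
#' @param library_size_cv Coefficient of variation of per-sample library
#'   factors.
#' @param affected_fraction Named numeric: fraction of features assigned to
#'   each effect template; must sum to <= 1. Unnamed features are null.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_params`.
#' @export
simulation_params <- function(n_features = 5500,
                              n_pathways = 250,
                              mean_pathways_per_ko = 1.6,
                              baseline_log_mean = 3,
                              baseline_log_sd = 1.5,
                              dispersion = 0.3,
                              library_size_cv = 0.15,
                              affected_fraction = numeric(0),
                              seed = 1L) {
  stopifnot(
    n_features > n_pathways, n_pathways >= 1,
    mean_pathways_per_ko >= 1, baseline_log_sd > 0,
    dispersion >= 0, library_size_cv >= 0
  )
  if (length(affected_fraction)) {
    if (is.null(names(affected_fraction)) || any(!nzchar(names(affected_fraction)))) {
      stop("affected_fraction must be named by template", call. = FALSE)
    }
    if (any(affected_fraction < 0) || any(affected_fraction > 1)) {
      stop("affected fractions must lie in [0, 1]", call. = FALSE)
    }
    if (sum(affected_fraction) > 1) {
      stop("affected fractions sum to > 1", call. = FALSE)
    }
  }
  structure(
    list(
      n_features = as.integer(n_features),
      n_pathways = as.integer(n_pathways),
      mean_pathways_per_ko = mean_pathways_per_ko,
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd,
      dispersion = dispersion,
      library_size_cv = library_size_cv,
      affected_fraction = affected_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' Generate a synthetic KO-to-pathway map
#'
#' Each KO's map degree is drawn from a shifted Poisson
#' (1 + Poisson(mean - 1)), so the average degree equals
#' `mean_pathways_per_ko` and every simulated KO maps to at least one pathway.
#' Pathway ids follow the KEGG `mapXXXXX` convention.
#'
#' @param n_features,n_pathways,mean_pathways_per_ko See [simulation_params()].
#' @param seed Integer RNG seed.
#' @return A tibble with columns `ko`, `pathway`.
#' @export
generate_ko_pathway_map <- function(n_features, n_pathways,
                                    mean_pathways_per_ko = 1.6, seed = 1L) {
  stopifnot(n_pathways >= 1, mean_pathways_per_ko >= 1)
  set.seed(seed)
  kos <- sprintf("K%05d", seq_len(n_features))
  pathways <- sprintf("map%05d", seq_len(n_pathways))
  deg <- 1L + stats::rpois(n_features, mean_pathways_per_ko - 1)
  deg <- pmin(deg, n_pathways)
  map <- purrr::map2_dfr(kos, deg, function(k, d) {
    tibble::tibble(ko = k, pathway = sample(pathways, d))
  })
  dplyr::arrange(map, .data$ko, .data$pathway)
}

# core count sampler: lfc_mat is feature x timepoint true log2FC
nb_counts_core <- function(design, params, lfc_mat, features) {
  timepoints <- sort(unique(design$time_h))
  mu_f <- stats::rlnorm(length(features), params$baseline_log_mean, params$baseline_log_sd)
  sdlog <- sqrt(log(1 + params$library_size_cv^2))
  lib <- stats::rlnorm(nrow(design), 0, sdlog)
  names(lib) <- design$sample
  counts <- matrix(0L, nrow = length(features), ncol = nrow(design),
                   dimnames = list(features, design$sample))
  for (j in seq_len(nrow(design))) {
    tp_idx <- match(design$time_h[j], timepoints)
    lfc <- if (design$condition[j] == "treatment") lfc_mat[, tp_idx] else 0
    mu <- lib[j] * mu_f * 2^lfc
    counts[, j] <- if (params$dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / params$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  counts
}

#' Simulate a mesocosm KO count table with known ground truth
#'
#' Per-feature baselines are lognormal; treatment-arm means at time t are
#' scaled by `2^lfc(t)` of the feature's assigned effect template; counts are
#' negative-binomial with per-sample lognormal library factors.
#'
#' @param design Sample metadata from [generate_design()].
#' @param params A [simulation_params()] object; `params$seed` fixes the run.
#' @param templates Effect templates tibble ([archetype_templates()]).
#' @param affected Optional named character vector `feature id -> template
#'   name` overriding the random assignment drawn from
#'   `params$affected_fraction`.
#' @return A list with `counts` (feature table tibble) and `truth` (tibble
#'   `feature`, `template`, plus one `lfc_<t>` column per timepoint).
#' @examples
#' d <- generate_design(2, c(1, 12))
#' p <- simulation_params(n_features = 50, n_pathways = 5, seed = 7)
#' sim <- generate_counts(d, p)
#' @export
generate_counts <- function(design, params, templates = NULL, affected = NULL) {
  validate_metadata(design)
  timepoints <- sort(unique(design$time_h))
  if (is.null(templates)) {
    templates <- if (length(timepoints) == 7L) archetype_templates(timepoints) else
      tibble::tibble(template = character(), time_h = numeric(), lfc = numeric())
  }
  features <- sprintf("K%05d", seq_len(params$n_features))
  set.seed(params$seed)

  tmpl_mat <- if (nrow(templates)) template_matrix(templates, timepoints) else
    matrix(0, 0, length(timepoints))
  assignment <- rep("null", params$n_features)
  names(assignment) <- features
  if (is.null(affected) && length(params$affected_fraction)) {
    unknown <- setdiff(names(params$affected_fraction), rownames(tmpl_mat))
    if (length(unknown)) stop("affected_fraction names not in templates: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    pool <- sample(features)
    k0 <- 0L
    for (nm in names(params$affected_fraction)) {
      k <- round(params$affected_fraction[[nm]] * params$n_features)
      if (k > 0) assignment[pool[(k0 + 1):(k0 + k)]] <- nm
      k0 <- k0 + k
    }
  } else if (!is.null(affected)) {
    bad <- setdiff(unname(affected), rownames(tmpl_mat))
    if (length(bad)) stop("unknown template(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    assignment[names(affected)] <- affected
  }

  lfc_mat <- matrix(0, nrow = params$n_features, ncol = length(timepoints),
                    dimnames = list(features, paste0("lfc_", timepoints)))
  hit <- assignment != "null"
  if (any(hit)) lfc_mat[hit, ] <- tmpl_mat[assignment[hit], , drop = FALSE]

  counts <- nb_counts_core(design, params, lfc_mat, features)
  truth <- dplyr::bind_cols(
    tibble::tibble(feature = features, template = unname(assignment)),
    tibble::as_tibble(lfc_mat)
  )
  list(counts = as_feature_table(counts), truth = truth)
}

#' Simulate an OTU table tied to cluster median trajectories
#'
#' Affected OTUs follow a supplied cluster-median log2FC trajectory, which
#' makes taxa-cluster correlation recovery testable with known truth.
#'
#' @param design Sample metadata.
#' @param params A [simulation_params()] object (`n_features` = number of
#'   OTUs; the pathway fields are ignored).
#' @param cluster_medians Numeric matrix, clusters x timepoints (timepoints in
#'   design order), e.g. the `medians` element of [cluster_trajectories()].
#' @param seed Integer RNG seed (overrides `params$seed`).
#' @return A list with `counts` (OTU feature table) and `truth` (`feature`,
#'   `template` = cluster name or "null", `lfc_<t>` columns).
#' @export
generate_otu_table <- function(design, params, cluster_medians, seed = params$seed) {
  validate_metadata(design)
  timepoints <- sort(unique(design$time_h))
  if (ncol(cluster_medians) != length(timepoints)) {
    stop("cluster_medians must have one column per design timepoint", call. = FALSE)
  }
  if (is.null(rownames(cluster_medians))) {
    rownames(cluster_medians) <- paste0("cluster_", seq_len(nrow(cluster_medians)))
  }
  features <- sprintf("OTU%04d", seq_len(params$n_features))
  set.seed(seed)

  assignment <- rep("null", params$n_features)
  names(assignment) <- features
  total_frac <- sum(params$affected_fraction)
  if (total_frac > 0) {
    n_hit <- round(total_frac * params$n_features)
    pool <- sample(features, n_hit)
    assignment[pool] <- rownames(cluster_medians)[
      rep_len(seq_len(nrow(cluster_medians)), n_hit)]
  }
  lfc_mat <- matrix(0, nrow = params$n_features, ncol = length(timepoints),
                    dimnames = list(features, paste0("lfc_", timepoints)))
  hit <- assignment != "null"
  if (any(hit)) lfc_mat[hit, ] <- cluster_medians[assignment[hit], , drop = FALSE]

  counts <- nb_counts_core(design, params, lfc_mat, features)
  truth <- dplyr::bind_cols(
    tibble::tibble(feature = features, template = unname(assignment)),
    tibble::as_tibble(lfc_mat)
  )
  list(counts = as_feature_table(counts), truth = truth)
}
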