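#' Default pipeline configuration
#'
#' The full synthetic-run configuration with every threshold at its
#' conventional default: BH filter alpha 0.05, enrichment alpha 0.01,
#' fold-change 2 (lfc_min 1), occurrence 10%, prevalence filter at 2 samples,
#' K = 6 ortholog and 7 pathway clusters, a 3+3-tank design over
#' 1-240 h, and a study-scale simulation (~5,500 KOs, 250 pathways) with 10%
#' of features carrying temporal effect archetypes.
#'
#' @param seed Master seed recorded in the manifest and used by every
#'   stochastic stage.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(tanks_per_arm = 3L,
                  timepoints_h = c(1, 12, 24, 48, 96, 168, 240)),
    simulation = list(
      n_features = 5500L, n_pathways = 250L, mean_pathways_per_ko = 1.6,
      baseline_log_mean = 3, baseline_log_sd = 1.5, dispersion = 0.3,
      library_size_cv = 0.15,
      affected_fraction = list(early_up_decay = 0.04, spike_then_crash = 0.03,
                               dip_recover = 0.03)
    ),
    thresholds = list(alpha_filter = 0.05, alpha_enrich = 0.01,
                      lfc_min = 1, occ_min = 0.10, min_prevalence = 2L),
    k = list(orthologs = 6L, pathways = 7L),
    exclude_samples = character(),
    stages = c("simulate", "diffabund", "snr", "cluster", "enrich")
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file fall back to [default_pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), user)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> pathway aggregation + prevalence filter ->
#' normalization -> differential abundance -> SNR time courses (unfiltered
#' and significance-filtered, at KO and pathway level) -> trajectory
#' clustering -> pathway enrichment, writing every artifact as TSV plus a
#' JSON run manifest (seeds, thresholds, effective parameters, skipped
#' timepoints). Reruns with the same configuration are bit-identical apart
#' from the manifest timestamp.
#'
#' @param config A configuration list ([default_pipeline_config()]), or a
#'   path to a YAML file. Set `config$inputs$ko_table`,
#'   `config$inputs$metadata` and `config$inputs$ko_pathway_map` to run on
#'   external TSV data instead of simulating.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.list(config), !missing(outdir))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  stages <- config$stages
  out <- list()
  tsv <- function(x, name) readr::write_tsv(x, file.path(outdir, name),
                                            progress = FALSE)

  # -- inputs: simulate or load ------------------------------------------
  if (!is.null(config$inputs)) {
    stage_log("load", "reading external inputs")
    for (f in c("ko_table", "metadata", "ko_pathway_map")) {
      if (is.null(config$inputs[[f]])) stop("inputs$", f, " missing", call. = FALSE)
      if (!file.exists(config$inputs[[f]])) {
        stop("input file not found: ", config$inputs[[f]], call. = FALSE)
      }
    }
    ko_counts <- read_feature_table(config$inputs$ko_table, integer_counts = TRUE)
    metadata <- read_sample_metadata(config$inputs$metadata)
    ko_map <- read_ko_pathway_map(config$inputs$ko_pathway_map)
    truth <- NULL
  } else {
    stage_log("simulate", "generating synthetic mesocosm data (seed ",
              config$seed, ")")
    metadata <- generate_design(config$design$tanks_per_arm,
                                config$design$timepoints_h)
    sim_cfg <- config$simulation
    params <- simulation_params(
      n_features = sim_cfg$n_features, n_pathways = sim_cfg$n_pathways,
      mean_pathways_per_ko = sim_cfg$mean_pathways_per_ko,
      baseline_log_mean = sim_cfg$baseline_log_mean,
      baseline_log_sd = sim_cfg$baseline_log_sd,
      dispersion = sim_cfg$dispersion,
      library_size_cv = sim_cfg$library_size_cv,
      affected_fraction = unlist(sim_cfg$affected_fraction),
      seed = config$seed
    )
    ko_map <- generate_ko_pathway_map(params$n_features, params$n_pathways,
                                      params$mean_pathways_per_ko,
                                      seed = config$seed + 1L)
    sim <- generate_counts(metadata, params)
    ko_counts <- sim$counts
    truth <- sim$truth
    tsv(truth, "ground_truth.tsv")
  }
  tsv(ko_counts, "ko_counts.tsv")
  tsv(metadata, "sample_metadata.tsv")
  tsv(ko_map, "ko_pathway_map.tsv")
  out$metadata <- metadata

  # -- aggregation + prevalence filter -----------------------------------
  stage_log("aggregate", "KO -> pathway aggregation and prevalence filter")
  pw_counts <- suppressMessages(aggregate_to_pathways(ko_counts, ko_map))
  ko_f <- prevalence_filter(ko_counts, th$min_prevalence)
  pw_f <- prevalence_filter(pw_counts, th$min_prevalence)
  tsv(pw_counts, "pathway_counts.tsv")

  ko_norm <- normalize_counts(ko_f)
  pw_norm <- normalize_counts(pw_f)
  out$ko_norm <- ko_norm
  out$pw_norm <- pw_norm

  # -- differential abundance --------------------------------------------
  smtto <- smttp <- character()
  if ("diffabund" %in% stages) {
    stage_log("diffabund", "NB treatment-by-time models, KO level (",
              nrow(ko_f), " features)")
    fit_ko <- fit_feature_models(ko_f, metadata)
    stage_log("diffabund", "NB treatment-by-time models, pathway level (",
              nrow(pw_f), " features)")
    fit_pw <- fit_feature_models(pw_f, metadata)
    smtto <- filter_significant(fit_ko, "treatment", th$alpha_filter)
    smttp <- filter_significant(fit_pw, "treatment", th$alpha_filter)
    tsv(tidy(fit_ko), "diffabund_ko.tsv")
    tsv(tidy(fit_pw), "diffabund_pathway.tsv")
    out$fit_ko <- fit_ko
    out$fit_pw <- fit_pw
  }

  # -- SNR time courses ---------------------------------------------------
  if ("snr" %in% stages) {
    datasets <- list(MTTO = ko_norm, MTTP = pw_norm)
    if (length(smtto) >= 2) datasets$SMTTO <- ko_norm[ko_norm$feature %in% smtto, ]
    if (length(smttp) >= 2) datasets$SMTTP <- pw_norm[pw_norm$feature %in% smttp, ]
    snr_all <- purrr::imap_dfr(datasets, function(d, nm) {
      stage_log("snr", nm, ": ", nrow(d), " features")
      tc <- tryCatch(
        snr_timecourse(d, metadata,
                       exclude_samples = unlist(config$exclude_samples)),
        error = function(e) {
          stage_log("snr", nm, " skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(tc)) return(NULL)
      dplyr::bind_cols(tibble::tibble(dataset = nm, .rows = nrow(tc)), tc)
    })
    tsv(snr_all, "snr_timecourse.tsv")
    out$snr <- snr_all
  }

  # -- trajectory clustering ---------------------------------------------
  if ("cluster" %in% stages) {
    stage_log("cluster", "log2FC trajectories and k-means")
    traj_ko <- log2fc_trajectories(ko_norm, metadata)
    traj_pw <- log2fc_trajectories(pw_norm, metadata)
    cl_ko <- cluster_trajectories(traj_ko, k = config$k$orthologs,
                                  seed = config$seed)
    cl_pw <- cluster_trajectories(traj_pw, k = config$k$pathways,
                                  seed = config$seed)
    tsv(traj_ko, "trajectories_ko.tsv")
    tsv(traj_pw, "trajectories_pathway.tsv")
    tsv(augment(cl_ko), "clusters_ko.tsv")
    tsv(augment(cl_pw), "clusters_pathway.tsv")
    tsv(cluster_medians(cl_ko), "cluster_medians_ko.tsv")
    tsv(cluster_medians(cl_pw), "cluster_medians_pathway.tsv")
    if (length(smtto) || length(smttp)) {
      ie_ko <- if (!is.null(out$fit_ko))
        filter_significant(out$fit_ko, "interaction", th$alpha_filter) else character()
      overlay <- overlay_subsets(cl_ko, smtto, ie_ko)
      tsv(overlay[, c("cluster", "n", "n_te", "n_ie")], "cluster_overlay_ko.tsv")
    }
    out$clusters_ko <- cl_ko
    out$clusters_pw <- cl_pw
  }

  # -- enrichment ---------------------------------------------------------
  if ("enrich" %in% stages) {
    stage_log("enrich", "per-timepoint hypergeometric pathway enrichment")
    enr <- enrichment_timecourse(ko_norm, metadata, ko_map,
                                 lfc_min = th$lfc_min, occ_min = th$occ_min,
                                 alpha = th$alpha_enrich)
    tsv(enr$results, "enrichment.tsv")
    tsv(enr$matrix, "enrichment_matrix.tsv")
    out$enrichment <- enr
  }

  # -- manifest -----------------------------------------------------------
  manifest <- list(
    package = "wwsignal",
    version = as.character(utils::packageVersion("wwsignal")),
    seed = config$seed,
    thresholds = th,
    k = config$k,
    stages = stages,
    exclude_samples = config$exclude_samples,
    n_ko = nrow(ko_counts), n_ko_filtered = nrow(ko_f),
    n_pathways = nrow(pw_counts), n_pathways_filtered = nrow(pw_f),
    n_smtto = length(smtto), n_smttp = length(smttp),
    skipped_timepoints = if (!is.null(out$snr)) {
      sk <- out$snr[!is.na(out$snr$skipped_reason), ]
      purrr::map2(sk$time_h, sk$skipped_reason,
                  ~ list(time_h = .x, reason = .y))
    } else list(),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
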