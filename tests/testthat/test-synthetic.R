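test_that("mesocosm design is balanced with the expected ids", {
  md <- generate_design()
  expect_equal(nrow(md), 42L)
  expect_true(all(c("C1_S1", "C3_S7", "T2_S4") %in% md$sample))
  expect_equal(sum(md$condition == "control"), 21L)
  expect_equal(nrow(generate_design(2, c(1, 12))), 8L)
  expect_error(generate_design(1, c(1, 12)), "control-control")
  expect_error(generate_design(3, c(12, 1)), "increasing")
})

test_that("effect archetypes encode the qualitative response shapes", {
  tmpl <- archetype_templates()
  expect_gte(dplyr::n_distinct(tmpl$template), 6L)
  # every template defined at all 7 design timepoints
  counts <- dplyr::count(tmpl, template)
  expect_true(all(counts$n == 7L))
  at <- function(nm, t) tmpl$lfc[tmpl$template == nm & tmpl$time_h == t]
  expect_equal(at("early_up_decay", 1), 2)
  expect_lte(at("spike_then_crash", 24), -2)
  expect_equal(at("early_up_decay", 240), 0)
  expect_lt(at("late_down", 240), 0)
  expect_gt(at("late_up", 240), 0)
})

test_that("KO-pathway map generation honours degree and determinism", {
  map1 <- generate_ko_pathway_map(2000, 50, mean_pathways_per_ko = 1,
                                  seed = 11)
  deg <- table(map1$ko)
  expect_equal(mean(deg), 1, tolerance = 0.02)
  map2 <- generate_ko_pathway_map(2000, 50, mean_pathways_per_ko = 1,
                                  seed = 11)
  expect_identical(map1, map2)

  one <- generate_ko_pathway_map(30, 1, seed = 2)
  expect_true(all(one$pathway == "map00001"))

  # mean degree tracks the shifted-Poisson parameter
  map3 <- generate_ko_pathway_map(3000, 200, mean_pathways_per_ko = 2.5,
                                  seed = 5)
  expect_equal(mean(table(map3$ko)), 2.5, tolerance = 0.05)
})

test_that("count generation is deterministic and respects the null model", {
  d <- toy_design(3, c(1, 12))
  p <- simulation_params(n_features = 100, n_pathways = 10,
                         dispersion = 0, library_size_cv = 0, seed = 4)
  s1 <- generate_counts(d, p)
  s2 <- generate_counts(d, p)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$truth$template == "null"))

  # all-zero templates: treatment and control column means agree within
  # Poisson error of the summed counts
  m <- feature_matrix(s1$counts)
  md <- d
  tot_c <- sum(m[, md$sample[md$condition == "control"]])
  tot_t <- sum(m[, md$sample[md$condition == "treatment"]])
  expect_lt(abs(tot_t - tot_c) / sqrt(tot_t + tot_c), 4)
})

test_that("an injected +2 log2FC template realises a 4x mean ratio", {
  d <- toy_design(3, c(1, 12))
  templates <- tibble::tibble(
    template = "flat_up2",
    time_h = rep(c(1, 12), 1),
    lfc = c(2, 2)
  )
  p <- simulation_params(n_features = 1500, n_pathways = 10,
                         baseline_log_mean = 5, baseline_log_sd = 0.2,
                         dispersion = 0.001, library_size_cv = 0, seed = 9,
                         affected_fraction = c(flat_up2 = 1))
  sim <- generate_counts(d, p, templates = templates)
  m <- feature_matrix(sim$counts)
  md <- d
  for (tp in c(1, 12)) {
    ctrl <- md$sample[md$condition == "control" & md$time_h == tp]
    trt <- md$sample[md$condition == "treatment" & md$time_h == tp]
    ratio <- mean(m[, trt]) / mean(m[, ctrl])
    expect_equal(ratio, 4, tolerance = 0.05)
  }
})

test_that("affected fractions summing over 1 are rejected", {
  expect_error(
    simulation_params(n_features = 10, n_pathways = 2,
                      affected_fraction = c(early_up_decay = 0.6,
                                            late_up = 0.6)),
    "sum to > 1"
  )
})

test_that("effect fidelity: realised log2FC tracks the template", {
  # moderate baseline, low dispersion: realised trajectory within 2 SE
  d <- generate_design()
  p <- simulation_params(n_features = 400, n_pathways = 20,
                         baseline_log_mean = log(200), baseline_log_sd = 0.1,
                         dispersion = 0.05, library_size_cv = 0, seed = 21,
                         affected_fraction = c(early_up_decay = 0.5))
  sim <- generate_counts(d, p)
  # raw counts: library_size_cv = 0, so no normalisation is needed and the
  # check isolates the generator itself
  traj <- log2fc_trajectories(sim$counts, d, pseudocount = 0.5)
  hit <- sim$truth$feature[sim$truth$template == "early_up_decay"]
  tm <- as.matrix(traj[traj$feature %in% hit, -1])
  tmpl <- archetype_templates()
  target <- tmpl$lfc[tmpl$template == "early_up_decay"]
  realised <- colMeans(tm)
  se <- apply(tm, 2, stats::sd) / sqrt(nrow(tm))
  expect_true(all(abs(realised - target) <= pmax(2 * se, 0.1)))
})

test_that("OTU tables tied to a median trajectory are recoverable", {
  d <- generate_design()
  medians <- rbind(strong = c(2, 2.5, 1.5, 0.8, 0.4, 0.1, 0))
  p <- simulation_params(n_features = 300, n_pathways = 5,
                         baseline_log_mean = log(500), baseline_log_sd = 0.2,
                         dispersion = 0.01, library_size_cv = 0,
                         affected_fraction = c(strong = 0.2), seed = 31)
  otu <- generate_otu_table(d, p, medians)
  traj <- log2fc_trajectories(otu$counts, d, pseudocount = 0.5)
  corr <- correlate_taxa(traj, medians)
  hit <- otu$truth$feature[otu$truth$template == "strong"]
  r_hit <- corr$r[corr$otu %in% hit]
  r_null <- corr$r[!corr$otu %in% hit & corr$flag == "ok"]
  expect_gt(min(r_hit), 0.9)
  expect_lt(abs(mean(r_null)), 0.15) # null correlations centred on 0
  # selection rule follows the positive-correlation criterion
  expect_true(all(corr$selected[corr$otu %in% hit]))
})
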