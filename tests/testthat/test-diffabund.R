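test_that("median-of-ratios size factors match hand computations", {
  # two identical samples
  tbl <- tiny_table(cbind(c(2, 8, 5), c(2, 8, 5)))
  expect_equal(unname(size_factors(tbl)), c(1, 1))

  # sample B = 2 x sample A elementwise -> (1/sqrt(2), sqrt(2))
  tbl2 <- tiny_table(cbind(c(1, 4, 10), c(2, 8, 20)))
  expect_equal(unname(size_factors(tbl2)), c(1 / sqrt(2), sqrt(2)))

  # single sample
  tbl3 <- tiny_table(matrix(c(3, 1), 2))
  expect_equal(unname(size_factors(tbl3)), 1)

  # all-zero table errors; no common reference feature falls back with warning
  expect_error(size_factors(tiny_table(matrix(0, 2, 2))), "all-zero")
  tbl4 <- tiny_table(cbind(c(4, 0), c(0, 4)))
  expect_warning(sf <- size_factors(tbl4), "positive-part")
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
})

test_that("size factors scale with sample depth and normalization undoes it", {
  sim <- quick_sim(seed = 2, n_features = 120)
  sf0 <- size_factors(sim$counts)
  scaled <- sim$counts
  scaled[[2]] <- scaled[[2]] * 4
  sf1 <- size_factors(scaled)
  # the scaled sample's factor increases 4-fold relative to the others
  rel0 <- sf0 / exp(mean(log(sf0[-1])))
  rel1 <- sf1 / exp(mean(log(sf1[-1])))
  expect_equal(unname(rel1[1] / rel0[1]), 4, tolerance = 1e-9)
  # normalized values change only by the shared geometric-mean renormalisation
  # constant (c^(1/n)), which vanishes as the sample count grows
  n0 <- feature_matrix(normalize_counts(sim$counts))
  n1 <- feature_matrix(normalize_counts(scaled))
  nz <- n0[, 1] > 0
  ratio <- n1[nz, 1] / n0[nz, 1]
  expect_lt(diff(range(ratio)), 1e-9)          # a single shared constant
  expect_equal(unname(ratio[1]), 4^(1 / 42), tolerance = 1e-9)
})

test_that("BH adjustment matches the step-up hand example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  # order-preserving and capped at 1
  p <- c(0.9, 0.5, 0.01, 0.04)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj <= 1))
})

test_that("filter_significant applies the strict below-alpha rule", {
  res <- tibble::tibble(
    feature = c("a", "b", "c"),
    padj_treatment = c(0.04, 0.05, 0.6),
    padj_interaction = c(0.2, 0.001, NA)
  )
  expect_equal(filter_significant(res, "treatment"), "a")
  expect_equal(filter_significant(res, "interaction"), "b")
  expect_equal(filter_significant(res, "treatment", alpha = 1), c("a", "b", "c"))
  expect_equal(filter_significant(res[0, ], "treatment"), character(0))
})

test_that("NB models find strong effects and stay quiet on flat features", {
  d <- generate_design()
  # 16-fold constant treatment effect, low dispersion
  templates <- tibble::tibble(template = "const4",
                              time_h = c(1, 12, 24, 48, 96, 168, 240),
                              lfc = rep(4, 7))
  p <- simulation_params(n_features = 60, n_pathways = 5,
                         baseline_log_mean = log(150), baseline_log_sd = 0.3,
                         dispersion = 0.01, library_size_cv = 0.1,
                         affected_fraction = c(const4 = 0.25), seed = 5)
  sim <- generate_counts(d, p, templates = templates)
  fit <- fit_feature_models(sim$counts, d)
  res <- tidy(fit)
  hit <- sim$truth$feature[sim$truth$template == "const4"]
  expect_true(all(res$padj_treatment[res$feature %in% hit] < 0.01))
  expect_true(all(abs(res$lfc_treatment[res$feature %in% hit] - 4) < 0.5))

  # features with identical counts in every sample (size factors all 1):
  # no signal, p ~ 1
  m_flat <- matrix(rep(c(7, 30, 120, 45, 9), each = 42), nrow = 5,
                   byrow = TRUE, dimnames = list(paste0("f", 1:5), d$sample))
  fit2 <- fit_feature_models(as_feature_table(m_flat), d)
  row1 <- tidy(fit2)[1, ]
  expect_lt(abs(row1$lfc_treatment), 1e-6)
  expect_gt(row1$p_treatment, 0.99)
})

test_that("features observed in under 3 samples are flagged with p = 1", {
  sim <- quick_sim(seed = 6, n_features = 50)
  sparse <- sim$counts
  sparse[1, -1] <- as.list(c(5, rep(0, 41)))
  fit <- fit_feature_models(sparse, generate_design())
  row1 <- tidy(fit)[1, ]
  expect_equal(row1$flag, "low_count")
  expect_equal(row1$p_treatment, 1)
  expect_equal(row1$p_interaction, 1)
})

test_that("model preconditions are enforced", {
  sim <- quick_sim(seed = 7, n_features = 20)
  d <- generate_design()
  frac <- sim$counts
  frac[[2]] <- frac[[2]] + 0.5
  expect_error(fit_feature_models(frac, d), "non-integer")
  only_ctrl <- d[d$condition == "control", ]
  expect_error(
    fit_feature_models(sim$counts[, c("feature", only_ctrl$sample)], only_ctrl),
    "both conditions"
  )
})

test_that("treatment LFCs agree with an independent DESeq2 fit", {
  skip_if_not_installed("DESeq2")
  d <- generate_design()
  templates <- tibble::tibble(template = "const2",
                              time_h = c(1, 12, 24, 48, 96, 168, 240),
                              lfc = rep(2, 7))
  p <- simulation_params(n_features = 80, n_pathways = 5,
                         baseline_log_mean = log(100), baseline_log_sd = 0.5,
                         dispersion = 0.05, library_size_cv = 0.1,
                         affected_fraction = c(const2 = 0.3), seed = 8)
  sim <- generate_counts(d, p, templates = templates)
  fit <- fit_feature_models(sim$counts, d)
  res <- tidy(fit)

  m <- feature_matrix(sim$counts)
  coldata <- data.frame(
    condition = factor(d$condition, levels = c("control", "treatment")),
    time = factor(d$time_h)
  )
  dds <- DESeq2::DESeqDataSetFromMatrix(m, coldata, ~ condition + time + condition:time)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ds <- DESeq2::results(dds, name = "condition_treatment_vs_control")

  keep <- res$base_mean > 50 & res$flag == "ok" & !is.na(ds$log2FoldChange)
  expect_gt(stats::cor(res$lfc_treatment[keep], ds$log2FoldChange[keep]), 0.95)
  # size factors agree with the shared median-of-ratios convention
  expect_equal(unname(fit$size_factors),
               unname(DESeq2::sizeFactors(dds) /
                        exp(mean(log(DESeq2::sizeFactors(dds))))),
               tolerance = 1e-6)
})
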