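test_that("log2FC trajectories match hand arithmetic", {
  d <- toy_design(3, c(1, 12))
  # feature means: treatment 15 vs control 3 at t1 -> log2(16/4) = 2
  m <- matrix(0, 2, 12, dimnames = list(c("f1", "f2"), d$sample))
  ctrl1 <- d$sample[d$condition == "control" & d$time_h == 1]
  trt1 <- d$sample[d$condition == "treatment" & d$time_h == 1]
  ctrl2 <- d$sample[d$condition == "control" & d$time_h == 12]
  trt2 <- d$sample[d$condition == "treatment" & d$time_h == 12]
  m["f1", ctrl1] <- 3; m["f1", trt1] <- 15
  m["f1", ctrl2] <- 7; m["f1", trt2] <- 7 # equal means -> 0
  # f2 all zero at both -> pseudocount-stabilised 0
  traj <- log2fc_trajectories(as_feature_table(m), d)
  expect_equal(traj$t1[traj$feature == "f1"], 2)
  expect_equal(traj$t12[traj$feature == "f1"], 0)
  expect_equal(unlist(traj[traj$feature == "f2", -1]), c(t1 = 0, t12 = 0))

  expect_error(log2fc_trajectories(as_feature_table(m[, -match(trt1, colnames(m))]),
                                   d[!d$sample %in% trt1, ]),
               "missing a condition")
})

test_that("well-separated archetypes are clustered perfectly", {
  set.seed(5)
  base <- rbind(matrix(2, 3, 7), matrix(-2, 3, 7))
  noise <- matrix(rnorm(42, sd = 0.01), 6, 7)
  m <- base + noise
  dimnames(m) <- list(paste0("f", 1:6), paste0("t", c(1, 12, 24, 48, 96, 168, 240)))
  traj <- tibble::as_tibble(cbind(tibble::tibble(feature = rownames(m)),
                                  as.data.frame(m)))
  cl <- cluster_trajectories(traj, k = 2, seed = 1)
  lab <- cl$assignments$cluster
  expect_equal(lab[1:3], rep(lab[1], 3))
  expect_equal(lab[4:6], rep(lab[4], 3))
  expect_true(lab[1] != lab[4])
  expect_equal(unname(cl$medians[, 1]), sort(c(2, -2), decreasing = TRUE),
               tolerance = 0.05)
})

test_that("SSE is the summed squared deviation from the cluster median line", {
  # 5 identical features plus one offset by 0.5 at each of 7 timepoints
  m <- rbind(matrix(1, 5, 7), matrix(1.5, 1, 7),
             matrix(-3, 4, 7))
  dimnames(m) <- list(paste0("f", 1:10), paste0("t", c(1, 12, 24, 48, 96, 168, 240)))
  traj <- tibble::as_tibble(cbind(tibble::tibble(feature = rownames(m)),
                                  as.data.frame(m)))
  cl <- cluster_trajectories(traj, k = 2, seed = 1)
  asg <- cl$assignments
  # median of the 6-member cluster is the 1-line: exact members have SSE 0
  expect_equal(asg$sse[asg$feature %in% paste0("f", 1:5)], rep(0, 5))
  # the 0.5-offset feature: 7 x 0.25 = 1.75 exactly
  expect_equal(asg$sse[asg$feature == "f6"], 1.75)
  expect_equal(asg$sse[asg$feature %in% paste0("f", 7:10)], rep(0, 4))
})

test_that("cluster labels are deterministic and content-based", {
  sim <- quick_sim(seed = 20, n_features = 200,
                   affected = c(early_up_decay = 0.2, late_down = 0.2))
  traj <- log2fc_trajectories(normalize_counts(sim$counts), generate_design())
  cl_a <- cluster_trajectories(traj, k = 4, seed = 1)
  cl_b <- cluster_trajectories(traj, k = 4, seed = 99)
  # same partition recovered regardless of seed-specific initial labels
  expect_gt(mclust::adjustedRandIndex(cl_a$assignments$cluster,
                                      cl_b$assignments$cluster), 0.99)
  # labels ordered by descending size
  expect_true(all(diff(cl_a$sizes) <= 0))
  expect_identical(cluster_trajectories(traj, k = 4, seed = 1), cl_a)
  expect_error(cluster_trajectories(traj, k = 300, seed = 1), "exceeds")
})

test_that("the median line minimises summed absolute deviation per timepoint", {
  sim <- quick_sim(seed = 21, n_features = 150,
                   affected = c(spike_then_crash = 0.3))
  traj <- log2fc_trajectories(normalize_counts(sim$counts), generate_design())
  cl <- cluster_trajectories(traj, k = 3, seed = 2)
  tm <- as.matrix(traj[, -1])
  rownames(tm) <- traj$feature
  for (k in 0:2) {
    members <- tm[cl$assignments$feature[cl$assignments$cluster == k], ,
                  drop = FALSE]
    med <- cl$medians[k + 1, ]
    for (j in seq_len(ncol(tm))) {
      l1_med <- sum(abs(members[, j] - med[j]))
      for (shift in c(-0.05, 0.05)) {
        expect_gte(sum(abs(members[, j] - (med[j] + shift))), l1_med)
      }
    }
  }
})

test_that("significant subsets overlay onto clusters with correct counts", {
  sim <- quick_sim(seed = 22, n_features = 100)
  traj <- log2fc_trajectories(normalize_counts(sim$counts), generate_design())
  cl <- cluster_trajectories(traj, k = 3, seed = 1)
  all_ids <- cl$assignments$feature
  ov <- overlay_subsets(cl, te_features = all_ids, ie_features = character())
  expect_equal(ov$n_te, ov$n)
  expect_equal(ov$n_ie, rep(0L, nrow(ov)))
  expect_warning(
    ov2 <- overlay_subsets(cl, te_features = c(all_ids[1:5], "ghost")),
    "absent")
  expect_equal(sum(ov2$n_te), 5L)
  # disjoint TE/IE supported
  ov3 <- overlay_subsets(cl, all_ids[1:10], all_ids[11:20])
  expect_equal(sum(ov3$n_te), 10L)
  expect_equal(sum(ov3$n_ie), 10L)
})

test_that("taxa correlation selects positive associations only", {
  medians <- rbind(up = c(2, 2.5, 1.5, 0.8, 0.4, 0.1, 0))
  tps <- c(1, 12, 24, 48, 96, 168, 240)
  m <- rbind(match_up = medians["up", ],
             inverse = -medians["up", ],
             flat = rep(0.3, 7))
  colnames(m) <- paste0("t", tps)
  traj <- tibble::as_tibble(cbind(tibble::tibble(feature = rownames(m)),
                                  as.data.frame(m)))
  corr <- correlate_taxa(traj, medians)
  expect_equal(corr$r[corr$otu == "match_up"], 1, tolerance = 1e-9)
  expect_true(corr$selected[corr$otu == "match_up"])
  expect_equal(corr$r[corr$otu == "inverse"], -1, tolerance = 1e-9)
  expect_false(corr$selected[corr$otu == "inverse"])
  expect_equal(corr$flag[corr$otu == "flat"], "zero_variance")
  expect_true(is.na(corr$r[corr$otu == "flat"]))
})
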