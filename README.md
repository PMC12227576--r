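# wwsignal

Detecting treated-wastewater perturbation signals in mesocosm community
metatranscriptomes.

Treated wastewater (TWW) discharged into rivers still carries residual
chemicals and nutrient loads. A sensitive way to detect its ecological
footprint is the community metatranscriptome: which genes the resident
microbes are actively expressing. `wwsignal` implements the downstream
statistics for the standard mesocosm exposure design — three control and
three treatment flume systems sampled at 1, 12, 24, 48, 96, 168 and 240 h
(42 samples), profiled as KEGG-ortholog (KO) and KEGG-pathway count
tables:

* **Signal-to-noise ratio (SNR) on beta diversity.** At each timepoint,
  Bray-Curtis dissimilarities are split into control–control (CC,
  replicate noise) and control–treatment (CT, signal) pairs and

  `SNR(t) = mean(CT distances) / mean(CC distances)`.

  SNR > 1 means the treatment signal exceeds replicate noise. CC vs CT is
  tested with a Welch t-test and an exact Mann-Whitney test (BH-adjusted
  across timepoints), plus pairwise PERMANOVA (pseudo-F, seeded or
  exhaustive permutations).
* **Negative-binomial differential abundance** under
  `~ condition + time + condition:time` (median-of-ratios size factors,
  per-feature method-of-moments dispersions, Wald test for the treatment
  effect, likelihood-ratio test for the interaction, BH per contrast).
  Filtering a table down to its significant features ("SMTTO/SMTTP"-style
  subsets) sharpens the SNR signal.
* **Trajectory clustering.** Per-timepoint log2 fold-change trajectories
  are clustered with k-means; clusters are characterised by per-timepoint
  median lines and per-feature SSE, significant subsets are overlaid, and
  OTU trajectories can be correlated against cluster medians (positive
  Pearson association, p < 0.05).
* **Hypergeometric pathway enrichment** per timepoint and direction:
  candidate KOs need fold change >= 2, detection in >= 10% of one group's
  samples and presence in both groups; pathways are tested with the exact
  upper-tail hypergeometric probability against the all-KO background
  (raw p < 0.01).
* **A synthetic mesocosm generator** (negative-binomial counts, lognormal
  baselines and library factors, temporal effect archetypes, KO-pathway
  maps, OTU tables) with known ground truth, so every stage is testable
  without any external data.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()` / `glance()` / `augment()` methods and result types have
`autoplot()` methods.

## Worked example

Simulate a perturbed mesocosm (800 KOs, 10% carrying temporal effect
archetypes), test for treatment effects, and compare the SNR time course
before and after significance filtering:

```r
library(wwsignal)

design <- generate_design()            # 3+3 tanks x 7 timepoints, 42 samples
params <- simulation_params(
  n_features = 800, n_pathways = 80,
  affected_fraction = c(early_up_decay = 0.04, spike_then_crash = 0.03,
                        dip_recover = 0.03),
  seed = 42
)
sim <- generate_counts(design, params)

fit <- fit_feature_models(sim$counts, design)
fit
#> Negative-binomial differential abundance fit
#>   design: ~ condition + time + condition:time
#>   800 features, 42 samples
#>   treatment padj < 0.05: 18
#>   interaction padj < 0.05: 39

smtto <- filter_significant(fit, "treatment")
norm  <- normalize_counts(prevalence_filter(sim$counts))

snr_timecourse(norm, design)[, c("time_h", "snr", "padj_t")]
#>   time_h   snr padj_t
#> 1      1 1.136  0.219
#> 2     12 1.109  0.054
#> 3     24 1.152  0.302
#> 4     48 1.026  0.546
#> 5     96 0.971  0.677
#> 6    168 0.957  0.219
#> 7    240 1.005  0.890

snr_timecourse(norm[norm$feature %in% smtto, ], design)[, c("time_h", "snr", "padj_t")]
#>   time_h  snr  padj_t
#> 1      1 1.99 0.00740
#> 2     12 3.12 0.00619
#> 3     24 1.27 0.32282
#> 4     48 1.27 0.12502
#> 5     96 1.18 0.32282
#> 6    168 1.18 0.32282
#> 7    240 1.04 0.79153
```

The unfiltered table shows only a weak, non-significant excess of
control–treatment dissimilarity, while restricting to the 18
treatment-significant features lifts the early SNR to 2–3 with BH-adjusted
p < 0.01 — the treatment signal is concentrated in the responding
features, and both curves relax back toward 1 as the community adapts.
Clustering the trajectories recovers the injected temporal shapes:

```r
traj <- log2fc_trajectories(norm, design)
cl <- cluster_trajectories(traj, k = 6, seed = 42)
tidy(cl)
#>   cluster size    t1    t12    t24   t48    t96   t168  t240
#> 1       0  189 -0.16 -0.340 -0.129  0.54  0.228  0.315 -0.23
#> 2       1  171  0.31 -0.090  0.035 -0.34 -0.069 -0.568 -0.44
#> 3       2  165 -0.57  0.337 -0.127  0.19 -0.550 -0.113  0.23
#> 4       3  146  0.05 -0.036  0.625 -0.29  0.266  0.168  0.61
#> 5       4   94  0.22  0.110 -1.529 -0.60 -0.224  0.031  0.10
#> 6       5   35  1.99  2.171  1.337  0.81  0.243  0.132 -0.12
```

Cluster 5's median line starts at +2, peaks at 12 h and decays to zero —
the injected early-induction archetype — while cluster 4 captures the
24-h crash pattern. `autoplot(cl, traj)` draws the member lines coloured
by SSE with the median line in black; `autoplot()` on an SNR time course
draws the SNR trend with significant timepoints filled.

The full pipeline (simulate → aggregate → differential abundance → SNR →
clustering → enrichment, with TSV artifacts and a JSON run manifest) is
one call:

```r
run_pipeline(default_pipeline_config(seed = 1), outdir = "out")
```

or from a shell via the thin wrapper
`inst/scripts/wwsignal-pipeline.R --outdir out --seed 1`.

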