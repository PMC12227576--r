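---
title: "Methods: detecting treated-wastewater signals in mesocosm metatranscriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting treated-wastewater signals in mesocosm metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Treated wastewater (TWW) released into rivers still carries residual
chemicals and nutrient loads, and detecting its ecological footprint is a
core water-quality question. A sensitive readout is the community
metatranscriptome: which genes the resident microbial community (here,
protists in river-water mesocosms) is actively expressing. `wwsignal`
implements the downstream statistics for a mesocosm exposure design: three
control and three treatment flume systems, sampled at 1, 12, 24, 48, 96, 168
and 240 hours after exposure (42 samples), profiled as counts of KEGG
orthologs (KOs) that aggregate into KEGG pathways.

The package answers three questions:

1. **Is there a treatment signal at all, and when?** — the signal-to-noise
   ratio (SNR) on Bray-Curtis dissimilarities, supported by Welch t,
   exact Mann-Whitney and PERMANOVA tests.
2. **Which functions drive it, and how do they move over time?** —
   negative-binomial differential abundance under a treatment-by-time
   design, and k-means clustering of per-timepoint log2 fold-change
   trajectories.
3. **Which pathways are over-represented among responding KOs?** —
   per-timepoint hypergeometric enrichment.

Because the raw sequencing study behind this design is processed on cluster
hardware, the package ships a synthetic mesocosm generator with known ground
truth; every statistical property claimed here is demonstrated on that
generator by the test suite and `scripts/acceptance.R`.

# Signal-to-noise ratio on beta diversity

At each timepoint the Bray-Curtis dissimilarities
$d(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)$ between samples are split
into control-control pairs (CC, replicate noise; $\binom{3}{2} = 3$ values)
and control-treatment pairs (CT, signal; $3 \times 3 = 9$ values).
The statistic is

$$\mathrm{SNR}(t) = \frac{\overline{d}_{CT}(t)}{\overline{d}_{CC}(t)},$$

with arithmetic means (a median variant is available via `summary =
"median"`). SNR > 1 means the treatment arm is farther from the controls
than the controls are from one another; SNR < 1 is meaningful too — the
control signal is the stronger one. CC and CT sets are compared with a
two-sided Welch t-test (unequal variances, since 3 vs 9 values) and an
exact two-sided Mann-Whitney test; p-values are BH-adjusted across the
seven timepoints of a dataset, matching a per-dataset trend display.
`permanova_pairwise()` provides the conventional pseudo-F permutation test
on the same distances, including an exhaustive-enumeration mode for the
$\binom{6}{3} = 20$ label splits of a 3-vs-3 design.

**Caveat.** The 3 CC and 9 CT distances at a timepoint share the same six
samples and are therefore not independent observations; the tests are
reported in the conventional way, but their p-values should be read as
descriptive. The exhaustive PERMANOVA p cannot go below 1/10 on this design.

Distances are computed on size-factor-normalized counts after a
prevalence filter that removes features detected in fewer than 2 of the 42
samples (the filter is dataset-wide, applied once before any distance
computation, and is idempotent).

**Significance filtering.** Restricting the table to features whose
BH-adjusted treatment-contrast p-value is below 0.05 (the "SMTTO/SMTTP"
style subset) concentrates the treatment signal; on synthetic data with 10%
affected features this raises the SNR in the affected window in essentially
every replicate, which is the package's qualitative reproduction of the
filtered-versus-unfiltered finding.

# Differential abundance

Counts are normalized by median-of-ratios size factors: for sample $j$,
$s_j = \mathrm{median}_f \, c_{fj} / (\prod_{j'} c_{fj'})^{1/n}$ over the
reference features that are nonzero in every sample, rescaled so the
factors have geometric mean 1. If no reference feature exists, geometric
means over positive counts are used, with a warning.

Each feature is fit with a negative-binomial GLM (log link, offset
$\log s_j$) under `~ condition + time + condition:time`, time a categorical
factor:

* **Dispersion** $\phi$ (variance $= \mu + \phi\mu^2$) is a per-feature
  method-of-moments estimate pooled over condition-by-time cells, floored
  at $10^{-8}$ and capped at 10. The contract is FDR calibration on
  synthetic data, not numerical identity with any particular reference
  implementation; the test suite cross-checks LFC estimates against an
  independent DESeq2 fit on a small fixture.
* **Treatment effect**: Wald test on the treatment coefficient, reported on
  the log2 scale. With an interaction present this coefficient is the
  treatment effect *at the reference (first) timepoint*; trajectory-resolved
  effects live in the trajectory module.
* **Interaction**: likelihood-ratio test of the full model against
  `~ condition + time` ($\chi^2$, 6 df on the 7-timepoint design). An LRT is
  used because "the interaction" spans six coefficients, not one.
* BH adjustment is applied separately per contrast across features.
  Features with nonzero counts in fewer than 3 samples are flagged
  `low_count` and assigned p = 1 rather than fit.

**Known limitation — composition bias.** Median-of-ratios normalization
assumes most features are unchanged. When a large, one-sided fraction of
features responds (e.g. 30% all up-shifted), size factors absorb part of
the shift and LFCs are compressed toward zero — an inherent property of
this normalization, visible in the generator because truth is known. At the
10% affected fraction used throughout, recovery of a true log2FC of 2 is
within ±0.25.

# Trajectory clustering

Per-timepoint log2 fold changes are
$\log_2\!\big((\bar{x}_{T,t} + 1)/(\bar{x}_{C,t} + 1)\big)$ on normalized
counts; the pseudocount of 1 stabilises zeros (two all-zero groups give
exactly 0). Features are clustered by k-means on the raw, unscaled log2FC
vectors — cluster identity is defined by absolute effect magnitude, so
standardising rows would destroy exactly the structure of interest.

Numerical choices:

* Lloyd's algorithm with ≥ 10 random restarts at a fixed seed (base R's
  k-means; the restart ensemble makes initialisation immaterial in
  practice — label agreement across seeds is checked by test).
* Labels are renumbered 0..K-1 deterministically by descending cluster
  size, ties broken by the median-line content, so labels are reproducible
  and independent of the seed-specific initial numbering.
* Defaults K = 6 for orthologs and K = 7 for pathways, following the
  observed cluster inventories (ortholog clusters labelled 0-5 and a
  pathway cluster 6); both are configurable.
* Each cluster is characterised by its per-timepoint **median** line (which
  minimises summed absolute deviation, checked per timepoint by test), and
  each member by its SSE — the sum over timepoints of squared deviations
  from that line. A feature deviating by 0.5 at each of 7 timepoints has
  SSE $7 \times 0.25 = 1.75$ exactly.

Significant subsets (treatment-effect and interaction-effect features from
the differential-abundance stage) are overlaid per cluster with
`overlay_subsets()`. OTU log2FC trajectories are correlated against cluster
median lines (Pearson, two-sided t-based p with $T - 2 = 5$ df); an OTU is
selected for a cluster only if $r > 0$ and $p < 0.05$ — positive
association only, since the question is which taxa *drive* a cluster.
The correlation targets the median line; a mean-line option exists.

# Pathway enrichment

At each timepoint, candidate KOs must (i) have $|\log_2\mathrm{FC}| \ge 1$
(fold change ≥ 2) between group means (pseudocount 1), (ii) be detected in
at least 10% of the samples of at least one group, and (iii) have nonzero
total counts in both groups. Positive log2FC puts a KO in the treatment
set, negative in the control set; swapping condition labels swaps the sets
exactly. With 3 replicates per group the 10% occurrence rule degenerates to
"at least one sample" — the threshold is kept configurable and this
degeneracy is deliberate, mirroring the stated rule rather than
strengthening it.

Each pathway with at least one background KO is tested with the exact
upper-tail hypergeometric probability $P(X \ge x)$ for $x$ of the $n$
test-set KOs falling among the $K$ pathway KOs in a background of $N$ (the
union of all KOs identified anywhere in the dataset). Enrichment uses a raw
p < 0.01 rule, with no multiplicity correction — the conventional screening
threshold for this analysis. `enrichment_timecourse()` assembles the
pathway-by-(direction × timepoint) incidence matrix with `"*"` markers.

# The synthetic mesocosm generator

The generator emulates the study conditions so that every stage is testable
with known truth:

* **Design**: 3 control + 3 treatment tanks × 7 timepoints = 42 samples,
  ids `C1_S1 … T3_S7`.
* **Counts**: feature baselines $\mu_f \sim \mathrm{logNormal}(3, 1.5)$
  (median ≈ 20 counts, heavy right tail); per-sample library factors
  lognormal with CV 0.15 (reflecting the modest spread of per-sample
  sequencing depth in such experiments); counts negative-binomial with
  dispersion $\phi = 0.3$ (a realistic replicate-level overdispersion for
  environmental metatranscriptomes), variance $\mu + \phi\mu^2$. The
  treatment-arm mean at time $t$ is $\mu_f \cdot 2^{\mathrm{lfc}(t)}$.
* **Effects**: six named archetypes (defined pointwise at the seven design
  hours, no interpolation — the design only observes those hours): an early
  ~4x induction peaking at 12 h and decaying to zero, an early repression
  recovering to zero, late-onset responses in both directions, an induction
  followed by a crash below one-fourth of control around 24 h, and a
  transient dip. The default perturbed scenario assigns 10% of features to
  archetypes.
* **Scale**: defaults of 5,500 KOs mapping to 250 pathways (map degree a
  shifted Poisson with mean 1.6, so every simulated KO has ≥ 1 pathway).
* **OTU tables** for taxa-correlation testing tie affected OTUs to supplied
  cluster median trajectories.

Identical seeds give bit-identical tables. What the generator does *not*
emulate: phylogenetic or co-expression correlation between features,
compositional coupling beyond library size, zero inflation beyond the NB,
taxon-specific annotation bias, or assembly/annotation noise. Passing tests
therefore demonstrate statistical correctness and calibration of the
methods under a realistic count model — not that any particular real
dataset will behave identically.

# Problem sizes used by the checks

The test suite and acceptance script run at reduced table sizes chosen as a
package decision to keep the checks quick while leaving every rate estimate
well-resolved: 600-feature tables for the 200-run null SNR calibration,
800-feature tables for the 50-replicate detection/filtering scenario,
2,000-feature null and 300-feature power scenarios for the
differential-abundance calibration, and 200-feature trajectory sets for
cluster recovery. The pipeline's own defaults remain at study scale.

# Reading the outputs

`run_pipeline()` writes TSVs for every stage plus a JSON manifest recording
seeds, thresholds, effective K values and skipped timepoints (e.g. a
timepoint left with fewer than two control replicates after exclusions is
recorded with its reason rather than failing the run). Reruns with the same
configuration are bit-identical apart from the manifest timestamp.
`autoplot()` methods cover the SNR trend and the cluster panels;
`plot_distance_partitions()` gives the CC/CT bar view.
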