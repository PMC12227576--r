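# Small in-code fixtures shared across tests.

# tiny feature table from a matrix literal
tiny_table <- function(values, features = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(features)) features <- paste0("f", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  as_feature_table(m)
}

# metadata for an ad-hoc set of columns: condition inferred from the C/T
# prefix, timepoint from the _S<idx> suffix over `timepoints_h`
toy_design <- function(tanks_per_arm = 3, timepoints_h = c(1, 12)) {
  generate_design(tanks_per_arm, timepoints_h)
}

# a quick simulated dataset at reduced scale
quick_sim <- function(seed = 1, n_features = 300, dispersion = 0.3,
                      affected = numeric(0),
                      design = generate_design(),
                      templates = NULL) {
  params <- simulation_params(
    n_features = n_features,
    n_pathways = max(5L, n_features %/% 12L),
    dispersion = dispersion,
    affected_fraction = affected,
    seed = seed
  )
  generate_counts(design, params, templates = templates)
}

# brute-force upper-tail hypergeometric by binomial-coefficient enumeration
# (independent of phyper)
hyper_upper_enum <- function(x, K, n, N) {
  if (x == 0) return(1)
  i <- x:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
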