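# toy builders shared across test files

# a som_model with explicit codebook / bmu, bypassing training
toy_model <- function(codebook, grid, bmu = NULL) {
  if (is.null(colnames(codebook))) {
    colnames(codebook) <- paste0("s", seq_len(ncol(codebook)))
  }
  if (is.null(bmu)) {
    bmu <- stats::setNames(seq_len(nrow(codebook)),
                           paste0("g", seq_len(nrow(codebook))))
  }
  structure(list(grid = as.integer(grid), codebook = codebook, bmu = bmu,
                 energy = numeric(0), training_meta = list()),
            class = "som_model")
}

random_expression <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 8), n_genes, n_samples)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  m
}

# sort-average-unsort quantile normalization oracle (tie-free inputs)
qn_oracle <- function(m) {
  mu <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) mu[rank(x)])
  dimnames(out) <- dimnames(m)
  out
}

# one-sided enrichment p by explicit hypergeometric enumeration with choose()
fisher_oracle <- function(k, spot, set, universe) {
  i <- seq(k, min(spot, set))
  sum(choose(set, i) * choose(universe - set, spot - i)) / choose(universe, spot)
}

# small simulated cohort reused by several structural tests
small_sim <- function(seed = 1) {
  cfg <- sim_config(n_genes = 600, n_modules = 6, module_size = 12,
                    n_controls = 6, n_cap = 60, seed = seed)
  simulate_cap_cohort(cfg)
}
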