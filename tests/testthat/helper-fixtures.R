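# Shared fixtures, all built in code at test time.

tiny_truth <- function(seed = 1, n_targets = 4, n_genes = 60, ...) {
  generate_ground_truth(n_targets, 11, n_genes, seed = seed, ...)
}

tiny_panel <- function(truth = tiny_truth(), n_drugs = 8, n_cells = 30,
                       noise_sd = 0.1, seed = 2, ...) {
  generate_panel(truth, n_drugs, n_cells, noise_sd = noise_sd,
                 seed = seed, ...)
}

# Interaction matrix with a structured similarity pattern: T2 tracks T1
# (similarity near +1), T4 mirrors T3 (near -1), remaining rows are
# independent, so |true similarity| > 0.7 holds for exactly those pairs.
structured_interactions <- function(seed = 1, n_extra = 2,
                                    pathways = default_pathways()) {
  set.seed(seed)
  K <- length(pathways)
  base1 <- rnorm(K); base3 <- rnorm(K)
  rows <- rbind(T1 = base1,
                T2 = base1 + rnorm(K, sd = 0.15),
                T3 = base3,
                T4 = -base3 + rnorm(K, sd = 0.15))
  if (n_extra > 0) {
    extra <- matrix(rnorm(n_extra * K), n_extra,
                    dimnames = list(sprintf("X%d", seq_len(n_extra)), NULL))
    rows <- rbind(rows, extra)
  }
  colnames(rows) <- pathways
  structure(rows, orientation = "sensitivity", tissue_label = "synthetic",
            class = c("interaction_matrix", "matrix", "array"))
}

# Observed sham (self-combination) surface: viability of the single drug
# at total dose d1 + d2, plus optional multiplicative assay noise.
sham_observed_surface <- function(curve, doses, noise_sd = 0, seed = 1) {
  set.seed(seed)
  d <- sort(unique(c(0, doses)))
  V <- outer(d, d, function(a, b) hill_viability(curve, a + b))
  V <- V + matrix(rnorm(length(V), sd = noise_sd), nrow(V))
  dose_surface(d, d, pmin(pmax(V, 0), 1.5))
}

# Plain named values of a delta_pa_scores object (drops class/provenance).
dpv <- function(x) setNames(as.numeric(x), names(x))

# Brute-force Pearson of two vectors (independent oracle used in several
# oracle-equivalence tests).
pearson_loop <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}
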