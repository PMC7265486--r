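# Permutation null models for both workflows, empirical two-tailed
# p-values, count-ratio Bayes factors, and FDR pass flags.

permutation_result <- function(observed_r, null_rs, B, seed, tail) {
  structure(list(observed_r = observed_r, null_rs = null_rs,
                 p_two_tailed = empirical_p(observed_r, null_rs, tail),
                 bayes_factor = bayes_factor(observed_r, null_rs),
                 B = B, seed = seed, tail = tail),
            class = "permutation_result")
}

#' Permutation null for the prioritization workflow
#'
#' Shuffles the aggregated synergy values across target pairs B times,
#' recomputing the Pearson correlation of |similarity| with synergy each
#' time, to build a null distribution of no synergy.
#'
#' @param sim_values named (by pair) or plain vector of functional
#'   similarities per target pair.
#' @param observed_pair_synergy synergy values aligned with `sim_values`
#'   (>= 3 pairs).
#' @param B number of permutations.
#' @param seed integer seed.
#' @param tail `"minmax"` (2 min(tails)/B) or `"abs"` (|null| >= |obs|).
#' @return a `permutation_result`: `observed_r`, `null_rs`,
#'   `p_two_tailed`, `bayes_factor`, `B`, `seed`.
#' @export
permute_pair_labels <- function(sim_values, observed_pair_synergy,
                                B = 1000L, seed = 1L,
                                tail = c("minmax", "abs")) {
  tail <- match.arg(tail)
  stop_if_not(length(sim_values) == length(observed_pair_synergy),
              "similarity and synergy vectors must align")
  stop_if_not(length(sim_values) >= 3L, "need >= 3 pairs")
  stop_if_not(is_count(B), "B must be >= 1")
  a <- abs(sim_values)
  obs <- cor(a, observed_pair_synergy)
  set.seed(as.integer(seed))
  null_rs <- vapply(seq_len(B), function(b)
    cor(a, sample(observed_pair_synergy)), numeric(1))
  permutation_result(obs, null_rs, B, as.integer(seed), tail)
}

#' Permutation null for the stratification workflow
#'
#' Within each drug combination independently, the cell labels of the
#' observed synergy records are shuffled; per-cell means are recomputed
#' and correlated with the per-cell predictions each iteration.
#'
#' @param predicted_per_cell named per-cell predicted synergy (Delta PA).
#' @param records synergy records (`drug1`, `drug2`, `cell`, `synergy`);
#'   every combination needs >= 2 cells.
#' @inheritParams permute_pair_labels
#' @return a `permutation_result`.
#' @export
permute_cell_labels <- function(predicted_per_cell, records, B = 1000L,
                                seed = 1L, tail = c("minmax", "abs")) {
  tail <- match.arg(tail)
  stop_if_not(is_count(B), "B must be >= 1")
  combo <- paste(records$drug1, records$drug2)
  sizes <- tapply(records$cell, combo, function(x) length(unique(x)))
  stop_if_not(all(sizes >= 2L), "every drug combination needs >= 2 cells")
  per_cell <- function(cells, syn) {
    vapply(split(syn, cells), mean, numeric(1))
  }
  align_r <- function(obs_means) {
    shared <- intersect(names(obs_means), names(predicted_per_cell))
    cor(predicted_per_cell[shared], obs_means[shared])
  }
  obs <- align_r(per_cell(records$cell, records$synergy))
  idx <- split(seq_len(nrow(records)), combo)
  set.seed(as.integer(seed))
  null_rs <- vapply(seq_len(B), function(b) {
    cells_perm <- records$cell
    for (rows in idx) cells_perm[rows] <- records$cell[sample(rows)]
    align_r(per_cell(cells_perm, records$synergy))
  }, numeric(1))
  permutation_result(obs, null_rs, B, as.integer(seed), tail)
}

#' Empirical two-tailed permutation p-value
#'
#' `"minmax"`: p = 2 min(#\{null >= obs\}, #\{null <= obs\}) / B, capped
#' at 1. `"abs"`: p = #\{|null| >= |obs|\} / B. No +1 smoothing is
#' applied, so p = 0 is reachable when the observed statistic beats every
#' null draw.
#'
#' @param observed_r observed statistic.
#' @param null_rs permutation null draws.
#' @param tail estimator variant.
#' @return p between 0 and 1.
#' @export
empirical_p <- function(observed_r, null_rs, tail = c("minmax", "abs")) {
  tail <- match.arg(tail)
  stop_if_not(length(null_rs) > 0, "empty null distribution")
  B <- length(null_rs)
  if (tail == "minmax") {
    p <- 2 * min(sum(null_rs >= observed_r), sum(null_rs <= observed_r)) / B
    min(p, 1)
  } else {
    sum(abs(null_rs) >= abs(observed_r)) / B
  }
}

#' Count-ratio Bayes factor against the permutation null
#'
#' BF = #\{null < observed\} / max(1, #\{null >= observed\}): the ratio of
#' null draws the observed statistic beats to those it does not, with a
#' floor of 1 in the denominator (so the printed ceiling at B = 1000 is
#' 999 when one draw is not beaten, and 1000 when none is). Ties count as
#' not beaten.
#'
#' @inheritParams empirical_p
#' @return BF >= 0.
#' @export
bayes_factor <- function(observed_r, null_rs) {
  stop_if_not(length(null_rs) > 0, "empty null distribution")
  n_better <- sum(null_rs < observed_r)
  n_better / max(1, length(null_rs) - n_better)
}

#' Benjamini-Hochberg FDR pass flags
#'
#' @param pvals p-values between 0 and 1.
#' @param q FDR level (default 25%).
#' @return data.frame with `p`, `p_adjusted` (BH) and `pass`
#'   (`p_adjusted <= q`).
#' @export
fdr_flags <- function(pvals, q = 0.25) {
  stop_if_not(all(pvals >= 0 & pvals <= 1), "p-values must be in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  data.frame(p = pvals, p_adjusted = adj, pass = adj <= q)
}
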