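# synstrat

Prioritize drug combinations and stratify cancer cell lines for synergy
using **monotherapy data only**: basal gene expression, single-drug
response (log IC50) and nominal drug-target annotation. No combination
screening data is needed to rank candidate combinations; a small amount
is used only to pick group sizes when stratifying.

## Who this is for

Computational pharmacology groups running (or mining) large monotherapy
screens (GDSC-style: hundreds of cell lines x hundreds of drugs) who want
to (a) decide *which* drug pairs are worth putting on a combination
screen, and (b) for a pair already known to be synergistic, predict *which*
cell lines (ultimately patients) will respond.

## The method

1. **Pathway activities.** Expression is collapsed to 11 signaling-pathway
   activity scores (EGFR, NFkB, TGFb, MAPK, p53, TNFa, PI3K, VEGF,
   Hypoxia, Trail, JAK-STAT) by multiplying the expression matrix with a
   perturbation-derived gene weight matrix (footprint scoring):
   `A = t(E) W`.
2. **Interaction matrix.** A Bayesian matrix factorization with side
   information (Gibbs-sampled; drug side = binary target annotation
   `X_D`, cell side = pathway activities `X_C`) models observed response
   `y_ij ~ N(u_i' v_j, 1/tau)` with
   `u_i ~ N(mu_u + beta_D' x_i, Lambda_u^-1)` and symmetrically for cells.
   The posterior mean of `beta_D beta_C'` over 600 Gibbs samples, averaged
   over 40 independent chains, is the **targets x pathways interaction
   matrix**: a positive entry means activation of that pathway associates
   with sensitivity when targeting that protein (IC50 input is negated at
   extraction so this orientation always holds).
3. **Target functional similarity.** For two targets, the Pearson
   correlation of their interaction rows across the 11 pathways. Pairs
   with |similarity| > 0.7 — functionally near-identical or
   near-opposite proteins — are the synergy candidates; pairs near 0
   rarely synergize.
4. **Delta Pathway Activity (Delta PA) stratification.** For a
   known-synergistic pair, per-cell predicted synergy is
   `mean(top-N sensitive pathway activities) - mean(top-M resistant) +/- genomics`
   (Model 1, similar targets; Model 2 swaps the two means for opposite
   targets, maximizing the resistance context), with N, M in 1..3 chosen
   by leave-one-out cross-validation and binary mutation/CNV indicators
   added with literature-assigned signs.
5. **Significance.** Permutation nulls (shuffling combination labels, or
   cell labels within each combination), two-tailed empirical p
   (`2*min(tails)/B`), a count-ratio Bayes factor (beaten null draws over
   unbeaten, ceiling 999 at B = 1000), and Benjamini-Hochberg flags at
   FDR < 25%.
6. **Loewe scoring.** Raw 5x5 dose-response matrices are scored as
   100 x mean(expected - observed viability) over interior cells, where
   the expected surface solves the Loewe dose-equivalence index
   `d1/D1(E) + d2/D2(E) = 1` from the two fitted monotherapy Hill curves.

A synthetic-data generator with known ground truth (interaction matrix,
pathway weights, Delta PA spec) makes the whole pipeline testable offline.

## Worked example

```r
library(synstrat)

truth <- generate_ground_truth(n_targets = 6, seed = 1)
panel <- generate_panel(truth, n_drugs = 18, n_cells = 60, noise_sd = 0.3, seed = 2)
pa    <- score_pathways(panel$expression, truth$pathway_weights_true, standardize = TRUE)

cfg <- macau_config(L = 8, n_burnin = 100, n_samples = 300, n_repeats = 4, seed = 3)
I   <- averaged_interactions(panel$response, panel$target_annotation, unclass(pa), cfg)
cor(as.vector(unclass(I)), as.vector(truth$interaction_true))
#> 0.906                      # recovered the generating interaction matrix

S <- similarity_matrix(I)
head(prioritize_pairs(S, threshold = 0.7), 3)
#>   target1 target2 similarity abs_similarity  pearson_p passes_threshold
#> 1     T02     T06 -0.735          0.735        0.00998             TRUE
#> 2     T01     T05 -0.585          0.585        0.0586             FALSE
#> 3     T03     T04 -0.486          0.486        0.130              FALSE
```

T02/T06 is the one pair whose |similarity| clears the 0.7 prioritization
threshold (its p-value from the t distribution on 9 df is shown for
context; ranking uses |similarity|). Stratifying a known-synergistic pair
and testing significance:

```r
pair <- c("T01", "T02")
rk   <- rank_pathways(I, pair, mechanism = truth$model_spec_true$mechanism)
recs <- generate_synergy_labels(truth, panel, pair, noise_sd = 5, seed = 4)
obs  <- aggregate_observed_synergy(recs, "per_cell_mean")
sel  <- select_group_sizes_loocv(rk, pa, panel$genomics, obs)
c(sel$n_sensitive, sel$m_resistant, sel$loocv_r)
#> 1 1 0.981                  # chosen group sizes and LOOCV correlation

sig <- permute_cell_labels(sel$predictions, recs, B = 1000, seed = 5)
c(sig$observed_r, sig$p_two_tailed, sig$bayes_factor)
#> 0.981 0 1000               # beats every one of 1000 null shuffles
```

## Command line

Every stage is exposed as a subcommand of `synstrat_cli()` (TSV in/out,
row labels in the first column):

```sh
Rscript -e 'synstrat::synstrat_cli()' simulate --out panel/ --seed 1
Rscript -e 'synstrat::synstrat_cli()' score-pathways --expression panel/expression.tsv \
    --weights weights.tsv --standardize on --out pa.tsv
Rscript -e 'synstrat::synstrat_cli()' fit --response panel/response.tsv \
    --drug-targets panel/targets.tsv --cell-activities pa.tsv \
    --config cfg.json --out fit/
Rscript -e 'synstrat::synstrat_cli()' similarity --interactions fit/interactions.tsv --out sim.tsv
Rscript -e 'synstrat::synstrat_cli()' prioritize --similarity sim.tsv --threshold 0.7 --out pairs.tsv
Rscript -e 'synstrat::synstrat_cli()' stratify --interactions fit/interactions.tsv \
    --activities pa.tsv --pair T01,T02 --mechanism auto --combos panel/combos.tsv --out strat
Rscript -e 'synstrat::synstrat_cli()' significance --mode cells \
    --predicted strat_predictions.tsv --combos panel/combos.tsv --B 1000 --seed 1 --out sig.json
Rscript -e 'synstrat::synstrat_cli()' synergy-score --combo-matrix combos_long.tsv --out scores.tsv
```

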