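---
title: "Predicting and stratifying drug synergy from monotherapy response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and stratifying drug synergy from monotherapy response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synstrat)
```

# The problem

The space of pairwise drug combinations grows quadratically while
combination screens remain small, sparse and biased toward well-known
biology. Monotherapy screens, in contrast, cover hundreds of drugs by
hundreds of characterized cancer cell lines. `synstrat` implements a
two-workflow methodology built entirely on monotherapy data:

* **Prioritization** — rank untested target pairs by how likely a
  combination hitting them is to synergize, with no combination data at
  all.
* **Stratification** — for a target pair already known to synergize,
  predict which cell lines will respond, using pathway activities and
  mutation/CNV status.

The hinge between the two is the **target functional similarity**: two
proteins whose inhibition responds to the signaling context in the same
way (similarity near +1) are likely in the same pathway, and combinations
against them can synergize by double-hitting that pathway; proteins with
opposite response profiles (near −1) offer an escape-blocking synergy;
profiles near 0 rarely synergize either way.

# Model and assumptions

## Pathway activities (footprint scoring)

Expression is reduced to 11 pathway activity scores (EGFR, NFkB, TGFb,
MAPK, p53, TNFa, PI3K, VEGF, Hypoxia, Trail, JAK-STAT) by multiplying the
genes × samples matrix with a genes × pathways weight matrix:
`A = t(E) W` over the shared gene set (`score_pathways()`). Weights are
*perturbation-derived*: `fit_progeny_weights()` regresses per-gene
perturbation z-scores (`perturbation_zscores()`, two-group pooled-sd
estimator) on a signed experiment × pathway design and keeps, per
pathway, the `top_k` genes by |t| — genes outside a pathway's signature
have weight exactly 0. The assumption inherited from footprint methods is
that response genes, not pathway members, carry the activity signal.

Z-scores use the pooled two-group standard deviation; the estimator is a
documented choice, since only "z-scores of perturbed minus control" is
specified by the method family. Genes with zero pooled sd score z = 0
with a warning rather than NaN.

## Factorization with side information

Observed response (log IC50), drugs × cells, is modelled as

$$y_{ij} \sim N(u_i^\top v_j,\ \tau^{-1}), \qquad
  u_i \sim N(\mu_u + \beta_D^\top x^{drug}_i,\ \Lambda_u^{-1}), \qquad
  v_j \sim N(\mu_v + \beta_C^\top x^{cell}_j,\ \Lambda_v^{-1}),$$

with normal–Wishart hyperpriors on each (μ, Λ), a zero-mean Gaussian
prior with precision `link_prior_precision` on every link-matrix entry,
and an optional Gamma prior on τ. All conditionals are conjugate and the
chain is plain Gibbs; link matrices are drawn from their exact
matrix-normal conditional because the feature dimensions here (tens of
targets, 11 pathways) never justify the conjugate-gradient
noise-injection sampler used by large-scale implementations of this model
family — the sampled distribution is identical.

The **interaction matrix** is the posterior mean of
$\beta_D \beta_C^\top$ (targets × pathways), averaged over collected
samples and then over independent chains (`averaged_interactions()`).
**Orientation contract:** when the response is IC50 (higher = resistant)
the product is negated at extraction, so a positive entry always reads
"activation of this pathway associates with sensitivity when targeting
this protein". Every downstream consumer relies on this flag instead of
guessing.

Assumptions worth stating: response is approximately linear in the latent
factors after per-drug standardization; missing entries are missing at
random (handled by conditioning each latent update on observed cells
only — no imputation); drug targets and pathway activities carry enough
signal that the link matrices are identified.

## Functional similarity and prioritization

`functional_similarity()` is the Pearson correlation of two targets' 11
interaction values, with a two-sided p from the t distribution on
`n_pathways − 2` df (reported for context; ranking uses |r| only, so no
multiple-testing correction is applied at this stage). Prioritization
(`prioritize_pairs()`) restricts to pairs coverable by two *different*
drugs, ranks by |r| descending and flags pairs strictly above the 0.7
threshold. A drug annotated with both targets of a pair does not by
itself make the pair testable, but it does not disqualify the pair if a
second drug exists — the stricter reading would silently drop valid
combinations.

## Delta Pathway Activity models

For a synergistic pair, per-cell predicted synergy is

$$\Delta PA \;=\; \frac{1}{N}\sum^{N} \text{(top sensitive pathways)}
  \;-\; \frac{1}{M}\sum^{M} \text{(top resistant pathways)}
  \;\pm\; \text{genomics}$$

under Model 1 (mechanism by similarity). Model 2 (mechanism by
compensation) swaps the two means: synergy is maximized in the resistance
context, where escape pathways would otherwise rescue the cell. When the
two groups coincide and no genomics terms are present the two models are
exact negations — a machine-precision invariant in the test suite.

Pathways are ranked by the pair's interaction profile
(`rank_pathways()`): Model 1 uses the mean of the two targets' rows;
Model 2 uses a single **anchor** target's row (default: the first of the
pair, configurable). The anchor is a design decision: for anticorrelated
profiles the mean cancels toward zero and ranks noise; whose resistance
profile should be maximized is genuinely ambiguous, so the package makes
the choice explicit rather than hiding it.

Mechanism selection (`select_model()`): literature overrides win;
otherwise similarity ≥ 0.4 → Model 1, ≤ −0.4 → Model 2, and the band in
between is *undetermined* — no Delta PA model should be built there.

Group construction (`build_model_spec()`) takes the top-N/top-M pathways
(N, M ∈ 1..3). A literature-flagged pathway outside its group is inserted
together with every pathway ranked between the group's first element and
it; when that interval exceeds the 3-pathway cap the rule is internally
contradictory, and the package resolves it as {rank-1, rank-2,
literature pathway} with a `literature_flag` on the spec. A pathway
claimed by both groups goes to the group where it ranks better and the
loser refills — both repairs are package decisions, stated here because
no canonical behavior exists.

Genomics terms enter as ±1 × indicator on the *standardized* activity
scale. Standardization before Delta PA is the default (and the generator
standardizes too): a raw activity axis would make a 0/1 mutation
indicator either negligible or dominant depending on arbitrary scale.
Signs come from literature, never from the data — fitting them would turn
an unsupervised stratifier into an (overfit) supervised one.

Group sizes are selected by leave-one-out cross-validation over the 9
candidates (`select_group_sizes_loocv()`), maximizing Pearson r between
held-out predictions and observed per-cell synergy; ties break to smaller
N + M, then smaller N (parsimony). Because Delta PA has no parameters
fitted to the training cells once the rankings are fixed, the held-out
prediction equals the full-data prediction; the cross-validation
machinery selects among group sizes only and is implemented (and
documented) as such. Candidates with constant predictions are skipped
with a warning; if all are skipped an error is raised.

Drug-level filters: `filter_specific_drugs()` keeps drugs annotated to
the target of interest with at most 3 annotated targets (off-target-heavy
compounds dilute the signal) and warns below 3 remaining pairs;
`eligible_target_pairs()` applies the three eligibility rules (top
synergy strictly > 20; cells with ≥ 2 distinct combinations; ≥ 10
retained cells).

## Significance

Two permutation nulls mirror the two workflows: shuffling aggregated
synergy across target pairs (`permute_pair_labels()`), and shuffling cell
labels independently within each drug combination
(`permute_cell_labels()`). The two-tailed empirical p is
`2·min(#{null ≥ obs}, #{null ≤ obs})/B`, capped at 1 — the phrase
"greater or smaller, two-tailed, divided by B" is ambiguous between this
and an |·|-based tail, so the standard min-tail form is the default and
`tail = "abs"` provides the alternative. No +1 smoothing is applied
(the division is by B exactly), so p = 0 is reachable and documented.
The Bayes factor is the count ratio `#{null < obs} / max(1, #{null ≥ obs})`
with ties counting against the observed statistic; the denominator floor
reproduces the conventional printed ceiling of 999 at B = 1000, and
1000 when every draw is beaten. An empirical permutation p can never be
smaller than 1/B; parametric correlation p-values (which can print as
< 2.2e−16) are a different estimator, which is why
`functional_similarity()` reports the parametric p separately.
FDR flags are Benjamini–Hochberg at q = 0.25.

## Loewe excess volume

Monotherapy viabilities are fitted with a three-parameter Hill curve
(`fit_hill()`: `e_inf ∈ [0,1)`, `ec50 > 0` searched in log space,
`slope ∈ [0.05, 20]`, untreated viability fixed at 1), by bounded
L-BFGS-B least squares from three slope starts. The Loewe surface
(`loewe_surface()`) solves the dose-equivalence index
`d1/D1(E) + d2/D2(E) = 1` per dose pair by bisection (200 halvings, i.e.
to floating-point resolution; interior index residuals are checked below
1e−8 in the acceptance suite). Where the additive effect is unreachable
(below one drug's asymptote) E is clamped to the boundary and flagged
per cell. The synergy score (`synergy_volume()`) is
`100 × mean(expected − observed)` over interior cells: the mean rather
than the sum keeps the score grid-size independent, and the ×100 scale
lands clearly synergistic surfaces near the conventional "> 20"
threshold. Bit-compatibility with any particular challenge's scoring code
is not claimed; the defining sanity property — a drug sham-combined with
itself scores ≈ 0 — is enforced in the acceptance suite.

# The synthetic generator: what a green test establishes

`generate_ground_truth()` draws a targets × pathways interaction matrix
i.i.d. N(0, `effect_sd`) with a fraction `sparsity` zeroed (any
all-zero target row gets one entry redrawn), a column-orthonormal gene
weight matrix, and a Delta PA spec derived from the interaction profile
of the first two targets. `generate_panel()` then emulates a
GDSC-like input set:

* true pathway activities P ~ N(0, 1) per cell;
* expression = `W P' + per-gene baseline + N(0, 0.1)` — orthonormal W
  guarantees scoring recovers P (r ≥ 0.95 per pathway at the default
  noise), which is a conditioning choice, not a claim about biology;
* response `Y = −(X_D I P') + per-drug N(0,1) offsets + N(0, noise_sd)`,
  IC50-oriented (the minus sign encodes "interaction = sensitization");
  offsets force the per-drug standardization path to be exercised;
* uniform missingness with a mask that never empties a row or column;
* synergy labels from the true Delta PA spec, rescaled so the strongest
  cell sits at |30| (the ±20–40 range of real synergy scores), with
  i.i.d. record noise.

Defaults (`noise_sd = 0.3` on response, `expr_noise_sd = 0.1`, 11
pathways, 40 drugs × 120 cells in the acceptance runs) are the stated
desk-scale world and are not tuned per test.

What the generator does **not** emulate: correlated transcriptomic
structure (real co-expression would make pathway scores collinear),
drug-specific dose-response heteroscedasticity, non-random missingness,
multi-target drugs (each synthetic drug has one target), or any causal
feedback between pathways. A green acceptance suite therefore
establishes that the *algorithms* recover a *bilinear, correctly
specified* world at realistic noise — not that the biological claims
transfer to any particular dataset.

## An identifiability limit, found and kept

Exact recovery of the generating group sizes (N, M) through *estimated*
rankings fails in a substantial fraction of random worlds: with
i.i.d.-normal interaction values, the profile gap between the rank-N and
rank-(N+1) pathway is often smaller than the estimation noise of a
fitted interaction row, so group membership is not identifiable no
matter how good the sampler is. The test suite therefore asserts exact
recovery where it is well-posed — the selector given consistent rankings
recovers (N, M) in ≥ 70% of seeds, and noiseless selection is exact with
LOOCV r = 1 — while the end-to-end test asserts the property that
survives near-ties: the selected model still predicts held-out synergy
(median LOOCV r ≥ 0.7 across seeds) with exact (N, M) recovery in a
minority of seeds. Real screens face the same limit; reporting the
selected spec together with its profile values (as `rank_pathways()`
does) is the honest interface.

# Numerical and configuration choices

* **Sampler defaults** (`macau_config()`): L = 10, 200 burn-in, 600
  collected samples, 40 chains. Samples-per-chain and chain count are
  the published protocol of this model family; L and burn-in are
  unstated there and follow the companion methodology's practice — all
  four are plain config fields, not constants.
* **Priors**: normal–Wishart with μ0 = 0, b0 = 2, ν0 = L, W0 = I;
  link precision 5 fixed by default (Gamma(1, 1)-sampled on request);
  τ ~ Gamma(0.5, 0.5) when sampled, or fixed for validation runs.
* **Per-drug standardization** of IC50 before fitting (inverse-applied on
  prediction): drugs differ by orders of magnitude in IC50 range and a
  shared τ is untenable otherwise. A documented side effect is that each
  target's interaction row is recovered up to a positive per-row scale;
  correlations down the pipeline are unaffected, but Model 1's
  mean-of-two-rows ranking can reorder pathways when the two rows have
  very different norms.
* **Determinism**: every stochastic entry point takes a seed; chain
  seeds are derived from the master seed via `derive_seeds()` (distinct
  by construction, all < 2^31); the C++ sampler draws exclusively from
  R's RNG so `set.seed()` governs everything.
* **Degenerate inputs**: constant interaction rows yield NaN similarity
  with a warning (never silently 0); constant activity columns
  standardize to 0 with a warning; flat dose-response data is flagged
  `no_response`; empty candidate sets warn and return empty rather than
  error; divergent chains abort citing the iteration.
* **Tie-breaks**: pathway ranking ties break by name; prioritization
  ties by lexicographic pair label; LOOCV ties by parsimony. All are
  deterministic on purpose.

# Known limitations

Linear pathway combination only — no per-pathway coefficients, no
AND/OR logic, no nonlinear effects; single-target attribution (the
drug-side feature map is the annotation matrix, and multi-target drugs
simply activate several features); the 11-pathway universe caps what
"functional similarity" can see; similarity metrics other than Pearson
and synergy scores other than the Loewe excess volume (Bliss, HSA, ZIP)
are out of scope; tensor (three-drug) combinations are not modelled.
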