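# Synthetic input panels with known ground truth: a target x pathway
# interaction matrix, orthonormal pathway weights, an IC50-like response
# matrix generated by the bilinear model the factorization assumes, and
# synergy labels generated by a known Delta Pathway Activity spec.

#' Generate a ground-truth interaction structure
#'
#' Draws a targets x pathways interaction matrix with i.i.d. N(0,
#' `effect_sd`) entries, zeroes a fraction `sparsity` of them, and redraws
#' one entry for any target row left all-zero so every target interacts
#' with at least one pathway. Positive entries are sensitivity-oriented:
#' activation of the pathway sensitizes cells to drugs hitting the target.
#' Also builds a column-orthonormal genes x pathways weight matrix (so
#' pathway scoring of generated expression is well conditioned) and a
#' Delta PA model spec derived from the interaction profile of the first
#' two targets, used later to generate synergy labels.
#'
#' @param n_targets,n_pathways,n_genes dimensions (`n_pathways >= 2`).
#' @param effect_sd sd of interaction entries.
#' @param sparsity fraction of entries set to zero (< 1).
#' @param seed integer seed; output is fully deterministic given it.
#' @param mechanism synergy mechanism of the generated model spec (1 =
#'   similarity, 2 = compensation).
#' @param n_sensitive,n_resistant group sizes of the generated model spec
#'   (1-3); drawn at random when `NULL`.
#' @return a `ground_truth` list: `interaction_true`,
#'   `pathway_weights_true`, `model_spec_true`, `seed`.
#' @export
generate_ground_truth <- function(n_targets, n_pathways = 11L,
                                  n_genes = 500L, effect_sd = 1,
                                  sparsity = 0.3, seed = 1L,
                                  mechanism = 1L,
                                  n_sensitive = NULL, n_resistant = NULL) {
  stop_if_not(is_count(n_targets) && is_count(n_genes),
              "dimensions must be positive integers")
  stop_if_not(is_count(n_pathways, min = 2L), "need n_pathways >= 2")
  stop_if_not(sparsity >= 0 && sparsity < 1, "sparsity must be in [0, 1)")
  set.seed(as.integer(seed))
  pw <- if (n_pathways == 11L) default_pathways() else
    sprintf("PW%02d", seq_len(n_pathways))
  tg <- sprintf("T%02d", seq_len(n_targets))
  gn <- sprintf("G%04d", seq_len(n_genes))

  I <- matrix(rnorm(n_targets * n_pathways, sd = effect_sd),
              n_targets, n_pathways, dimnames = list(tg, pw))
  n_zero <- floor(sparsity * length(I))
  if (n_zero > 0) I[sample(length(I), n_zero)] <- 0
  for (i in seq_len(n_targets)) {           # regeneration rule
    if (all(I[i, ] == 0))
      I[i, sample(n_pathways, 1L)] <- rnorm(1L, sd = effect_sd)
  }

  W <- qr.Q(qr(matrix(rnorm(n_genes * n_pathways), n_genes, n_pathways)))
  dimnames(W) <- list(gn, pw)

  if (is.null(n_sensitive)) n_sensitive <- sample(3L, 1L)
  if (is.null(n_resistant)) n_resistant <- sample(3L, 1L)
  profile <- if (mechanism == 1L) colMeans(I[1:min(2L, n_targets), , drop = FALSE])
             else I[1L, ]
  spec <- model_spec_from_profile(profile, mechanism = mechanism,
                                  n_sensitive = n_sensitive,
                                  n_resistant = n_resistant,
                                  anchor_target = tg[1L])

  structure(list(interaction_true = I, pathway_weights_true = W,
                 model_spec_true = spec, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate a full synthetic input panel
#'
#' Cells get standard-normal true pathway activities P; expression is
#' `W_true %*% t(P)` plus per-gene baselines and N(0, `expr_noise_sd`)
#' noise, so scoring expression with the true weights recovers P up to
#' noise. Drug d is annotated to target `((d-1) mod n_targets) + 1`, so
#' every target has at least one drug. Response is IC50-like: higher
#' interaction means lower IC50, hence
#' `Y = -(X_D I_true t(P)) + drug offsets + N(0, noise_sd)`, with entries
#' masked at rate `missing_frac` (the mask is redrawn if it would empty a
#' drug row or cell column). Drug offsets are N(0,1) to force per-drug
#' standardization downstream.
#'
#' @param truth a [generate_ground_truth()] object.
#' @param n_drugs,n_cells panel size (`n_drugs >= n_targets`).
#' @param noise_sd response noise sd.
#' @param missing_frac fraction of response entries masked, in [0, 1).
#' @param seed integer seed.
#' @param expr_noise_sd gene-level expression noise sd.
#' @return a `synthetic_panel` list: `expression` (genes x cells),
#'   `response` (drugs x cells, NA = missing), `target_annotation`
#'   (drugs x targets binary), `genomics` (cells x markers binary),
#'   `pathway_activity_true` (cells x pathways), `provenance`.
#' @export
generate_panel <- function(truth, n_drugs, n_cells, noise_sd = 0.3,
                           missing_frac = 0, seed = 1L,
                           expr_noise_sd = 0.1) {
  stop_if_not(inherits(truth, "ground_truth"), "`truth` must be a ground_truth")
  I <- truth$interaction_true
  W <- truth$pathway_weights_true
  n_targets <- nrow(I); K <- ncol(I)
  stop_if_not(is_count(n_drugs, n_targets),
              "need n_drugs >= n_targets (%d)", n_targets)
  stop_if_not(missing_frac >= 0 && missing_frac < 1,
              "missing_frac must be in [0, 1)")
  set.seed(as.integer(seed))
  cells <- sprintf("C%03d", seq_len(n_cells))
  drugs <- sprintf("D%03d", seq_len(n_drugs))

  P <- matrix(rnorm(n_cells * K), n_cells, K,
              dimnames = list(cells, colnames(I)))
  baseline <- rnorm(nrow(W))
  E <- W %*% t(P) + baseline +
    matrix(rnorm(nrow(W) * n_cells, sd = expr_noise_sd), nrow(W), n_cells)
  dimnames(E) <- list(rownames(W), cells)

  X <- matrix(0L, n_drugs, n_targets, dimnames = list(drugs, rownames(I)))
  X[cbind(seq_len(n_drugs), ((seq_len(n_drugs) - 1L) %% n_targets) + 1L)] <- 1L

  offsets <- rnorm(n_drugs)
  Y <- -(X %*% I %*% t(P)) + offsets +
    matrix(rnorm(n_drugs * n_cells, sd = noise_sd), n_drugs, n_cells)
  dimnames(Y) <- list(drugs, cells)
  if (missing_frac > 0) {
    for (try in 1:100) {
      mask <- matrix(runif(length(Y)) < missing_frac, n_drugs, n_cells)
      ok <- !any(rowSums(!mask) == 0) && !any(colSums(!mask) == 0)
      if (ok) break
      stop_if_not(try < 100, "could not draw a mask keeping all rows/columns")
    }
    Y[mask] <- NA_real_
  }

  markers <- c("KRAS_mut", "BRAF_mut", "TP53_mut", "PIK3CA_mut")
  G <- matrix(rbinom(n_cells * length(markers), 1L, 0.3), n_cells,
              dimnames = list(cells, markers))

  structure(list(expression = E, response = Y, target_annotation = X,
                 genomics = G, pathway_activity_true = P,
                 combo_records = NULL,
                 provenance = list(truth = truth, noise_sd = noise_sd,
                                   missing_frac = missing_frac,
                                   expr_noise_sd = expr_noise_sd,
                                   seed = as.integer(seed))),
            class = "synthetic_panel")
}

#' Generate synergy labels from the ground-truth Delta PA model
#'
#' Per-cell noiseless synergy is the Delta PA of `truth$model_spec_true`
#' evaluated on the standardized true pathway activities (plus any genomics
#' terms in the spec), linearly rescaled so the largest |score| is 30
#' (landing the signal in the +/-20-40 synergy-score range). One record is
#' emitted for every ordered drug pair (d1, d2) where d1 annotates the
#' first target and d2 the second, with independent N(0, `noise_sd`) noise
#' per record.
#'
#' @param truth a [generate_ground_truth()] object.
#' @param panel a [generate_panel()] object built from `truth`.
#' @param target_pair length-2 character vector of target ids.
#' @param noise_sd per-record label noise sd.
#' @param seed integer seed.
#' @return data.frame of synergy records (`drug1`, `drug2`, `cell`,
#'   `synergy`) with attribute `noiseless` (named per-cell vector).
#' @export
generate_synergy_labels <- function(truth, panel, target_pair,
                                    noise_sd = 0, seed = 1L) {
  stop_if_not(inherits(panel, "synthetic_panel"), "`panel` must be a panel")
  X <- panel$target_annotation
  for (t in target_pair)
    stop_if_not(t %in% colnames(X), "no target '%s' in annotation", t)
  d1 <- rownames(X)[X[, target_pair[1L]] == 1L]
  d2 <- rownames(X)[X[, target_pair[2L]] == 1L]
  stop_if_not(length(d1) > 0, "no drugs annotate target '%s'", target_pair[1L])
  stop_if_not(length(d2) > 0, "no drugs annotate target '%s'", target_pair[2L])

  pa <- standardize_activities(as_pathway_activity(panel$pathway_activity_true))
  score <- delta_pa(truth$model_spec_true, pa, genomics = panel$genomics)
  s <- unclass(score)
  if (max(abs(s)) > 0) s <- s * (30 / max(abs(s)))

  set.seed(as.integer(seed))
  pairs <- expand.grid(drug1 = d1, drug2 = d2, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$drug1 != pairs$drug2, , drop = FALSE]
  stop_if_not(nrow(pairs) > 0, "no distinct drug pair annotates the targets")
  recs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    data.frame(drug1 = pairs$drug1[k], drug2 = pairs$drug2[k],
               cell = names(s),
               synergy = s + rnorm(length(s), sd = noise_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  structure(recs, noiseless = s)
}

#' Generate perturbation z-score fixtures
#'
#' Emulates a perturbation compendium for weight fitting: each pathway is
#' activated (+1) and inhibited (-1) in `n_per_pathway` experiments each;
#' z-scores are `scale * W_true %*% t(design)` plus N(0, `noise_sd`) noise.
#' [fit_progeny_weights()] on these fixtures recovers the sign pattern of
#' the true weights for its kept genes.
#'
#' @param truth a [generate_ground_truth()] object.
#' @param n_per_pathway experiments per (pathway, sign).
#' @param noise_sd z-score noise sd.
#' @param scale signal amplitude applied to the orthonormal true weights.
#' @param seed integer seed.
#' @return list with `zscores` (genes x experiments) and `design`
#'   (experiments x pathways, signed).
#' @export
generate_perturbation_zscores <- function(truth, n_per_pathway = 3L,
                                          noise_sd = 0.1, scale = 10,
                                          seed = 1L) {
  W <- truth$pathway_weights_true
  K <- ncol(W)
  set.seed(as.integer(seed))
  design <- do.call(rbind, lapply(seq_len(K), function(p) {
    out <- matrix(0, 2L * n_per_pathway, K)
    out[seq_len(n_per_pathway), p] <- 1
    out[n_per_pathway + seq_len(n_per_pathway), p] <- -1
    out
  }))
  colnames(design) <- colnames(W)
  rownames(design) <- sprintf("E%03d", seq_len(nrow(design)))
  Z <- scale * (W %*% t(design)) +
    matrix(rnorm(nrow(W) * nrow(design), sd = noise_sd), nrow(W))
  dimnames(Z) <- list(rownames(W), rownames(design))
  list(zscores = Z, design = design)
}
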