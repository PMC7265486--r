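# Bayesian matrix factorization with side information: R-level contracts
# around the compiled Gibbs sampler, interaction-matrix extraction with an
# explicit sensitivity-orientation contract, chain averaging, stability
# summaries and out-of-matrix prediction.

#' Configuration for the Gibbs sampler
#'
#' Defaults follow published practice for this model family: L = 10 latent
#' dimensions, 200 burn-in iterations, 600 collected samples per chain and
#' 40 independent chains averaged. The noise precision tau is Gamma-sampled
#' by default (`noise_precision = "sampled"`); pass a positive number to
#' hold it fixed. Each link-matrix entry has a zero-mean Gaussian prior
#' with precision `link_prior_precision`, optionally resampled under a
#' Gamma hyperprior.
#'
#' @param L latent dimension (>= 1).
#' @param n_burnin burn-in iterations per chain.
#' @param n_samples collected Gibbs samples per chain (>= 1).
#' @param n_repeats independent chains averaged by
#'   [averaged_interactions()].
#' @param noise_precision `"sampled"` or a fixed positive precision.
#' @param link_prior_precision positive prior precision of link entries.
#' @param sample_link_precision resample the link precision under a
#'   Gamma(1, 1) hyperprior.
#' @param sample_hyper sample the normal-Wishart hyperparameters (disable
#'   only for validation against fixed-hyperparameter oracles, supplying
#'   `mu_u`, `mu_v` and `prec_fixed`).
#' @param mu_u,mu_v,prec_fixed fixed latent means and isotropic precision,
#'   used only when `sample_hyper = FALSE`.
#' @param seed master seed; chain seeds are derived from it.
#' @return a `macau_config` list.
#' @export
macau_config <- function(L = 10L, n_burnin = 200L, n_samples = 600L,
                         n_repeats = 40L, noise_precision = "sampled",
                         link_prior_precision = 5,
                         sample_link_precision = FALSE,
                         sample_hyper = TRUE,
                         mu_u = NULL, mu_v = NULL, prec_fixed = 1,
                         seed = 1L) {
  stop_if_not(is_count(L) && is_count(n_samples) && is_count(n_repeats) &&
                is_count(n_burnin, min = 0L), "invalid sampler dimensions")
  sample_tau <- identical(noise_precision, "sampled")
  if (!sample_tau)
    stop_if_not(is.numeric(noise_precision) && noise_precision > 0,
                "noise_precision must be \"sampled\" or a positive number")
  stop_if_not(link_prior_precision > 0, "link_prior_precision must be > 0")
  structure(list(L = as.integer(L), n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples),
                 n_repeats = as.integer(n_repeats),
                 noise_precision = noise_precision,
                 sample_tau = sample_tau,
                 link_prior_precision = link_prior_precision,
                 sample_link_precision = isTRUE(sample_link_precision),
                 sample_hyper = isTRUE(sample_hyper),
                 mu_u = mu_u, mu_v = mu_v, prec_fixed = prec_fixed,
                 seed = as.integer(seed)),
            class = "macau_config")
}

#' Construct a response matrix with an orientation contract
#'
#' @param values drugs x cells numeric matrix, NA for missing entries;
#'   every drug row and cell column must keep at least one observation.
#' @param orientation `"ic50"` (higher = resistant; the default for log
#'   IC50 input) or `"sensitivity"` (higher = sensitive).
#' @return a `response_matrix` object.
#' @export
response_matrix <- function(values, orientation = c("ic50", "sensitivity")) {
  orientation <- match.arg(orientation)
  values <- as.matrix(values)
  stop_if_not(all(rowSums(!is.na(values)) > 0),
              "every drug row needs >= 1 observed entry")
  stop_if_not(all(colSums(!is.na(values)) > 0),
              "every cell column needs >= 1 observed entry")
  stop_if_not(all(is.finite(values[!is.na(values)])),
              "observed entries must be finite")
  structure(values, orientation = orientation,
            class = c("response_matrix", "matrix", "array"))
}

#' Fit the factorization by Gibbs sampling
#'
#' Model: observed `y_ij ~ N(u_i' v_j, 1/tau)`;
#' `u_i ~ N(mu_u + beta_D' x_i, Lambda_u^-1)` with the drug-target
#' annotation as side information x_i, and symmetrically for cells with
#' pathway activities; normal-Wishart hyperpriors on (mu, Lambda);
#' zero-mean Gaussian priors on link-matrix entries. All conditionals are
#' closed-form; link matrices are drawn from their exact multivariate
#' normal conditional (feature dimensions here are small). Responses are
#' centred and scaled per drug by default (IC50 ranges differ wildly
#' across drugs; a shared noise precision needs a common scale), and
#' predictions are returned on the original scale.
#'
#' @param y a [response_matrix()] or plain drugs x cells matrix (then
#'   assumed `"ic50"`-oriented).
#' @param drug_side drugs x targets binary side-information matrix (or
#'   NULL).
#' @param cell_side cells x pathways side-information matrix (or NULL).
#' @param cfg a [macau_config()].
#' @param standardize centre/scale each drug row before fitting.
#' @param keep_samples store per-sample latents (needed by
#'   [predict_response()]).
#' @return a `macau_fit` object: posterior means of U, V, the two link
#'   matrices, the running interaction mean, per-sample training RMSE
#'   trace, the per-drug centring used, and the configuration.
#' @export
fit_macau <- function(y, drug_side = NULL, cell_side = NULL,
                      cfg = macau_config(), standardize = TRUE,
                      keep_samples = TRUE) {
  if (!inherits(y, "response_matrix")) y <- response_matrix(y)
  Y <- unclass(y)
  check_side <- function(s, n, label) {
    if (is.null(s)) return(matrix(numeric(0), n, 0))
    s <- as.matrix(s)
    stop_if_not(!anyNA(s), "NA in %s side information", label)
    stop_if_not(nrow(s) == n, "%s side rows must match response", label)
    s
  }
  Xd <- check_side(drug_side, nrow(Y), "drug")
  Xc <- check_side(cell_side, ncol(Y), "cell")

  centers <- rep(0, nrow(Y)); scales <- rep(1, nrow(Y))
  if (standardize) {
    centers <- rowMeans(Y, na.rm = TRUE)
    scales <- apply(Y, 1L, sd, na.rm = TRUE)
    scales[!is.finite(scales) | scales == 0] <- 1
    Y <- (Y - centers) / scales
  }

  L <- cfg$L
  mu_u <- if (is.null(cfg$mu_u)) rep(0, L) else rep_len(cfg$mu_u, L)
  mu_v <- if (is.null(cfg$mu_v)) rep(0, L) else rep_len(cfg$mu_v, L)
  tau_init <- if (cfg$sample_tau) 2 else cfg$noise_precision

  set.seed(cfg$seed)
  raw <- macau_gibbs_cpp(Y, Xd, Xc, L, cfg$n_burnin, cfg$n_samples,
                         cfg$sample_tau, tau_init,
                         cfg$link_prior_precision,
                         cfg$sample_link_precision,
                         cfg$sample_hyper, mu_u, mu_v, cfg$prec_fixed,
                         keep_samples)
  stop_if_not(all(is.finite(raw$rmse_trace)),
              "divergent chain: non-finite RMSE trace")
  dimnames(raw$interaction_mean) <- list(colnames(Xd), colnames(Xc))
  rownames(raw$U_mean) <- rownames(Y)
  rownames(raw$V_mean) <- colnames(Y)
  structure(c(raw, list(cfg = cfg, centers = centers, scales = scales,
                        orientation = attr(y, "orientation"),
                        standardized_per_drug = standardize,
                        drug_features = colnames(Xd),
                        cell_features = colnames(Xc),
                        drugs = rownames(Y), cells = colnames(Y))),
            class = "macau_fit")
}

#' Extract the target x pathway interaction matrix from a fit
#'
#' The interaction matrix is the mean over collected Gibbs samples of
#' `beta_D %*% t(beta_C)`. Under `"ic50"` orientation the product is
#' negated so that positive entries always mean "activation of the pathway
#' associates with sensitivity when targeting the protein" (the
#' sensitivity-orientation contract shared by all downstream modules).
#'
#' @param fit a [fit_macau()] result (both side matrices required).
#' @param tissue_label free-text context label carried along.
#' @return an `interaction_matrix`: targets x pathways numeric matrix with
#'   attributes `n_chains_averaged`, `orientation` and `tissue_label`.
#' @export
interaction_matrix <- function(fit, tissue_label = "") {
  stop_if_not(inherits(fit, "macau_fit"), "`fit` must be a macau_fit")
  M <- fit$interaction_mean
  stop_if_not(length(M) > 0, "fit has no drug and/or cell side information")
  if (fit$orientation == "ic50") M <- -M
  structure(M, n_chains_averaged = 1L, orientation = "sensitivity",
            tissue_label = tissue_label,
            class = c("interaction_matrix", "matrix", "array"))
}

#' Average interaction matrices over independent chains
#'
#' Runs `cfg$n_repeats` independent Gibbs chains with distinct seeds
#' derived from the master seed and returns the elementwise mean of their
#' interaction matrices (and optionally the per-chain matrices, e.g. for
#' [stability_report()]).
#'
#' @inheritParams fit_macau
#' @param tissue_label carried to the result.
#' @param return_chains also return the per-chain matrices.
#' @return an `interaction_matrix` (with `chains` attribute when
#'   `return_chains`).
#' @export
averaged_interactions <- function(y, drug_side, cell_side,
                                  cfg = macau_config(), standardize = TRUE,
                                  tissue_label = "",
                                  return_chains = FALSE) {
  stop_if_not(cfg$n_repeats >= 1L, "n_repeats must be >= 1")
  seeds <- derive_seeds(cfg$seed, cfg$n_repeats)
  stop_if_not(!anyDuplicated(seeds), "derived chain seeds must be distinct")
  chains <- vector("list", cfg$n_repeats)
  for (k in seq_len(cfg$n_repeats)) {
    cfg_k <- cfg; cfg_k$seed <- seeds[k]
    fit <- tryCatch(
      fit_macau(y, drug_side, cell_side, cfg_k, standardize = standardize,
                keep_samples = FALSE),
      error = function(e) stop(sprintf(
        "chain with seed %d failed: %s", seeds[k], conditionMessage(e)),
        call. = FALSE))
    chains[[k]] <- interaction_matrix(fit, tissue_label)
  }
  avg <- Reduce(`+`, lapply(chains, unclass)) / cfg$n_repeats
  out <- structure(avg, n_chains_averaged = cfg$n_repeats,
                   orientation = "sensitivity", tissue_label = tissue_label,
                   class = c("interaction_matrix", "matrix", "array"))
  if (return_chains) attr(out, "chains") <- chains
  out
}

#' Stability of averaged interaction matrices under chain subsampling
#'
#' Emulates the robustness protocol of averaging random subsets of
#' independent-chain interaction matrices: draws `n_draws` random subsets
#' of size `subsample_size`, averages each, and reports (i) mean and sd of
#' all pairwise Pearson correlations among the subset averages and (ii)
#' the per-target-pair coefficient of variation of functional similarity
#' across the subset averages.
#'
#' @param matrices list of >= 2 interaction matrices (same dimnames).
#' @param subsample_size chains per subset (<= length(matrices)).
#' @param n_draws number of subsets (>= 2).
#' @param seed integer seed for the draws.
#' @return list with `mean_pairwise_r`, `sd_pairwise_r`, `pairwise_r`,
#'   and `similarity_cv` (named per target pair).
#' @export
stability_report <- function(matrices, subsample_size, n_draws = 50L,
                             seed = 1L) {
  stop_if_not(length(matrices) >= 2L, "need >= 2 interaction matrices")
  stop_if_not(subsample_size <= length(matrices),
              "subsample_size exceeds number of matrices")
  stop_if_not(is_count(n_draws, min = 2L),
              "pairwise statistics need n_draws >= 2")
  set.seed(as.integer(seed))
  avgs <- lapply(seq_len(n_draws), function(i) {
    idx <- sample(length(matrices), subsample_size)
    Reduce(`+`, lapply(matrices[idx], unclass)) / subsample_size
  })
  combos <- combn(n_draws, 2L)
  prs <- apply(combos, 2L, function(ij)
    cor(as.vector(avgs[[ij[1L]]]), as.vector(avgs[[ij[2L]]])))
  targets <- rownames(matrices[[1L]])
  cv <- c()
  if (length(targets) >= 2L) {
    tp <- combn(targets, 2L)
    cv <- apply(tp, 2L, function(p) {
      sims <- vapply(avgs, function(A)
        suppressWarnings(cor(A[p[1L], ], A[p[2L], ])), numeric(1))
      if (mean(sims) == 0) NA_real_ else sd(sims) / abs(mean(sims))
    })
    names(cv) <- apply(tp, 2L, paste, collapse = "|")
  }
  list(mean_pairwise_r = mean(prs), sd_pairwise_r = sd(prs),
       pairwise_r = prs, similarity_cv = cv)
}

#' Predict drug response for new cells from their side information
#'
#' Per collected sample, a new cell's latent mean is
#' `mu_v + t(beta_C) x_new`, and predictions `U (mu_v + t(beta_C) x)'`
#' are averaged over samples, then mapped back through the per-drug
#' centring used at fit time.
#'
#' @param fit a [fit_macau()] result with `keep_samples = TRUE`.
#' @param new_cell_side new cells x pathways matrix whose columns match
#'   the training cell side information.
#' @return drugs x new-cells predicted response matrix (original scale
#'   and orientation).
#' @export
predict_response <- function(fit, new_cell_side) {
  stop_if_not(inherits(fit, "macau_fit"), "`fit` must be a macau_fit")
  stop_if_not(!is.null(fit$U_samples),
              "fit was run with keep_samples = FALSE")
  X <- as.matrix(new_cell_side)
  missing <- setdiff(fit$cell_features, colnames(X))
  stop_if_not(length(missing) == 0, "missing pathway column(s): %s",
              paste(missing, collapse = ", "))
  X <- X[, fit$cell_features, drop = FALSE]
  ns <- dim(fit$U_samples)[3L]
  slice <- function(a, s) array(a[, , s], dim(a)[1:2])  # keep matrix shape
  acc <- 0
  for (s in seq_len(ns)) {
    Vnew <- sweep(X %*% slice(fit$beta_c_samples, s), 2L,
                  fit$mu_v_samples[, s], "+")
    acc <- acc + slice(fit$U_samples, s) %*% t(Vnew)
  }
  pred <- acc / ns
  pred <- pred * fit$scales + fit$centers
  dimnames(pred) <- list(fit$drugs, rownames(X))
  pred
}
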