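# Footprint-style pathway activity scoring: fit gene weights from
# perturbation z-scores, score basal expression by a matrix product.

#' Default pathway set
#'
#' The 11 signaling pathways used throughout: EGFR, NFkB, TGFb, MAPK, p53,
#' TNFa, PI3K, VEGF, Hypoxia, Trail and JAK-STAT.
#'
#' @export
default_pathways <- function() {
  c("EGFR", "NFkB", "TGFb", "MAPK", "p53", "TNFa",
    "PI3K", "VEGF", "Hypoxia", "Trail", "JAK-STAT")
}

#' Perturbation z-scores for one experiment
#'
#' Computes per-gene z-scores of perturbed minus control expression,
#' standardized by the two-group pooled standard deviation:
#' \eqn{z_g = (\bar x_{pert,g} - \bar x_{ctrl,g}) / s_{pooled,g}}.
#' Genes whose pooled sd is zero get z = 0; their count is attached as the
#' `n_zero_sd` attribute and a warning is raised.
#'
#' @param perturbed genes x samples matrix of the perturbed arm.
#' @param control genes x samples matrix of the control arm (>= 2 samples).
#' @return named numeric vector of z-scores over the shared gene set.
#' @export
perturbation_zscores <- function(perturbed, control) {
  perturbed <- as.matrix(perturbed); control <- as.matrix(control)
  shared <- intersect(rownames(perturbed), rownames(control))
  stop_if_not(length(shared) > 0, "perturbed and control share no genes")
  stop_if_not(ncol(control) >= 2L,
              "need >= 2 control samples for a pooled sd estimate")
  xp <- perturbed[shared, , drop = FALSE]
  xc <- control[shared, , drop = FALSE]
  n1 <- ncol(xp); n2 <- ncol(xc)
  v1 <- if (n1 > 1L) apply(xp, 1L, var) else rep(0, length(shared))
  v2 <- apply(xc, 1L, var)
  pooled <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  delta <- rowMeans(xp) - rowMeans(xc)
  z <- ifelse(pooled > 0, delta / pooled, 0)
  n_zero <- sum(pooled == 0)
  if (n_zero > 0)
    warning(sprintf("%d gene(s) had zero pooled sd; z set to 0", n_zero))
  structure(setNames(z, shared), n_zero_sd = n_zero)
}

#' Fit pathway gene weights from perturbation z-scores
#'
#' Per gene, ordinary least squares of its z-scores across experiments on a
#' signed pathway design matrix gives one coefficient per pathway; per
#' pathway, only the `top_k` genes by coefficient significance (|t|) are
#' kept, all other weights are set exactly to zero. This mirrors how
#' footprint signatures are derived from perturbation compendia.
#'
#' @param zscores genes x experiments matrix.
#' @param design experiments x pathways signed indicator matrix (+1
#'   activating, -1 inhibiting, 0 untouched); must have full column rank.
#' @param top_k number of signature genes retained per pathway.
#' @return a `progeny_weights` object: genes x pathways matrix whose
#'   non-signature entries are exactly 0, with attribute `tstats`.
#' @export
fit_progeny_weights <- function(zscores, design, top_k = 100L) {
  zscores <- as.matrix(zscores); design <- as.matrix(design)
  stop_if_not(is_count(top_k), "`top_k` must be >= 1")
  stop_if_not(nrow(design) == ncol(zscores),
              "design rows must match z-score experiments")
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[-seq_len(qrd$rank)]
    stop(sprintf("design is rank-deficient; collinear pathway column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  XtXi <- chol2inv(qr.R(qrd))
  B <- zscores %*% design %*% XtXi        # genes x pathways coefficients
  fitted <- B %*% t(design)
  rss <- rowSums((zscores - fitted)^2)
  df <- ncol(zscores) - ncol(design)
  sigma2 <- if (df > 0) rss / df else rep(0, nrow(zscores))
  se <- sqrt(outer(sigma2, diag(XtXi)))
  tstat <- ifelse(se > 0, B / se, ifelse(B == 0, 0, Inf * sign(B)))
  W <- B
  for (p in seq_len(ncol(W))) {
    # |t| primary, |coef| breaks Inf ties from zero-residual fits
    ord <- order(-abs(tstat[, p]), -abs(B[, p]))
    drop_idx <- ord[-seq_len(min(top_k, length(ord)))]
    W[drop_idx, p] <- 0
  }
  dimnames(W) <- list(rownames(zscores), colnames(design))
  structure(W, tstats = tstat, class = c("progeny_weights", "matrix", "array"))
}

#' Score pathway activities from expression
#'
#' The activity of a pathway in a sample is the sum over the pathway's
#' signature genes of expression times gene weight, i.e. the matrix product
#' t(expression) %*% weights restricted to the shared gene set.
#'
#' @param expr genes x samples expression matrix (log scale).
#' @param weights genes x pathways weight matrix (`progeny_weights` or plain).
#' @param standardize if `TRUE`, z-score each pathway across samples
#'   (see [standardize_activities()]).
#' @return a `pathway_activity` object: samples x pathways matrix with
#'   attributes `standardized` and `n_shared_genes`.
#' @export
score_pathways <- function(expr, weights, standardize = FALSE) {
  expr <- as.matrix(expr); W <- unclass(as.matrix(weights))
  shared <- intersect(rownames(expr), rownames(W))
  stop_if_not(length(shared) > 0,
              "no shared genes between expression and weight matrix")
  A <- t(expr[shared, , drop = FALSE]) %*% W[shared, , drop = FALSE]
  out <- structure(A, standardized = FALSE, n_shared_genes = length(shared),
                   class = c("pathway_activity", "matrix", "array"))
  if (standardize) out <- standardize_activities(out) else out
}

#' Standardize pathway activities
#'
#' Z-scores each pathway column across samples (denominator n - 1) and sets
#' the `standardized` flag. Constant columns are set to 0 with a warning.
#' Idempotent. A unit scale is required before mixing activities with
#' binarized genomics terms in Delta Pathway Activity models.
#'
#' @param pa samples x pathways activity matrix.
#' @return standardized `pathway_activity` object.
#' @export
standardize_activities <- function(pa) {
  A <- unclass(as.matrix(pa))
  stop_if_not(nrow(A) >= 2L, "need >= 2 samples to standardize")
  mu <- colMeans(A)
  s <- apply(A, 2L, sd)
  Z <- sweep(A, 2L, mu)
  const <- s == 0
  if (any(const)) {
    warning(sprintf("constant pathway column(s) set to 0: %s",
                    paste(colnames(A)[const], collapse = ", ")))
    s[const] <- 1
  }
  Z <- sweep(Z, 2L, s, "/")
  Z[, const] <- 0
  structure(Z, standardized = TRUE,
            n_shared_genes = attr(pa, "n_shared_genes"),
            class = c("pathway_activity", "matrix", "array"))
}

is_standardized <- function(pa) isTRUE(attr(pa, "standardized"))

#' Wrap a plain matrix as a pathway activity matrix
#'
#' @param x samples x pathways numeric matrix.
#' @param standardized whether columns are already z-scored.
#' @return a `pathway_activity` object.
#' @export
as_pathway_activity <- function(x, standardized = FALSE) {
  structure(as.matrix(x), standardized = isTRUE(standardized),
            class = c("pathway_activity", "matrix", "array"))
}
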