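# Target functional similarity and the combination prioritization
# workflow: correlate two targets' interaction profiles over the pathway
# axis, rank candidate pairs by |similarity|, pool across tissues, and
# relate |similarity| to observed synergy.

#' Functional similarity of two targets
#'
#' Pearson correlation between the two targets' rows of the interaction
#' matrix (their interaction values with the pathways), with a two-sided
#' p-value from the t distribution on `n_pathways - 2` degrees of freedom.
#' A constant row makes r undefined: it is reported as NaN with a warning,
#' never silently zero.
#'
#' @param interactions targets x pathways interaction matrix
#'   (sensitivity-oriented), >= 3 pathway columns.
#' @param t1,t2 target ids.
#' @return named vector `c(r, p)`.
#' @export
functional_similarity <- function(interactions, t1, t2) {
  I <- as.matrix(interactions)
  stop_if_not(ncol(I) >= 3L, "need >= 3 pathways")
  for (t in c(t1, t2))
    stop_if_not(t %in% rownames(I), "target '%s' not in interaction matrix", t)
  x <- I[t1, ]; y <- I[t2, ]
  if (sd(x) == 0 || sd(y) == 0) {
    warning(sprintf("constant interaction row for %s/%s: similarity is NaN",
                    t1, t2))
    return(c(r = NaN, p = NaN))
  }
  pearson_with_p(x, y)
}

#' All pairwise target functional similarities
#'
#' @inheritParams functional_similarity
#' @return a `similarity_matrix`: symmetric targets x targets matrix with
#'   unit diagonal, values between -1 and 1 (NaN where a row is constant), and
#'   attributes `n_pathways`, `pvalues`, `tissue_label`.
#' @export
similarity_matrix <- function(interactions) {
  I <- as.matrix(interactions)
  stop_if_not(nrow(I) >= 2L, "need >= 2 targets")
  stop_if_not(ncol(I) >= 3L, "need >= 3 pathways")
  n <- nrow(I)
  S <- diag(nrow = n); P <- matrix(NA_real_, n, n)
  dimnames(S) <- dimnames(P) <- list(rownames(I), rownames(I))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    rp <- suppressWarnings(
      functional_similarity(I, rownames(I)[i], rownames(I)[j]))
    S[i, j] <- S[j, i] <- rp[["r"]]
    P[i, j] <- P[j, i] <- rp[["p"]]
  }
  if (anyNA(S)) warning("constant interaction row(s): NaN similarities")
  structure(S, n_pathways = ncol(I), pvalues = P,
            tissue_label = attr(interactions, "tissue_label"),
            class = c("similarity_matrix", "matrix", "array"))
}

#' Prioritize target pairs by absolute functional similarity
#'
#' Restricts to pairs of `common_targets` whose two proteins are hit by
#' two different drugs (when an annotation is supplied; a single drug
#' annotated with both targets does not itself form a combination, but
#' does not disqualify the pair), ranks pairs by |similarity| descending
#' (ties broken by lexicographic pair name) and flags pairs strictly
#' exceeding the threshold.
#'
#' @param sim a [similarity_matrix()].
#' @param common_targets targets shared with the combination screen;
#'   defaults to all targets in `sim`.
#' @param threshold |similarity| pass threshold (strict `>`).
#' @param annotation optional drug -> targets annotation (matrix or named
#'   list) enforcing the two-different-drugs rule.
#' @return a `prioritized_pairs` data.frame: `target1`, `target2`,
#'   `similarity`, `abs_similarity`, `pearson_p`, `passes_threshold`.
#' @export
prioritize_pairs <- function(sim, common_targets = rownames(sim),
                             threshold = 0.7, annotation = NULL) {
  stop_if_not(inherits(sim, "similarity_matrix"),
              "`sim` must be a similarity_matrix")
  stop_if_not(all(common_targets %in% rownames(sim)),
              "common_targets must be a subset of the similarity targets")
  P <- attr(sim, "pvalues")
  pairs <- if (length(common_targets) >= 2L)
    t(combn(sort(common_targets), 2L)) else matrix(character(0), 0, 2)
  if (!is.null(annotation) && nrow(pairs) > 0) {
    ann <- as_target_list(annotation)
    ok <- apply(pairs, 1L, function(p) {
      d1 <- names(ann)[vapply(ann, function(ts) p[1L] %in% ts, logical(1))]
      d2 <- names(ann)[vapply(ann, function(ts) p[2L] %in% ts, logical(1))]
      # need two *different* drugs covering the two targets
      length(d1) > 0 && length(d2) > 0 && length(union(d1, d2)) >= 2L &&
        any(outer(d1, d2, `!=`))
    })
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    warning("no candidate target pair")
    out <- data.frame(target1 = character(), target2 = character(),
                      similarity = numeric(), abs_similarity = numeric(),
                      pearson_p = numeric(), passes_threshold = logical())
  } else {
    s <- sim[pairs]
    out <- data.frame(target1 = pairs[, 1L], target2 = pairs[, 2L],
                      similarity = s, abs_similarity = abs(s),
                      pearson_p = P[pairs],
                      passes_threshold = abs(s) > threshold)
    out <- out[order(-out$abs_similarity,
                     paste(out$target1, out$target2)), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, threshold = threshold,
            class = c("prioritized_pairs", "data.frame"))
}

#' Average functional similarity across tissues
#'
#' Elementwise NaN-aware mean of per-tissue similarity matrices over a
#' shared target set (pairwise-complete: an entry missing in every tissue
#' stays NaN).
#'
#' @param mats list of [similarity_matrix()] objects with identical
#'   target sets.
#' @return a `similarity_matrix` labelled `"cross-tissue"`.
#' @export
cross_tissue_similarity <- function(mats) {
  stop_if_not(length(mats) >= 1L, "need >= 1 similarity matrix")
  tg <- rownames(mats[[1L]])
  for (m in mats)
    stop_if_not(identical(rownames(m), tg), "target sets differ across tissues")
  arr <- simplify2array(lapply(mats, unclass))
  avg <- apply(arr, c(1L, 2L), function(v)
    if (all(is.na(v))) NaN else mean(v, na.rm = TRUE))
  structure(avg, n_pathways = attr(mats[[1L]], "n_pathways"),
            pvalues = NULL, tissue_label = "cross-tissue",
            class = c("similarity_matrix", "matrix", "array"))
}

#' Correlate |similarity| with observed synergy across target pairs
#'
#' @param sim a [similarity_matrix()].
#' @param pair_synergy data.frame with `target1`, `target2`, `synergy`
#'   (aggregated observed synergy per target pair).
#' @return Pearson r between |similarity| and synergy (>= 3 complete
#'   pairs required), with the paired values as attributes.
#' @export
similarity_vs_synergy <- function(sim, pair_synergy) {
  stop_if_not(all(c("target1", "target2", "synergy") %in%
                    names(pair_synergy)), "malformed pair_synergy")
  s <- mapply(function(a, b) sim[a, b],
              pair_synergy$target1, pair_synergy$target2)
  keep <- is.finite(s) & is.finite(pair_synergy$synergy)
  stop_if_not(sum(keep) >= 3L, "need >= 3 pairs with both values")
  r <- cor(abs(s[keep]), pair_synergy$synergy[keep])
  structure(r, abs_similarity = abs(s[keep]),
            synergy = pair_synergy$synergy[keep])
}
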