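# Delta Pathway Activity models: mechanism selection, pathway ranking,
# group construction (with literature insertion and disjointness repair),
# per-cell prediction, drug-specificity and eligibility filters, observed
# synergy aggregation, and LOOCV group-size selection.

#' Construct a Delta PA model specification
#'
#' @param mechanism 1 (synergy by similarity: maximize drug sensitivity) or
#'   2 (synergy by compensation: maximize drug resistance).
#' @param sensitive_pathways,resistant_pathways ordered character vectors,
#'   each of 1-3 pathways; the two groups must be disjoint.
#' @param genomics_terms named numeric vector of signs (+1/-1) keyed by
#'   marker name, entering the score as `sign * indicator`; signs come from
#'   literature, never from the data.
#' @param anchor_target target whose interaction row ranks pathways under
#'   mechanism 2.
#' @param literature_flag set when the literature-insertion interval rule
#'   had to be truncated (see [build_model_spec()]).
#' @return a `synergy_model_spec` object.
#' @export
synergy_model_spec <- function(mechanism, sensitive_pathways,
                               resistant_pathways,
                               genomics_terms = numeric(),
                               anchor_target = NULL,
                               literature_flag = FALSE) {
  mechanism <- as.integer(mechanism)
  stop_if_not(mechanism %in% c(1L, 2L), "mechanism must be 1 or 2")
  ns <- length(sensitive_pathways); nm <- length(resistant_pathways)
  stop_if_not(ns >= 1L && ns <= 3L && nm >= 1L && nm <= 3L,
              "each group must hold 1 to 3 pathways")
  stop_if_not(length(intersect(sensitive_pathways, resistant_pathways)) == 0,
              "sensitive and resistant groups must be disjoint")
  if (length(genomics_terms))
    stop_if_not(all(genomics_terms %in% c(-1, 1)) &&
                  !is.null(names(genomics_terms)),
                "genomics_terms must be a named vector of +1/-1 signs")
  structure(list(mechanism = mechanism,
                 sensitive_pathways = as.character(sensitive_pathways),
                 resistant_pathways = as.character(resistant_pathways),
                 genomics_terms = genomics_terms,
                 anchor_target = anchor_target,
                 literature_flag = isTRUE(literature_flag)),
            class = "synergy_model_spec")
}

# Spec from a raw interaction profile: top-N most positive pathways are
# sensitive, top-M most negative are resistant.
model_spec_from_profile <- function(profile, mechanism, n_sensitive,
                                    n_resistant, anchor_target = NULL,
                                    genomics_terms = numeric()) {
  ord_sen <- names(sort(profile, decreasing = TRUE))
  ord_res <- names(sort(profile, decreasing = FALSE))
  synergy_model_spec(mechanism,
                     ord_sen[seq_len(n_sensitive)],
                     ord_res[seq_len(n_resistant)],
                     genomics_terms = genomics_terms,
                     anchor_target = anchor_target)
}

#' Select the synergy mechanism from target functional similarity
#'
#' Literature overrides win when provided; otherwise similarity >= 0.4
#' selects Model 1 (similarity), <= -0.4 selects Model 2 (compensation),
#' and the band in between is an undetermined case in which no Delta PA
#' model should be built.
#'
#' @param similarity target functional similarity between -1 and 1.
#' @param literature_override optional mechanism (1 or 2) from literature.
#' @return 1L, 2L, or `NA_integer_` (undetermined).
#' @export
select_model <- function(similarity, literature_override = NULL) {
  if (!is.null(literature_override)) {
    stop_if_not(literature_override %in% c(1L, 2L),
                "literature_override must be 1 or 2")
    return(as.integer(literature_override))
  }
  stop_if_not(is.finite(similarity) && abs(similarity) <= 1,
              "similarity must be in [-1, 1]")
  if (similarity >= 0.4) 1L else if (similarity <= -0.4) 2L else NA_integer_
}

#' Rank pathways by their sensitivity/resistance interaction profile
#'
#' Mechanism 1 ranks on the mean of the two targets' sensitivity-oriented
#' interaction rows; mechanism 2 (anticorrelated profiles, whose mean would
#' cancel) ranks on a single anchor target's row. The sensitive ranking
#' orders pathways by descending profile value, the resistant ranking by
#' ascending value. Ranks are invariant under positive rescaling of the
#' interaction matrix; ties break by pathway name for determinism.
#'
#' @param interactions an [interaction_matrix()] (or plain targets x
#'   pathways matrix, sensitivity-oriented).
#' @param pair length-2 character vector of target ids.
#' @param mechanism 1 or 2.
#' @param anchor_target anchor for mechanism 2; defaults to `pair[1]`.
#' @return a `pathway_rankings` list: `sensitive`, `resistant` (ordered
#'   pathway names) and `profile` (named values).
#' @export
rank_pathways <- function(interactions, pair, mechanism = 1L,
                          anchor_target = pair[1L]) {
  I <- as.matrix(interactions)
  for (t in pair)
    stop_if_not(t %in% rownames(I), "target '%s' not in interaction matrix", t)
  profile <- if (mechanism == 1L) colMeans(I[pair, , drop = FALSE])
             else I[anchor_target, ]
  ord <- order(-profile, colnames(I))
  structure(list(sensitive = colnames(I)[ord],
                 resistant = rev(colnames(I)[ord]),
                 profile = profile, mechanism = as.integer(mechanism),
                 anchor_target = anchor_target, pair = pair),
            class = "pathway_rankings")
}

# Apply the literature interval rule to one group. ranking: full ordered
# pathway vector for this group; returns list(group, truncated).
insert_literature <- function(group, ranking, lit) {
  r <- match(lit, ranking)
  stop_if_not(!is.na(r), "literature pathway '%s' not in pathway universe", lit)
  if (lit %in% group) return(list(group = group, truncated = FALSE))
  if (r <= 3L) return(list(group = ranking[seq_len(r)], truncated = FALSE))
  # interval from the group's first element to the literature pathway
  # exceeds the 3-pathway cap: keep ranks 1-2 plus the literature pathway
  list(group = c(ranking[1:2], lit), truncated = TRUE)
}

#' Build a Delta PA model spec from pathway rankings
#'
#' Takes the top `n_sensitive` of the sensitive ranking and top
#' `n_resistant` of the resistant ranking. A literature pathway outside a
#' group is inserted together with every pathway ranked between the
#' group's first element and it; if that interval exceeds the 3-pathway
#' cap, ranks 1-2 plus the literature pathway are kept and the spec is
#' flagged (`literature_flag`). A pathway claimed by both groups goes to
#' the group where its |profile value| rank is better, and the losing
#' group refills from its ranking.
#'
#' @param rankings a [rank_pathways()] result.
#' @param n_sensitive,n_resistant group sizes (1-3).
#' @param genomics_terms named sign vector, see [synergy_model_spec()].
#' @param literature_pathways optional named character vector mapping
#'   pathway name -> group (`"sensitive"` or `"resistant"`).
#' @return a `synergy_model_spec`.
#' @export
build_model_spec <- function(rankings, n_sensitive, n_resistant,
                             genomics_terms = numeric(),
                             literature_pathways = NULL) {
  stop_if_not(inherits(rankings, "pathway_rankings"),
              "`rankings` must come from rank_pathways()")
  stop_if_not(n_sensitive >= 1L && n_sensitive <= 3L &&
                n_resistant >= 1L && n_resistant <= 3L,
              "group sizes must be in 1..3")
  sen <- rankings$sensitive[seq_len(n_sensitive)]
  res <- rankings$resistant[seq_len(n_resistant)]
  truncated <- FALSE
  if (!is.null(literature_pathways)) {
    stop_if_not(all(literature_pathways %in% c("sensitive", "resistant")),
                "literature groups must be 'sensitive' or 'resistant'")
    for (lit in names(literature_pathways)) {
      if (literature_pathways[[lit]] == "sensitive") {
        ins <- insert_literature(sen, rankings$sensitive, lit)
        sen <- ins$group
      } else {
        ins <- insert_literature(res, rankings$resistant, lit)
        res <- ins$group
      }
      truncated <- truncated || ins$truncated
    }
  }
  overlap <- intersect(sen, res)
  for (p in overlap) {
    keep_sen <- match(p, rankings$sensitive) <= match(p, rankings$resistant)
    if (keep_sen) {
      res <- setdiff(res, p)
      refill <- setdiff(rankings$resistant, c(res, sen))
      if (length(res) == 0L) res <- refill[1L]
    } else {
      sen <- setdiff(sen, p)
      refill <- setdiff(rankings$sensitive, c(res, sen))
      if (length(sen) == 0L) sen <- refill[1L]
    }
  }
  synergy_model_spec(rankings$mechanism, sen, res,
                     genomics_terms = genomics_terms,
                     anchor_target = rankings$anchor_target,
                     literature_flag = truncated)
}

#' Delta Pathway Activity scores
#'
#' Mechanism 1:
#' `mean(sensitive-group activities) - mean(resistant-group activities)
#'  + sum(sign * marker)`;
#' mechanism 2 swaps the two group means (maximize resistance, minimize
#' sensitization). Activities should be standardized so the binarized
#' genomics terms are on a comparable scale; a warning is raised otherwise.
#'
#' @param spec a [synergy_model_spec()].
#' @param pa samples x pathways activity matrix (standardized).
#' @param genomics optional cells x markers binary matrix; required when
#'   the spec carries genomics terms.
#' @return a `delta_pa_scores` named vector (one score per cell in `pa`).
#' @export
delta_pa <- function(spec, pa, genomics = NULL) {
  stop_if_not(inherits(spec, "synergy_model_spec"),
              "`spec` must be a synergy_model_spec")
  A <- as.matrix(pa)
  if (!is_standardized(pa))
    warning("pathway activities are not flagged standardized; ",
            "genomics terms assume a unit activity scale")
  need <- c(spec$sensitive_pathways, spec$resistant_pathways)
  miss <- setdiff(need, colnames(A))
  stop_if_not(length(miss) == 0, "pathway(s) missing from activities: %s",
              paste(miss, collapse = ", "))
  sen <- rowMeans(A[, spec$sensitive_pathways, drop = FALSE])
  res <- rowMeans(A[, spec$resistant_pathways, drop = FALSE])
  score <- if (spec$mechanism == 1L) sen - res else res - sen
  if (length(spec$genomics_terms)) {
    stop_if_not(!is.null(genomics), "spec has genomics terms but no genomics")
    G <- as.matrix(genomics)
    missm <- setdiff(names(spec$genomics_terms), colnames(G))
    stop_if_not(length(missm) == 0, "marker(s) missing from genomics: %s",
                paste(missm, collapse = ", "))
    for (m in names(spec$genomics_terms))
      score <- score + spec$genomics_terms[[m]] * G[rownames(A), m]
  }
  structure(setNames(as.numeric(score), rownames(A)),
            spec = spec, class = "delta_pa_scores")
}

#' Keep drugs specific to the two targets of interest
#'
#' A drug is admissible for target t if it is annotated to t and has at
#' most `max_targets` annotated targets (off-target-heavy drugs are
#' removed). Returns all cross pairs of admissible drugs for the two
#' targets; warns when fewer than 3 pairs remain.
#'
#' @param annotation named list mapping drug -> character vector of targets
#'   (or a drugs x targets binary matrix).
#' @param pair length-2 character vector of target ids.
#' @param max_targets maximum annotated targets for an admissible drug.
#' @return data.frame with columns `drug1`, `drug2`.
#' @export
filter_specific_drugs <- function(annotation, pair, max_targets = 3L) {
  ann <- as_target_list(annotation)
  admissible <- function(t)
    names(ann)[vapply(ann, function(ts)
      t %in% ts && length(ts) <= max_targets, logical(1))]
  d1 <- admissible(pair[1L]); d2 <- admissible(pair[2L])
  out <- expand.grid(drug1 = d1, drug2 = d2, stringsAsFactors = FALSE)
  out <- out[out$drug1 != out$drug2, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < 3L)
    warning(sprintf("only %d admissible drug pair(s) for %s/%s",
                    nrow(out), pair[1L], pair[2L]))
  out
}

# Accept either a drugs x targets 0/1 matrix or a named list of target sets.
as_target_list <- function(annotation) {
  if (is.matrix(annotation))
    return(apply(annotation, 1L, function(r)
      colnames(annotation)[r != 0], simplify = FALSE))
  stop_if_not(is.list(annotation) && !is.null(names(annotation)),
              "annotation must be a binary matrix or named list")
  annotation
}

# Expand records to canonical target pairs via the annotation.
records_target_pairs <- function(records, annotation) {
  ann <- as_target_list(annotation)
  out <- lapply(seq_len(nrow(records)), function(k) {
    t1 <- ann[[records$drug1[k]]]; t2 <- ann[[records$drug2[k]]]
    if (is.null(t1) || is.null(t2)) return(NULL)
    g <- expand.grid(a = t1, b = t2, stringsAsFactors = FALSE)
    g <- g[g$a != g$b, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    data.frame(pair = unique(canonical_pair(g$a, g$b)), row = k)
  })
  do.call(rbind, out)
}

#' Eligibility report for target pairs
#'
#' A target pair is eligible for stratification when (1) its top observed
#' synergy exceeds 20 (strict), (2) after dropping cells tested with fewer
#' than two distinct drug combinations, (3) at least 10 cells remain.
#'
#' @param records synergy records data.frame (`drug1`, `drug2`, `cell`,
#'   `synergy`).
#' @param annotation drug -> targets annotation (matrix or named list).
#' @param min_cells,min_combos,synergy_threshold the three rule parameters.
#' @return data.frame per target pair: `pair`, `max_synergy`,
#'   `n_cells_retained`, `eligible`, and a `cells` list-column of retained
#'   cell ids.
#' @export
eligible_target_pairs <- function(records, annotation, min_cells = 10L,
                                  min_combos = 2L, synergy_threshold = 20) {
  stop_if_not(nrow(records) > 0, "no synergy records")
  map <- records_target_pairs(records, annotation)
  stop_if_not(!is.null(map) && nrow(map) > 0,
              "no record maps to an annotated target pair")
  out <- lapply(split(map$row, map$pair), function(rows) {
    rec <- records[rows, , drop = FALSE]
    combo <- paste(pmin(rec$drug1, rec$drug2), pmax(rec$drug1, rec$drug2))
    n_combos <- tapply(combo, rec$cell, function(x) length(unique(x)))
    retained <- names(n_combos)[n_combos >= min_combos]
    data.frame(max_synergy = max(rec$synergy),
               n_cells_retained = length(retained),
               eligible = max(rec$synergy) > synergy_threshold &&
                 length(retained) >= min_cells,
               cells = I(list(retained)))
  })
  res <- do.call(rbind, out)
  res <- data.frame(pair = names(out), res, row.names = NULL)
  res
}

#' Aggregate observed synergy for one target pair
#'
#' `level = "pair_top3"`: mean of the three largest synergy scores among
#' the pair's drug1-drug2-cell triplets (all records if fewer than three,
#' with a warning). `level = "per_cell_mean"`: per-cell mean over that
#' cell's drug combinations.
#'
#' @param records synergy records for the pair of interest.
#' @param level aggregation level.
#' @return a single number (`pair_top3`) or a named per-cell vector.
#' @export
aggregate_observed_synergy <- function(records,
                                       level = c("pair_top3",
                                                 "per_cell_mean")) {
  level <- match.arg(level)
  stop_if_not(nrow(records) > 0, "no records for the requested pair")
  if (level == "pair_top3") {
    s <- sort(records$synergy, decreasing = TRUE)
    if (length(s) < 3L)
      warning(sprintf("only %d record(s); averaging all of them", length(s)))
    return(mean(head(s, 3L)))
  }
  vapply(split(records$synergy, records$cell), mean, numeric(1))
}

#' Select Delta PA group sizes by leave-one-out cross-validation
#'
#' For each candidate (N, M) in {1,2,3}^2 the spec is built from the fixed
#' rankings, each cell is left out in turn and its Delta PA predicted, and
#' the Pearson r between LOOCV predictions and observed per-cell synergy is
#' recorded. The (N, M) maximizing r wins; ties break towards smaller
#' N + M, then smaller N. Candidates with constant predictions are skipped
#' with a warning. Note that because Delta PA has no parameters fitted to
#' the training cells once the rankings are fixed, the held-out prediction
#' coincides with the full-data prediction; cross-validation here selects
#' among group sizes only.
#'
#' @param rankings a [rank_pathways()] result.
#' @param pa standardized activity matrix covering the observed cells.
#' @param genomics optional cells x markers binary matrix.
#' @param observed named per-cell observed synergy vector (>= 3 cells).
#' @param genomics_terms,literature_pathways passed to [build_model_spec()].
#' @return list with `n_sensitive`, `m_resistant`, `loocv_r`, `spec`,
#'   `predictions`, and the full candidate `table`.
#' @export
select_group_sizes_loocv <- function(rankings, pa, genomics = NULL,
                                     observed, genomics_terms = numeric(),
                                     literature_pathways = NULL) {
  stop_if_not(length(observed) >= 3L, "need >= 3 cells with observed synergy")
  cells <- intersect(names(observed), rownames(pa))
  stop_if_not(length(cells) >= 3L, "fewer than 3 observed cells have activities")
  obs <- observed[cells]
  grid <- expand.grid(N = 1:3, M = 1:3)
  rows <- list(); preds <- list()
  for (k in seq_len(nrow(grid))) {
    spec <- build_model_spec(rankings, grid$N[k], grid$M[k],
                             genomics_terms = genomics_terms,
                             literature_pathways = literature_pathways)
    # per-cell pure: the held-out cell's prediction equals its full-data
    # Delta PA, so one vectorized evaluation gives all LOOCV predictions
    pa_sub <- structure(pa[cells, , drop = FALSE],
                        standardized = attr(pa, "standardized"))
    pred <- unclass(delta_pa(spec, pa_sub, genomics = genomics))
    if (sd(pred) == 0) {
      warning(sprintf("candidate (N=%d, M=%d): constant predictions, skipped",
                      grid$N[k], grid$M[k]))
      r <- NA_real_
    } else r <- cor(pred, obs)
    rows[[k]] <- data.frame(N = grid$N[k], M = grid$M[k], r = r)
    preds[[k]] <- pred
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$r))
  stop_if_not(length(ok) > 0, "no valid candidate: all correlations undefined")
  best <- ok[order(-tab$r[ok], tab$N[ok] + tab$M[ok], tab$N[ok])][1L]
  spec <- build_model_spec(rankings, tab$N[best], tab$M[best],
                           genomics_terms = genomics_terms,
                           literature_pathways = literature_pathways)
  list(n_sensitive = tab$N[best], m_resistant = tab$M[best],
       loocv_r = tab$r[best], spec = spec,
       predictions = preds[[best]], table = tab)
}
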