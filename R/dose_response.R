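# Monotherapy Hill curves, the Loewe additivity surface on a dose grid,
# and the observed-minus-expected volume synergy score.

#' Evaluate a Hill viability curve
#'
#' `v(d) = e_inf + (1 - e_inf) / (1 + (d / ec50)^slope)`, with untreated
#' viability fixed at 1 (`v(0) = 1`).
#'
#' @param curve a [fit_hill()] object (or list with `e_inf`, `ec50`,
#'   `slope`).
#' @param dose dose vector (>= 0).
#' @return viability fractions.
#' @export
hill_viability <- function(curve, dose) {
  ifelse(dose <= 0, 1,
         curve$e_inf + (1 - curve$e_inf) / (1 + (dose / curve$ec50)^curve$slope))
}

# Inverse: dose producing viability E, defined for E in (e_inf, 1).
hill_inverse <- function(curve, E) {
  curve$ec50 * ((1 - curve$e_inf) / (E - curve$e_inf) - 1)^(1 / curve$slope)
}

#' Fit a Hill curve to monotherapy dose-response data
#'
#' Bounded least squares of
#' `v(d) = e_inf + (1 - e_inf)/(1 + (d/ec50)^slope)` with `e_inf` in
#' [0, 1), `ec50 > 0` (searched in log space) and `slope > 0`, from
#' several starting points. Flat data (no measurable response) is flagged
#' `no_response` with the EC50 pushed to the search bound.
#'
#' @param doses positive dose vector (>= 3 distinct doses).
#' @param viabilities viability fractions at those doses.
#' @return a `hill_curve` list: `e_inf`, `ec50`, `slope`, `e0 = 1`,
#'   `rmse`, `no_response`.
#' @export
fit_hill <- function(doses, viabilities) {
  keep <- doses > 0
  doses <- doses[keep]; viabilities <- viabilities[keep]
  stop_if_not(length(unique(doses)) >= 3L, "need >= 3 positive doses")
  stop_if_not(all(is.finite(viabilities)), "viabilities must be finite")
  lec_lo <- log(min(doses)) - log(1e4)
  lec_hi <- log(max(doses)) + log(1e4)
  obj <- function(par) {
    cv <- list(e_inf = par[1L], ec50 = exp(par[2L]), slope = exp(par[3L]))
    sum((viabilities - hill_viability(cv, doses))^2)
  }
  starts <- list()
  e0 <- max(0, min(min(viabilities), 0.99))
  mid_dose <- doses[which.min(abs(viabilities - (1 + e0) / 2))]
  for (sl in c(1, 0.5, 2))
    starts[[length(starts) + 1L]] <- c(e0, log(mid_dose), log(sl))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, obj, method = "L-BFGS-B",
            lower = c(0, lec_lo, log(0.05)),
            upper = c(0.9999, lec_hi, log(20)),
            control = list(factr = 1e3, maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  stop_if_not(!is.null(best), "Hill fit did not converge")
  par <- best$par
  curve <- structure(list(e_inf = par[1L], ec50 = exp(par[2L]),
                          slope = exp(par[3L]), e0 = 1,
                          rmse = sqrt(best$value / length(doses)),
                          no_response = FALSE),
                     class = "hill_curve")
  span <- 1 - hill_viability(curve, max(doses))
  if (span < 0.01 || par[2L] > lec_hi - 1e-6) curve$no_response <- TRUE
  curve
}

#' Loewe additivity surface for a dose grid
#'
#' For each positive dose pair (d1, d2) the expected viability E solves
#' the dose-equivalence index equation `d1/D1(E) + d2/D2(E) = 1`, where
#' `Di(E)` is drug i's inverse Hill curve; the root is found by bisection
#' on the achievable effect interval. Margins (a zero dose) reproduce the
#' monotherapy curves exactly. Where the additive effect is unreachable
#' (below one drug's lower asymptote), E is clamped to the boundary and
#' the cell is flagged.
#'
#' @param curve1,curve2 [fit_hill()] curves.
#' @param doses_1,doses_2 ascending dose vectors; a leading 0 is added if
#'   absent so margins are always present.
#' @return a `dose_surface` list: `doses_1`, `doses_2`, `values`
#'   (viability matrix), `clamped` (logical matrix), `index_residual`
#'   (|d1/D1 + d2/D2 - 1| at interior cells).
#' @export
loewe_surface <- function(curve1, curve2, doses_1, doses_2) {
  doses_1 <- sort(unique(c(0, doses_1)))
  doses_2 <- sort(unique(c(0, doses_2)))
  n1 <- length(doses_1); n2 <- length(doses_2)
  V <- matrix(NA_real_, n1, n2,
              dimnames = list(paste0("d1_", signif(doses_1, 6)),
                              paste0("d2_", signif(doses_2, 6))))
  clamped <- matrix(FALSE, n1, n2)
  resid <- matrix(NA_real_, n1, n2)
  lo0 <- max(curve1$e_inf, curve2$e_inf)
  eps <- 1e-12
  index_f <- function(E, d1, d2)
    d1 / hill_inverse(curve1, E) + d2 / hill_inverse(curve2, E) - 1
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    d1 <- doses_1[i]; d2 <- doses_2[j]
    if (d1 == 0 && d2 == 0) { V[i, j] <- 1; next }
    if (d2 == 0) { V[i, j] <- hill_viability(curve1, d1); next }
    if (d1 == 0) { V[i, j] <- hill_viability(curve2, d2); next }
    lo <- lo0 + eps; hi <- 1 - eps
    f_lo <- index_f(lo, d1, d2)
    if (!is.finite(f_lo) || f_lo >= 0) {
      V[i, j] <- lo0; clamped[i, j] <- TRUE
      resid[i, j] <- if (is.finite(f_lo)) abs(f_lo) else NA_real_
      next
    }
    for (k in 1:200) {            # f increasing in E; bisect to fp limit
      mid <- 0.5 * (lo + hi)
      if (mid == lo || mid == hi) break
      if (index_f(mid, d1, d2) < 0) lo <- mid else hi <- mid
    }
    E <- 0.5 * (lo + hi)
    V[i, j] <- E
    resid[i, j] <- abs(index_f(E, d1, d2))
  }
  structure(list(doses_1 = doses_1, doses_2 = doses_2, values = V,
                 clamped = clamped, index_residual = resid),
            class = "dose_surface")
}

#' Build a dose surface from measured viabilities
#'
#' @param doses_1,doses_2 ascending dose vectors including 0.
#' @param values viability matrix (rows = doses_1, cols = doses_2);
#'   values between 0 and 1.5 (mild assay noise above 1 tolerated).
#' @return a `dose_surface`.
#' @export
dose_surface <- function(doses_1, doses_2, values) {
  values <- as.matrix(values)
  stop_if_not(nrow(values) == length(doses_1) &&
                ncol(values) == length(doses_2), "grid/value shape mismatch")
  stop_if_not(0 %in% doses_1 && 0 %in% doses_2,
              "zero-dose margins must be present")
  stop_if_not(all(values >= 0 & values <= 1.5),
              "viabilities must lie in [0, 1.5]")
  structure(list(doses_1 = sort(doses_1), doses_2 = sort(doses_2),
                 values = values, clamped = NULL, index_residual = NULL),
            class = "dose_surface")
}

#' Loewe excess-volume synergy score
#'
#' `score = 100 * mean(expected - observed)` over the non-margin cells
#' (both doses positive). Positive scores mean the combination kills more
#' than Loewe additivity predicts (synergy); the mean (rather than sum)
#' makes the score independent of grid size, landing clearly synergistic
#' surfaces near the conventional > 20 threshold.
#'
#' @param observed,expected `dose_surface` objects on identical grids.
#' @return numeric score with attribute `n_cells`.
#' @export
synergy_volume <- function(observed, expected) {
  stop_if_not(isTRUE(all.equal(observed$doses_1, expected$doses_1)) &&
                isTRUE(all.equal(observed$doses_2, expected$doses_2)),
              "dose grids differ")
  interior <- outer(observed$doses_1 > 0, observed$doses_2 > 0, `&`)
  diff <- expected$values[interior] - observed$values[interior]
  structure(100 * mean(diff), n_cells = sum(interior))
}
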