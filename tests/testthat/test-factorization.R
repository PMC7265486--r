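fast_cfg <- function(...) {
  macau_config(L = 5, n_burnin = 60, n_samples = 120, n_repeats = 1,
               seed = 1, ...)
}

test_that("response_matrix enforces its invariants", {
  y <- matrix(rnorm(12), 3, 4)
  expect_s3_class(response_matrix(y), "response_matrix")
  y[1, ] <- NA
  expect_error(response_matrix(y), "drug row")
  y2 <- matrix(rnorm(12), 3, 4); y2[, 2] <- NA
  expect_error(response_matrix(y2), "cell column")
  y3 <- matrix(rnorm(12), 3, 4); y3[1, 1] <- Inf
  expect_error(response_matrix(y3), "finite")
})

test_that("noiseless rank-1 matrix is reconstructed", {
  set.seed(4)
  y <- outer(rnorm(20, 1), rnorm(30, 1))
  cfg <- macau_config(L = 1, n_burnin = 100, n_samples = 200, seed = 2)
  fit <- fit_macau(response_matrix(y), NULL, NULL, cfg, standardize = FALSE)
  rmse <- sqrt(mean((fit$yhat_mean - y)^2))
  expect_lt(rmse, 0.05 * sd(y))
})

test_that("fit is deterministic given the seed and rejects NaN side info", {
  truth <- tiny_truth()
  panel <- tiny_panel(truth)
  pa <- score_pathways(panel$expression, truth$pathway_weights_true,
                       standardize = TRUE)
  f1 <- fit_macau(panel$response, panel$target_annotation, unclass(pa),
                  fast_cfg())
  f2 <- fit_macau(panel$response, panel$target_annotation, unclass(pa),
                  fast_cfg())
  expect_identical(f1$interaction_mean, f2$interaction_mean)

  bad <- unclass(pa); bad[1, 1] <- NaN
  expect_error(fit_macau(panel$response, panel$target_annotation, bad,
                         fast_cfg()), "NA in cell side")
})

test_that("relabeling cells permutes V and leaves the link estimate alone", {
  truth <- tiny_truth()
  panel <- tiny_panel(truth, n_cells = 25)
  pa <- unclass(score_pathways(panel$expression,
                               truth$pathway_weights_true, TRUE))
  cfg <- macau_config(L = 5, n_burnin = 200, n_samples = 800, seed = 1)
  f1 <- fit_macau(panel$response, panel$target_annotation, pa, cfg)
  perm <- sample(ncol(panel$response))
  f2 <- fit_macau(panel$response[, perm], panel$target_annotation,
                  pa[perm, ], cfg)
  expect_gt(cor(as.vector(f1$interaction_mean),
                as.vector(f2$interaction_mean)), 0.99)
})

test_that("interaction extraction honours the orientation contract", {
  truth <- tiny_truth()
  panel <- tiny_panel(truth)
  pa <- unclass(score_pathways(panel$expression,
                               truth$pathway_weights_true, TRUE))
  fit <- fit_macau(panel$response, panel$target_annotation, pa, fast_cfg())
  I_ic50 <- interaction_matrix(fit)
  expect_equal(unclass(I_ic50), -fit$interaction_mean,
               ignore_attr = TRUE)
  # sensitivity orientation: no negation
  ys <- response_matrix(unclass(panel$response), orientation = "sensitivity")
  fit2 <- fit_macau(ys, panel$target_annotation, pa, fast_cfg())
  expect_equal(unclass(interaction_matrix(fit2)), fit2$interaction_mean,
               ignore_attr = TRUE)
  # positive entries mean sensitization: recovery of the true signs
  expect_gt(cor(as.vector(unclass(I_ic50)),
                as.vector(truth$interaction_true)), 0.5)
})

test_that("averaged_interactions derives distinct seeds and averages", {
  truth <- tiny_truth()
  panel <- tiny_panel(truth, n_cells = 20)
  pa <- unclass(score_pathways(panel$expression,
                               truth$pathway_weights_true, TRUE))
  seeds <- derive_seeds(99, 40)
  expect_false(any(duplicated(seeds)))
  expect_true(all(seeds < 2^31))

  cfg <- fast_cfg(); cfg$n_repeats <- 1L; cfg$seed <- 99L
  avg1 <- averaged_interactions(panel$response, panel$target_annotation,
                                pa, cfg)
  cfg_direct <- fast_cfg(); cfg_direct$seed <- derive_seeds(99, 1)[1L]
  direct <- interaction_matrix(
    fit_macau(panel$response, panel$target_annotation, pa, cfg_direct))
  expect_equal(unclass(avg1), unclass(direct), ignore_attr = TRUE)
  expect_identical(attr(avg1, "n_chains_averaged"), 1L)

  cfg4 <- fast_cfg(); cfg4$n_repeats <- 4L
  avg4 <- averaged_interactions(panel$response, panel$target_annotation,
                                pa, cfg4, return_chains = TRUE)
  chains <- attr(avg4, "chains")
  expect_length(chains, 4L)
  expect_equal(unclass(avg4),
               Reduce(`+`, lapply(chains, unclass)) / 4, ignore_attr = TRUE)
})

test_that("averaging chains reduces Monte-Carlo variance", {
  # 8 single chains vs 8 averages of 4: entrywise variance must drop
  truth <- tiny_truth()
  panel <- tiny_panel(truth, n_cells = 20)
  pa <- unclass(score_pathways(panel$expression,
                               truth$pathway_weights_true, TRUE))
  run_one <- function(seed) {
    cfg <- fast_cfg(); cfg$seed <- seed
    unclass(interaction_matrix(
      fit_macau(panel$response, panel$target_annotation, pa, cfg,
                keep_samples = FALSE)))
  }
  singles <- lapply(derive_seeds(5, 8), run_one)
  quads <- lapply(derive_seeds(6, 8), function(s) {
    mats <- lapply(derive_seeds(s, 4), run_one)
    Reduce(`+`, mats) / 4
  })
  var_of <- function(mats) {
    arr <- simplify2array(mats)
    mean(apply(arr, c(1, 2), var))
  }
  expect_gt(var_of(singles), var_of(quads))
})

test_that("stability report behaves on identical and noisy inputs", {
  truth <- tiny_truth()
  I0 <- truth$interaction_true
  same <- replicate(6, I0, simplify = FALSE)
  rep_same <- stability_report(same, subsample_size = 3, n_draws = 10)
  expect_equal(rep_same$mean_pairwise_r, 1, tolerance = 1e-12)
  expect_true(all(rep_same$similarity_cv < 1e-12))

  set.seed(8)
  noisy <- replicate(16, I0 + matrix(rnorm(length(I0), sd = 0.8), nrow(I0)),
                     simplify = FALSE)
  rs <- vapply(c(2, 4, 8), function(k)
    stability_report(noisy, k, n_draws = 30, seed = 1)$mean_pairwise_r,
    numeric(1))
  expect_true(all(diff(rs) > 0))

  expect_error(stability_report(same[1], 1), ">= 2")
  expect_error(stability_report(same, 3, n_draws = 1), "n_draws")
  expect_error(stability_report(same, 7), "exceeds")
})

test_that("prediction from side information works and is linear", {
  truth <- tiny_truth()
  panel <- tiny_panel(truth, n_cells = 25, noise_sd = 0.05)
  pa <- unclass(score_pathways(panel$expression,
                               truth$pathway_weights_true, TRUE))
  fit <- fit_macau(panel$response, panel$target_annotation, pa, fast_cfg())
  pred <- predict_response(fit, pa[1:5, , drop = FALSE])
  for (j in 1:5)
    expect_gt(cor(pred[, j], panel$response[, j]), 0.9)
  expect_error(predict_response(fit, pa[, 1:3]), "missing pathway")

  # with mu_v fixed at zero, predictions are linear in the side info
  cfg0 <- macau_config(L = 3, n_burnin = 40, n_samples = 60,
                       sample_hyper = FALSE, mu_u = 0, mu_v = 0,
                       prec_fixed = 2, seed = 3)
  fit0 <- fit_macau(panel$response, panel$target_annotation, pa, cfg0,
                    standardize = FALSE)
  x <- pa[2, , drop = FALSE]
  expect_equal(predict_response(fit0, 3 * x),
               3 * predict_response(fit0, x), tolerance = 1e-10,
               ignore_attr = TRUE)
  zero <- predict_response(fit0, 0 * x)
  expect_true(all(abs(zero) < 1e-12))
})

test_that("swapping drug and cell axes transposes the interaction estimate", {
  truth <- tiny_truth()
  panel <- generate_panel(truth, n_drugs = 8, n_cells = 30, noise_sd = 0.1,
                          seed = 31)
  pa <- unclass(score_pathways(panel$expression,
                               truth$pathway_weights_true, TRUE))
  cfg <- fast_cfg()
  f1 <- fit_macau(panel$response, panel$target_annotation, pa, cfg,
                  standardize = FALSE)
  f2 <- fit_macau(t(unclass(panel$response)), pa, panel$target_annotation,
                  cfg, standardize = FALSE)
  expect_gt(cor(as.vector(f1$interaction_mean),
                as.vector(t(f2$interaction_mean))), 0.8)
})
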