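# Helper: a small pipeline state (diversity, ordination, covariates, ratio)
# from one simulated experiment, for predictor assembly.
sim_state <- function(seed = 1, n_replicates = 2L) {
  sim <- simulate_experiment(small_scenario(seed = seed,
                                            n_replicates = n_replicates))
  div <- repeated_rarefaction(sim$counts, n_iter = 20,
                              seed = seed_stream(seed, "div"))
  ord <- pcoa(bray_curtis_matrix(sim$counts))
  rel <- aggregate_rank(sim$counts, "phylum")
  pa <- phylum_ratio(rel, "Proteobacteria", "Actinobacteriota")
  list(sim = sim, div = div, ord = ord, pa = pa)
}

test_that("predictor assembly follows the response-specific scheme", {
  st <- sim_state(seed = 2)
  X_nit <- assemble_predictors(st$div, st$ord, st$sim$proc, st$pa,
                               response = "nitrification")
  expect_true(all(c("aoa", "aob") %in% colnames(X_nit)))
  X_cmin <- assemble_predictors(st$div, st$ord, st$sim$proc, st$pa,
                                response = "c_mineralization")
  expect_false(any(c("aoa", "aob") %in% colnames(X_cmin)))
  expect_true(all(c("richness", "shannon", "PCoA1", "PCoA2", "PCoA3",
                    "biomass", "proteo_actino_ratio") %in% colnames(X_cmin)))
  # constant column is dropped with a warning naming it
  proc2 <- st$sim$proc
  proc2$tetw <- 5
  expect_warning(X2 <- assemble_predictors(st$div, st$ord, proc2, st$pa,
                                           response = "sir"),
                 "tetw")
  expect_false("tetw" %in% colnames(X2))
  # genus variant appends the supplied genus columns
  grel <- aggregate_rank(st$sim$counts, "genus")
  gsub <- grel[, 1:6]
  colnames(gsub) <- paste0("genus_", colnames(gsub))
  X3 <- assemble_predictors(st$div, st$ord, st$sim$proc, st$pa,
                            response = "sir", variant = "genus",
                            genus_rel = gsub)
  expect_true(all(colnames(gsub) %in% colnames(X3)))
  # too few rows errors
  expect_error(assemble_predictors(st$div[1:4, ], st$ord, st$sim$proc, st$pa,
                                   response = "sir"),
               "fewer than 10")
})

test_that("mtry tuning minimizes OOB error deterministically", {
  set.seed(4)
  n <- 200
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 3 * X$x1 + rnorm(n, 0, 0.1)
  fit <- tune_and_fit(X, y, n_trees = 300, seed = 5)
  expect_equal(nrow(fit$tuning), 3)
  expect_equal(fit$tuning$oob_mse[fit$mtry], min(fit$tuning$oob_mse))
  # near-deterministic signal: OOB R2 above 0.8
  expect_gt(1 - fit$oob_mse / var(y) / ((n - 1) / n), 0.8)
  fit2 <- tune_and_fit(X, y, n_trees = 300, seed = 5)
  expect_identical(fit$tuning, fit2$tuning)
  expect_equal(fit$oob_mse, fit2$oob_mse)
  # single predictor: grid is {1}
  f1 <- tune_and_fit(X[, 1, drop = FALSE], y, n_trees = 100, seed = 1)
  expect_equal(f1$tuning$mtry, 1)
  expect_error(tune_and_fit(X, rep(1, n), n_trees = 100), "constant response")
  expect_error(tune_and_fit(X, y, n_trees = 10), ">= 100")
})

test_that("permutation importance is OOB-evaluated and matches a manual oracle", {
  set.seed(6)
  n <- 30
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- 2 * X$x1 + rnorm(n, 0, 0.2)
  fit <- tune_and_fit(X, y, n_trees = 100, seed = 2)
  imp <- permutation_importance(fit, X, y, n_shuffles = 1, seed = 9)

  # manual oracle: recompute the shuffled OOB error from the per-tree
  # predictions and inbag matrix, independent of the package's helper
  model <- fit$model
  oob <- model$inbag == 0
  oob_mse <- function(Xq) {
    pred <- predict(model, newdata = Xq, predict.all = TRUE)$individual
    mean((rowSums(pred * oob) / rowSums(oob) - y)^2)
  }
  base <- oob_mse(X)
  for (pn in colnames(X)) {
    Xp <- X
    set.seed(seed_stream(9, "shuffle", pn, 1))
    Xp[[pn]] <- sample(X[[pn]])
    manual <- oob_mse(Xp) - base
    expect_equal(imp$importance[imp$predictor == pn], manual, tolerance = 1e-10)
  }
  # determinism
  imp2 <- permutation_importance(fit, X, y, n_shuffles = 1, seed = 9)
  expect_identical(as.data.frame(imp), as.data.frame(imp2))
})

test_that("planted signal ranks first and pure noise stays near zero", {
  first <- 0L
  noise_imps <- numeric(0)
  for (s in 1:10) {
    set.seed(40 + s)
    n <- 120
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
    y <- 3 * X$x1 + 0.5 * X$x2 + rnorm(n, 0, 0.3)
    fit <- tune_and_fit(X, y, n_trees = 200, seed = s)
    imp <- permutation_importance(fit, X, y, n_shuffles = 5, seed = s)
    first <- first + (imp$predictor[imp$rank == 1] == "x1")
    noise_imps <- c(noise_imps, imp$importance[imp$predictor == "noise"])
  }
  expect_gte(first, 9)
  # the null predictor's mean importance is within 2 se of zero
  expect_lt(abs(mean(noise_imps)),
            2 * sd(noise_imps) / sqrt(length(noise_imps)) + 1e-8)
})

test_that("importance is invariant to affine rescaling of a predictor", {
  set.seed(7)
  n <- 60
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- X$x1 + 0.5 * X$x2 + rnorm(n, 0, 0.2)
  fit <- tune_and_fit(X, y, n_trees = 200, seed = 3)
  imp <- permutation_importance(fit, X, y, n_shuffles = 3, seed = 4)
  X2 <- X
  X2$x2 <- X$x2 * 1000 - 5
  fit2 <- tune_and_fit(X2, y, n_trees = 200, seed = 3)
  imp2 <- permutation_importance(fit2, X2, y, n_shuffles = 3, seed = 4)
  # trees split on rank order, so rescaling changes nothing materially
  expect_equal(imp$importance, imp2$importance, tolerance = 0.15)
  expect_equal(imp$predictor[imp$rank == 1], imp2$predictor[imp2$rank == 1])
})

test_that("run_all_models produces one ranked result per response", {
  st <- sim_state(seed = 9)
  ft <- function_table(st$sim$proc)
  mf <- multifunctionality(ft)
  cfg <- run_config(n_trees = 120, n_shuffles = 2, seed = 11)
  res <- run_all_models(ft, mf, st$div, st$ord, st$sim$proc, st$pa,
                        config = cfg)
  expect_length(res, 7)
  expect_true("multifunctionality" %in% names(res))
  for (r in res) {
    expect_s3_class(r, "importance_result")
    expect_setequal(r$rank, seq_len(nrow(r)))
  }
  comb <- attr(res, "combined")
  expect_equal(sort(unique(comb$response)), sort(names(res)))
  expect_lte(nrow(top_predictors(res[[1]])), 6)
  # a degenerate response is isolated, not fatal
  ft2 <- ft
  ft2$sir <- 1
  expect_warning(res2 <- run_all_models(ft2, NULL, st$div, st$ord,
                                        st$sim$proc, st$pa, config = cfg),
                 "sir")
  expect_null(res2$sir)
  expect_s3_class(res2$c_mineralization, "importance_result")
})
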