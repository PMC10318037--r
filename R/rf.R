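# Random-forest ranking of microbial predictors of ecosystem functions.
# The forest learner is randomForest; the mtry tuning loop and the
# whole-dataset shuffle permutation importance (evaluated strictly
# out-of-bag) are implemented here. "Model error" is always the OOB mean
# squared error: each sample is predicted only by trees whose bootstrap
# sample excluded it, for both tuning and importance, so shuffling a
# predictor cannot be rewarded for overfitting.

#' Assemble the candidate predictor matrix for one response
#'
#' The standard candidate set is: ASV richness, Shannon diversity, the
#' first `k` PCoA axis scores (community membership), microbial biomass,
#' DNA yield, 16S gene abundance, community-mean 16S operon number, tetW
#' and tetM abundances, and the Proteobacteria:Actinobacteria ratio.
#' Nitrifier abundances (AOA, AOB) are added only when the response is
#' nitrification; genus relative abundances are appended only in the
#' `"genus"` variant. Zero-variance columns are dropped with a warning.
#'
#' @param diversity Result of [repeated_rarefaction()].
#' @param ord Result of [pcoa()] on the community dissimilarity matrix.
#' @param covariates Data frame with `sample_id`, `biomass`, `dna_yield`,
#'   `abund_16s`, `mean_operon_number`, `tetw`, `tetm`, and (for
#'   nitrification) `aoa`, `aob`.
#' @param pa_ratio Named per-sample Proteobacteria:Actinobacteria ratio
#'   (from [phylum_ratio()]).
#' @param response Response name (`"nitrification"` switches in AOA/AOB).
#' @param k_axes Number of PCoA axes offered (default 3).
#' @param variant `"primary"` or `"genus"`.
#' @param genus_rel Optional relative-abundance matrix whose columns are
#'   appended in the `"genus"` variant.
#' @return Numeric matrix, rows keyed by sample id, one column per
#'   candidate predictor.
#' @export
assemble_predictors <- function(diversity, ord, covariates, pa_ratio,
                                response, k_axes = 3L,
                                variant = c("primary", "genus"),
                                genus_rel = NULL) {
  variant <- match.arg(variant)
  ids <- Reduce(intersect, list(diversity$sample_id,
                                rownames(ord$coordinates),
                                covariates$sample_id,
                                names(pa_ratio)))
  ids <- sort(ids)
  if (length(ids) < 10) stop("fewer than 10 complete samples; a forest is not meaningful",
                             call. = FALSE)
  k <- min(k_axes, ncol(ord$coordinates))
  div <- diversity[match(ids, diversity$sample_id), ]
  cov <- covariates[match(ids, covariates$sample_id), ]
  X <- cbind(richness = div$mean_richness,
             shannon = div$mean_shannon,
             ord$coordinates[ids, seq_len(k), drop = FALSE],
             biomass = cov$biomass,
             dna_yield = cov$dna_yield,
             abund_16s = cov$abund_16s,
             mean_operon_number = cov$mean_operon_number,
             tetw = cov$tetw,
             tetm = cov$tetm,
             proteo_actino_ratio = pa_ratio[ids])
  if (response == "nitrification") {
    X <- cbind(X, aoa = cov$aoa, aob = cov$aob)
  }
  if (variant == "genus") {
    if (is.null(genus_rel)) stop("genus variant requires genus_rel", call. = FALSE)
    X <- cbind(X, genus_rel[ids, , drop = FALSE])
  }
  rownames(X) <- ids
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (any(!keep)) {
    warning("dropping zero-variance predictor(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  cc <- stats::complete.cases(X)
  if (sum(cc) < 10) stop("fewer than 10 complete rows after filtering", call. = FALSE)
  X[cc, , drop = FALSE]
}

#' Tune mtry by OOB error and fit the final forest
#'
#' Fits one forest per candidate value of mtry (1..P), records the OOB mean
#' squared error at full tree count, and refits at the minimizer (ties go
#' to the smallest mtry). Each fit uses a deterministic substream of
#' `seed`.
#'
#' @param X Predictor matrix (samples x predictors).
#' @param y Numeric response aligned with `X`.
#' @param n_trees Trees per forest (default 10000; reduce for exploratory
#'   runs — tree count affects only Monte-Carlo noise).
#' @param seed Base seed.
#' @return List of class `rf_fit`: `model` (randomForest with inbag
#'   records), `mtry`, `oob_mse`, `tuning` (data frame mtry x oob_mse),
#'   `n_trees`, `seed`.
#' @export
tune_and_fit <- function(X, y, n_trees = 10000L, seed = 1L) {
  if (n_trees < 100) stop("n_trees must be >= 100", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response cannot be modelled", call. = FALSE)
  X <- as.data.frame(X)
  P <- ncol(X)
  oob <- vapply(seq_len(P), function(m) {
    fit <- with_seed(seed_stream(seed, "tune", m), {
      randomForest::randomForest(x = X, y = y, mtry = m, ntree = n_trees)
    })
    fit$mse[n_trees]
  }, numeric(1))
  best <- which.min(oob) # which.min takes the first (smallest mtry) on ties
  model <- with_seed(seed_stream(seed, "fit", best), {
    randomForest::randomForest(x = X, y = y, mtry = best, ntree = n_trees,
                               keep.forest = TRUE, keep.inbag = TRUE)
  })
  out <- list(model = model, mtry = best, oob_mse = model$mse[n_trees],
              tuning = data.frame(mtry = seq_len(P), oob_mse = oob),
              n_trees = n_trees, seed = seed)
  class(out) <- "rf_fit"
  out
}

# OOB predictions for (possibly permuted) data: per-tree predictions
# averaged over the trees that did not see each sample in their bootstrap.
oob_predict <- function(model, X) {
  pred <- stats::predict(model, newdata = as.data.frame(X),
                         predict.all = TRUE)$individual
  oob <- model$inbag == 0
  rowSums(pred * oob) / rowSums(oob)
}

#' Whole-dataset shuffle permutation importance (OOB-evaluated)
#'
#' Importance of a predictor is the mean increase in OOB mean squared error
#' after randomly shuffling that predictor's column across the data set
#' (all other columns fixed), over `n_shuffles` independent permutations.
#' Raw (possibly negative) importances are retained; ranks are computed on
#' values clamped at zero.
#'
#' @param fit An [tune_and_fit()] result.
#' @param X,y The training data.
#' @param n_shuffles Permutations per predictor (default 30).
#' @param seed Base seed.
#' @return Data frame of class `importance_result`, sorted by rank:
#'   `predictor`, `importance` (raw mean error increase), `rank`;
#'   attributes `baseline_mse`, `mtry`, `n_trees`, `n_shuffles`, `seed`,
#'   `tuning`.
#' @export
permutation_importance <- function(fit, X, y, n_shuffles = 30L, seed = 1L) {
  stopifnot(inherits(fit, "rf_fit"))
  X <- as.matrix(X)
  baseline <- mean((oob_predict(fit$model, X) - y)^2)
  imp <- vapply(colnames(X), function(pn) {
    errs <- vapply(seq_len(n_shuffles), function(s) {
      Xp <- X
      Xp[, pn] <- with_seed(seed_stream(seed, "shuffle", pn, s), {
        sample(X[, pn])
      })
      mean((oob_predict(fit$model, Xp) - y)^2)
    }, numeric(1))
    mean(errs) - baseline
  }, numeric(1))
  out <- data.frame(predictor = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-pmax(out$importance, 0), ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "baseline_mse") <- baseline
  attr(out, "mtry") <- fit$mtry
  attr(out, "n_trees") <- fit$n_trees
  attr(out, "n_shuffles") <- n_shuffles
  attr(out, "seed") <- seed
  attr(out, "tuning") <- fit$tuning
  class(out) <- c("importance_result", "data.frame")
  out
}

#' Fit tuned forests and rank predictors for every ecosystem function
#'
#' Runs one model per response: the six functions plus multifunctionality.
#' Per-response failures are isolated (warning, `NULL` entry) so one
#' degenerate response does not abort the run.
#'
#' @param funcs Function table from [function_table()].
#' @param multifunc Result of [multifunctionality()] (or `NULL` to skip).
#' @param diversity,ord,covariates,pa_ratio As in [assemble_predictors()].
#' @param config A [run_config()] supplying `n_trees`, `n_shuffles`,
#'   `pcoa_axes`, `seed`.
#' @param variant,genus_rel Passed to [assemble_predictors()].
#' @return Named list of `importance_result` (one per response); attribute
#'   `combined` is a long data frame over all responses.
#' @export
run_all_models <- function(funcs, multifunc, diversity, ord, covariates,
                           pa_ratio, config = run_config(),
                           variant = "primary", genus_rel = NULL) {
  responses <- ECOSYSTEM_FUNCTIONS
  ytab <- funcs
  if (!is.null(multifunc)) {
    ytab <- merge(funcs, multifunc, by = "sample_id")
    responses <- c(responses, "multifunctionality")
  }
  results <- stats::setNames(vector("list", length(responses)), responses)
  for (resp in responses) {
    results[[resp]] <- tryCatch({
      X <- assemble_predictors(diversity, ord, covariates, pa_ratio,
                               response = resp, k_axes = config$pcoa_axes,
                               variant = variant, genus_rel = genus_rel)
      y <- ytab[[resp]][match(rownames(X), ytab$sample_id)]
      ok <- !is.na(y)
      fit <- tune_and_fit(X[ok, , drop = FALSE], y[ok],
                          n_trees = config$n_trees,
                          seed = seed_stream(config$seed, "rf", resp))
      permutation_importance(fit, X[ok, , drop = FALSE], y[ok],
                             n_shuffles = config$n_shuffles,
                             seed = seed_stream(config$seed, "imp", resp))
    }, error = function(e) {
      warning("model for '", resp, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }
  ok <- !vapply(results, is.null, logical(1))
  combined <- do.call(rbind, lapply(names(results)[ok], function(r) {
    cbind(response = r, as.data.frame(results[[r]]))
  }))
  attr(results, "combined") <- combined
  results
}

#' Top-ranked predictors of an importance result
#' @param imp An `importance_result`.
#' @param n Number of predictors (default 6, the usual reporting cut).
#' @return The first `n` rows by rank.
#' @export
top_predictors <- function(imp, n = 6L) {
  utils::head(imp[order(imp$rank), ], n)
}
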