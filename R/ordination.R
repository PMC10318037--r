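# Principal coordinates analysis of dissimilarity matrices and a minimal
# sequential permutational multivariate ANOVA on the Gower-centered matrix.

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers -1/2 J D^2 J (J the centering matrix), eigendecomposes,
#' and scales eigenvectors by the square root of their (positive)
#' eigenvalues. Negative eigenvalues are reported, not corrected. RC-Bray
#' matrices (which carry -1 on the diagonal and possibly negative entries)
#' are first shifted by subtracting the minimum off-diagonal value and
#' zeroing the diagonal — a monotone transform that preserves rank order;
#' the applied shift is recorded in the result.
#'
#' @param d Square symmetric dissimilarity matrix with dimnames.
#' @param sym_tol Asymmetry tolerance (default 1e-8).
#' @return List of class `pcoa_result`: `coordinates` (samples x positive
#'   axes, named `PCoA1..`), `eigenvalues` (all, descending),
#'   `rel_eig` (share of positive-eigenvalue variance per positive axis),
#'   `negative_mass` (|sum of negative eigenvalues| / sum |eigenvalues|),
#'   `shift` (value subtracted from off-diagonals, 0 if none).
#' @export
pcoa <- function(d, sym_tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square", call. = FALSE)
  if (max(abs(d - t(d))) > sym_tol) {
    stop("dissimilarity matrix asymmetric beyond tolerance", call. = FALSE)
  }
  shift <- 0
  off <- d[row(d) != col(d)]
  if (length(off) && (min(off) < 0 || any(diag(d) != 0))) {
    shift <- min(off)
    d <- d - shift
    diag(d) <- 0
  }
  n <- nrow(d)
  G <- gower_center(d)
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  pos <- which(ev > max(ev[1], 0) * 1e-12 & ev > 0)
  coords <- if (length(pos)) {
    sweep(eg$vectors[, pos, drop = FALSE], 2, sqrt(ev[pos]), `*`)
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(d)
  if (ncol(coords)) colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  res <- list(coordinates = coords,
              eigenvalues = ev,
              rel_eig = if (length(pos)) ev[pos] / sum(ev[pos]) else numeric(),
              negative_mass = if (any(ev < 0)) sum(abs(ev[ev < 0])) / sum(abs(ev)) else 0,
              shift = shift)
  class(res) <- "pcoa_result"
  res
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes (first axis %.1f%% of positive variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              if (length(x$rel_eig)) 100 * x$rel_eig[1] else 0))
  if (x$shift != 0) cat(sprintf("  input shifted by %+.4g before embedding\n", -x$shift))
  invisible(x)
}

# Gower-centered inner-product matrix from a dissimilarity matrix.
gower_center <- function(d) {
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Permutational multivariate ANOVA (sequential sums of squares)
#'
#' Partitions the trace of the Gower-centered matrix sequentially over the
#' model terms; significance of each term's pseudo-F is assessed by free
#' permutation of sample rows. `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`
#' (one-sided, never exactly zero).
#'
#' @param d Square symmetric dissimilarity matrix keyed by sample ids.
#' @param meta Data frame with `sample_id` and the factor columns.
#' @param terms Character vector of metadata columns, fitted in order.
#' @param n_perm Number of permutations (default 999, minimum 99).
#' @param seed Seed for the permutation stream.
#' @return Data frame of class `permanova_result`: one row per term plus
#'   `Residual` and `Total`, with `df`, `ss`, `r2`, `f`, `p`; attributes
#'   `n_perm`, `seed`.
#' @export
permanova <- function(d, meta, terms, n_perm = 999L, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  d <- as.matrix(d)
  ids <- rownames(d)
  idx <- match(ids, meta$sample_id)
  if (anyNA(idx)) stop("metadata missing samples: ",
                       paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  mf <- meta[idx, terms, drop = FALSE]
  for (tm in terms) {
    f <- factor(mf[[tm]])
    if (nlevels(f) < 2) stop("term '", tm, "' has fewer than 2 levels", call. = FALSE)
    if (nlevels(f) == nrow(mf)) {
      stop("term '", tm, "' is confounded with sample identity (all singleton levels)",
           call. = FALSE)
    }
    mf[[tm]] <- f
  }
  n <- nrow(d)
  G <- gower_center(d)
  # hat matrices of the cumulative (sequential) model
  hats <- vector("list", length(terms))
  X <- matrix(1, n, 1)
  df_terms <- integer(length(terms))
  for (k in seq_along(terms)) {
    Xk <- cbind(X, stats::model.matrix(~ mf[[terms[k]]])[, -1, drop = FALSE])
    df_terms[k] <- ncol(Xk) - ncol(X)
    X <- Xk
    hats[[k]] <- X %*% solve(crossprod(X)) %*% t(X)
  }
  df_res <- n - ncol(X)
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)
  ss_stats <- function(Gp) {
    tr_cum <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss_total <- sum(diag(Gp))
    ss_term <- diff(c(0, tr_cum))
    ss_res <- ss_total - tr_cum[length(tr_cum)]
    f <- (ss_term / df_terms) / (ss_res / df_res)
    list(ss_term = ss_term, ss_res = ss_res, ss_total = ss_total, f = f)
  }
  obs <- ss_stats(G)
  exceed <- rep(0L, length(terms))
  with_seed(seed_stream(seed, "permanova"), {
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      fp <- ss_stats(G[p, p])$f
      exceed <- exceed + (fp >= obs$f)
    }
  })
  pval <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    ss = c(obs$ss_term, obs$ss_res, obs$ss_total),
    r2 = c(obs$ss_term, obs$ss_res, obs$ss_total) / obs$ss_total,
    f = c(obs$f, NA, NA),
    p = c(pval, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permanova_result", "data.frame")
  out
}
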