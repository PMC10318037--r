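# Bray-Curtis dissimilarity and its abundance-based Raup-Crick
# standardization (RC-Bray). Observed Bray-Curtis is ranked within a null
# distribution of dissimilarities between probabilistically assembled
# communities that preserve each sample's richness and total abundance and
# the regional occurrence/abundance structure, yielding a dissimilarity on
# [-1, 1] that is independent of alpha-diversity differences.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `BC = sum |x_i - y_i| / sum (x_i + y_i)`; 0 for identical vectors, 1 for
#' disjoint supports.
#'
#' @param x,y Non-negative abundance vectors of equal length.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (sum(x) <= 0 || sum(y) <= 0) {
    stop("Bray-Curtis undefined for a zero-total vector", call. = FALSE)
  }
  sum(abs(x - y)) / sum(x + y)
}

#' Pairwise Bray-Curtis matrix for a count table
#' @param table A [count_table()].
#' @return Square symmetric matrix keyed by sample ids, attribute
#'   `metric = "bray"`.
#' @export
bray_curtis_matrix <- function(table) {
  m <- table$counts
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  attr(out, "metric") <- "bray"
  out
}

#' Build the regional species pool for null assembly
#'
#' Occurrence frequency (fraction of samples containing each taxon) governs
#' which taxa enter a null community; pooled relative abundance (taxon total
#' over grand total) governs how the remaining individuals are distributed.
#'
#' @param table A [count_table()], or an integer matrix samples x taxa.
#' @return List with `occurrence`, `rel_abund`, `taxon_ids`.
#' @export
null_pool <- function(table) {
  m <- if (inherits(table, "count_table")) table$counts else table
  occ <- colMeans(m > 0)
  ra <- colSums(m) / sum(m)
  list(occurrence = occ, rel_abund = ra, taxon_ids = colnames(m))
}

# One null community: S distinct taxa drawn sequentially without replacement
# with probability proportional to occurrence frequency, then 1 individual
# placed per drawn taxon and the remaining N - S distributed multinomially
# with probability proportional to pooled relative abundance. The weighted
# draw uses exponential keys (rexp(w)/w, keep the S smallest), which is
# distributionally identical to sequential weighted sampling without
# replacement but vectorized. Uses the current RNG stream.
assemble_null_community <- function(pool, S, N) {
  occ <- pool$occurrence
  eligible <- occ > 0
  if (S > sum(eligible)) {
    stop("richness ", S, " exceeds the ", sum(eligible),
         " taxa with positive occurrence", call. = FALSE)
  }
  if (N < S) stop("total abundance below richness", call. = FALSE)
  keys <- rep(Inf, length(occ))
  keys[eligible] <- stats::rexp(sum(eligible)) / occ[eligible]
  drawn <- order(keys)[seq_len(S)]
  counts <- integer(length(occ))
  counts[drawn] <- 1L
  if (N > S) {
    w <- pool$rel_abund[drawn]
    if (sum(w) <= 0) w <- rep(1, length(drawn))
    counts[drawn] <- counts[drawn] +
      stats::rmultinom(1, N - S, prob = w)[, 1]
  }
  names(counts) <- pool$taxon_ids
  counts
}

#' Assemble one null pair of communities
#'
#' Each member is assembled independently with its own richness S and total
#' N held at the empirical values (see [rc_bray_pair()] for the RC use).
#'
#' @param pool From [null_pool()].
#' @param s_x,n_x,s_y,n_y Richness and total for each member.
#' @param seed Optional seed for a self-contained draw.
#' @return List with integer vectors `x` and `y`.
#' @export
assemble_null_pair <- function(pool, s_x, n_x, s_y, n_y, seed = NULL) {
  with_seed(seed, {
    list(x = assemble_null_community(pool, s_x, n_x),
         y = assemble_null_community(pool, s_y, n_y))
  })
}

#' Raup-Crick standardized Bray-Curtis for one sample pair
#'
#' The observed Bray-Curtis is compared to `n_null` dissimilarities between
#' null pairs with matched richness and totals. With
#' `alpha = [#(null < obs - tol) + 0.5 * #(|null - obs| <= tol)] / n_null`,
#' `RC = 2 * alpha - 1`: -1 means the pair is far more similar than the null
#' expects, +1 far more dissimilar, 0 indistinguishable from stochastic
#' assembly.
#'
#' @param x,y Count vectors.
#' @param pool From [null_pool()] (regional pool; defaults elsewhere to all
#'   samples in the table).
#' @param n_null Null iterations (default 1000).
#' @param seed Optional seed.
#' @param tie_tol Absolute tolerance for counting a null draw as tied with
#'   the observed value (default 1e-10).
#' @return RC value in `[-1, 1]`, with attribute `obs_bray`.
#' @export
rc_bray_pair <- function(x, y, pool, n_null = 1000L, seed = NULL,
                         tie_tol = 1e-10) {
  if (n_null < 1) stop("n_null must be >= 1", call. = FALSE)
  obs <- bray_curtis(x, y)
  s_x <- sum(x > 0); n_x <- sum(x)
  s_y <- sum(y > 0); n_y <- sum(y)
  rc <- with_seed(seed, {
    null_bc <- vapply(seq_len(n_null), function(i) {
      nx <- assemble_null_community(pool, s_x, n_x)
      ny <- assemble_null_community(pool, s_y, n_y)
      bray_curtis(nx, ny)
    }, numeric(1))
    alpha <- (sum(null_bc < obs - tie_tol) +
                0.5 * sum(abs(null_bc - obs) <= tie_tol)) / n_null
    2 * alpha - 1
  })
  attr(rc, "obs_bray") <- obs
  rc
}

#' RC-Bray dissimilarity matrix
#'
#' All unordered sample pairs, each with a deterministic RNG substream keyed
#' by (seed, id_i, id_j) with the pair ids sorted, so the matrix is
#' symmetric by construction and invariant to sample order. The diagonal is
#' set to -1 (a sample is maximally "more similar than null" to itself).
#'
#' @param table A [count_table()].
#' @param n_null Null iterations per pair (default 1000).
#' @param seed Base seed.
#' @param tie_tol Tie tolerance (see [rc_bray_pair()]).
#' @param pool Optional [null_pool()]; default pools across all samples in
#'   `table`.
#' @return Square symmetric matrix in `[-1, 1]` keyed by sample ids;
#'   attributes `metric = "rc_bray"`, `n_null`, `seed`, `tie_tol`, and
#'   `bray` (the observed Bray-Curtis matrix).
#' @export
rc_bray_matrix <- function(table, n_null = 1000L, seed = 1L, tie_tol = 1e-10,
                           pool = NULL) {
  m <- table$counts
  n <- nrow(m)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(pool)) pool <- null_pool(table)
  ids <- rownames(m)
  out <- matrix(-1, n, n, dimnames = list(ids, ids))
  bray <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # pair ordered by id so the null stream is invariant to sample order
      pair <- sort(c(ids[i], ids[j]))
      rc <- rc_bray_pair(m[pair[1], ], m[pair[2], ], pool, n_null = n_null,
                         seed = seed_stream(seed, "rc", pair[1], pair[2]),
                         tie_tol = tie_tol)
      out[i, j] <- out[j, i] <- as.numeric(rc)
      bray[i, j] <- bray[j, i] <- attr(rc, "obs_bray")
    }
  }
  attr(out, "metric") <- "rc_bray"
  attr(out, "n_null") <- n_null
  attr(out, "seed") <- seed
  attr(out, "tie_tol") <- tie_tol
  attr(out, "bray") <- bray
  out
}

#' Write a square dissimilarity matrix as TSV with matching headers
#' @param d Square matrix with dimnames.
#' @param path Output path.
#' @export
write_dissimilarity <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  cm <- c(paste0("metric: ", attr(d, "metric") %||% "unknown"))
  if (!is.null(attr(d, "n_null"))) {
    cm <- c(cm, paste0("n_null: ", attr(d, "n_null")),
            paste0("seed: ", attr(d, "seed")))
  }
  write_tsv_commented(df, path, cm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
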