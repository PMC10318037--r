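# Alpha diversity by repeated rarefaction: Shannon index and observed ASV
# richness averaged over many independent subsamples at a fixed depth, which
# standardizes unequal sequencing effort without committing to a single
# arbitrary subsample.

#' Shannon diversity of a count vector
#'
#' H' = -sum p_i log(p_i) over taxa with positive count. Natural log (nats)
#' by default; the base is configurable (log2 gives bits).
#'
#' @param x Non-negative integer (or numeric) abundance vector.
#' @param base Logarithm base; `exp(1)` for nats.
#' @return Shannon index, a single non-negative number.
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("negative abundances", call. = FALSE)
  total <- sum(x)
  if (total <= 0) stop("all-zero abundance vector has no diversity", call. = FALSE)
  p <- x[x > 0] / total
  -sum(p * log(p)) / log(base)
}

#' Rarefy a sample once to a fixed depth
#'
#' Draws exactly `depth` individuals without replacement from the sample's
#' individuals (multivariate hypergeometric). Implemented by sampling
#' individual indices and mapping them back to taxa through the cumulative
#' counts, so no individual-level vector is materialized.
#'
#' @param x Non-negative integer counts (named or not).
#' @param depth Target total; must not exceed `sum(x)`.
#' @param seed Optional seed for a self-contained reproducible draw; `NULL`
#'   uses (and advances) the current RNG stream.
#' @return Integer vector of the same length as `x` summing to `depth`.
#' @export
rarefy_once <- function(x, depth, seed = NULL) {
  total <- sum(x)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (total < depth) stop("sample total (", total, ") below depth (", depth, ")",
                          call. = FALSE)
  if (total == depth) return(as.integer(x))
  with_seed(seed, {
    idx <- sample.int(total, depth)
    bins <- cumsum(c(0, x))
    out <- tabulate(findInterval(idx - 0.5, bins), nbins = length(x))
    names(out) <- names(x)
    as.integer(out)
  })
}

#' Repeated-rarefaction alpha diversity
#'
#' Per retained sample, Shannon index and observed richness are computed on
#' each of `n_iter` independent rarefactions and averaged; per-iteration
#' draws are seeded deterministically from (seed, sample id, iteration), so
#' results are reproducible and independent of sample order. Samples whose
#' total is below `depth` are excluded with a warning and listed in the
#' result.
#'
#' @param table A [count_table()].
#' @param depth Rarefaction depth; default is the smallest sample total.
#' @param n_iter Number of rarefaction iterations (default 1000).
#' @param seed Base seed.
#' @param base Logarithm base for Shannon (default nats).
#' @return Data frame (class `diversity_result`) with columns `sample_id`,
#'   `mean_shannon`, `sd_shannon`, `mean_richness`, `sd_richness`;
#'   attributes `depth`, `n_iter`, `excluded`, `shannon_base`.
#' @export
repeated_rarefaction <- function(table, depth = NULL, n_iter = 1000L,
                                 seed = 1L, base = exp(1)) {
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  m <- table$counts
  totals <- rowSums(m)
  if (is.null(depth)) depth <- min(totals)
  excluded <- rownames(m)[totals < depth]
  keep <- rownames(m)[totals >= depth]
  if (!length(keep)) stop("all samples fall below depth ", depth, call. = FALSE)
  if (length(excluded)) {
    warning("excluding ", length(excluded), " sample(s) below depth ", depth, ": ",
            paste(utils::head(excluded, 5), collapse = ", "), call. = FALSE)
  }
  res <- lapply(keep, function(sid) {
    x <- m[sid, ]
    h <- numeric(n_iter)
    s <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      r <- rarefy_once(x, depth, seed = seed_stream(seed, sid, it))
      s[it] <- sum(r > 0)
      h[it] <- shannon(r, base = base)
    }
    data.frame(sample_id = sid,
               mean_shannon = mean(h), sd_shannon = stats::sd(h),
               mean_richness = mean(s), sd_richness = stats::sd(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (n_iter == 1L) out$sd_shannon <- out$sd_richness <- 0
  attr(out, "depth") <- depth
  attr(out, "n_iter") <- n_iter
  attr(out, "excluded") <- excluded
  attr(out, "shannon_base") <- base
  attr(out, "seed") <- seed
  class(out) <- c("diversity_result", "data.frame")
  out
}

#' Expected rarefied richness (closed form)
#'
#' The hypergeometric expectation of observed richness when `depth`
#' individuals are drawn without replacement:
#' `E[S] = sum_i (1 - choose(N - x_i, depth) / choose(N, depth))`.
#' Used as the analytic reference for the Monte-Carlo estimator.
#'
#' @param x Integer counts.
#' @param depth Subsample size.
#' @return Expected richness.
#' @export
expected_rarefied_richness <- function(x, depth) {
  total <- sum(x)
  if (depth > total) stop("depth exceeds sample total", call. = FALSE)
  x <- x[x > 0]
  # P(taxon absent) via lchoose for numerical safety at large totals
  p_absent <- exp(lchoose(total - x, depth) - lchoose(total, depth))
  p_absent[total - x < depth] <- 0
  sum(1 - p_absent)
}

#' Rarefaction curves
#'
#' Mean observed richness across `n_iter` rarefactions at each depth in an
#' ascending grid, per sample. Depths exceeding a sample's total yield `NA`
#' for that sample.
#'
#' @param table A [count_table()].
#' @param depths Ascending integer vector of depths.
#' @param n_iter Iterations per depth (default 100).
#' @param seed Base seed.
#' @return Long data frame: `sample_id`, `depth`, `mean_richness`.
#' @export
rarefaction_curve <- function(table, depths, n_iter = 100L, seed = 1L) {
  if (is.unsorted(depths)) stop("depth grid must be ascending", call. = FALSE)
  m <- table$counts
  rows <- list()
  for (sid in rownames(m)) {
    x <- m[sid, ]
    total <- sum(x)
    for (d in depths) {
      mr <- if (d > total) NA_real_ else {
        mean(vapply(seq_len(n_iter), function(it) {
          sum(rarefy_once(x, d, seed = seed_stream(seed, sid, d, it)) > 0)
        }, numeric(1)))
      }
      rows[[length(rows) + 1L]] <- data.frame(sample_id = sid, depth = d,
                                              mean_richness = mr,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
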