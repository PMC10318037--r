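# Taxonomic aggregation and composition-derived quantities: rank-level
# relative abundances, phylum ratios, community-weighted mean 16S operon
# number, and a simple fold-change + rank-test screen for responder taxa.

#' Aggregate a count table to a taxonomic rank as relative abundances
#'
#' Counts are summed within rank labels (taxa with a missing label pool into
#' `"Unclassified"` so row sums stay 1) and divided by sample totals.
#'
#' @param table A [count_table()].
#' @param rank One of the taxonomy schema ranks (`"phylum"`, `"genus"`, ...).
#' @return Matrix samples x labels of relative abundances (rows sum to 1),
#'   with attributes `rank` and `agg_counts` (the aggregated integer counts).
#' @export
aggregate_rank <- function(table, rank) {
  if (!rank %in% TAXONOMIC_RANKS) {
    stop("unknown rank '", rank, "'; expected one of ",
         paste(TAXONOMIC_RANKS, collapse = ", "), call. = FALSE)
  }
  m <- table$counts
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("sample(s) with zero total: ",
         paste(rownames(m)[totals == 0], collapse = ", "), call. = FALSE)
  }
  lab <- table$taxonomy[[rank]][match(colnames(m), table$taxonomy$taxon_id)]
  lab[is.na(lab) | lab == ""] <- "Unclassified"
  agg <- t(rowsum(t(m), group = lab))
  rel <- agg / totals
  attr(rel, "rank") <- rank
  attr(rel, "agg_counts") <- agg
  rel
}

#' Per-sample ratio of two rank-level abundances
#'
#' `(p_num + pseudo) / (p_den + pseudo)`; the pseudo-count keeps the ratio
#' finite when the denominator taxon is absent. The classic use is the
#' Proteobacteria:Actinobacteria ratio as a coarse copiotroph/oligotroph
#' axis.
#'
#' @param rel Relative-abundance matrix from [aggregate_rank()].
#' @param numerator,denominator Column labels; a label absent from the
#'   matrix is treated as all-zero.
#' @param pseudo Non-negative pseudo-count (default 1e-6).
#' @return Named numeric vector, one ratio per sample.
#' @export
phylum_ratio <- function(rel, numerator, denominator, pseudo = 1e-6) {
  if (pseudo < 0) stop("pseudo-count must be non-negative", call. = FALSE)
  get_col <- function(lab) {
    if (lab %in% colnames(rel)) rel[, lab] else stats::setNames(rep(0, nrow(rel)),
                                                                rownames(rel))
  }
  (get_col(numerator) + pseudo) / (get_col(denominator) + pseudo)
}

#' Community-weighted mean 16S operon number
#'
#' Abundance-weighted mean rRNA operon (16S copy) number per sample, a
#' community-level life-history indicator (fast growers carry more
#' operons). Relative abundances are renormalized over the taxa with a
#' known copy number; the covered fraction of each sample's reads is
#' reported.
#'
#' @param table A [count_table()].
#' @param copy_numbers Named numeric vector, taxon_id -> copies (>= 1).
#' @return Data frame: `sample_id`, `mean_operon_number`, `coverage`.
#' @export
mean_operon_number <- function(table, copy_numbers) {
  if (any(copy_numbers < 1, na.rm = TRUE)) {
    stop("operon copy numbers must be >= 1", call. = FALSE)
  }
  m <- table$counts
  known <- intersect(colnames(m), names(copy_numbers)[!is.na(copy_numbers)])
  if (!length(known)) stop("no taxon with a known operon copy number", call. = FALSE)
  sub <- m[, known, drop = FALSE]
  sub_tot <- rowSums(sub)
  if (any(sub_tot == 0)) {
    stop("sample(s) contain no reads from taxa with known copy number: ",
         paste(rownames(m)[sub_tot == 0], collapse = ", "), call. = FALSE)
  }
  wmean <- as.numeric(sub %*% copy_numbers[known]) / sub_tot
  data.frame(sample_id = rownames(m), mean_operon_number = wmean,
             coverage = sub_tot / rowSums(m), stringsAsFactors = FALSE)
}

#' Screen for differentially abundant taxa between two groups
#'
#' A deliberately simple responder screen: per taxon, log2 fold change of
#' group means (with pseudo-count) and a two-sided Wilcoxon rank-sum test,
#' Benjamini-Hochberg adjusted. A taxon is flagged when both the effect size
#' and the adjusted p pass their thresholds.
#'
#' @param rel Relative-abundance matrix from [aggregate_rank()].
#' @param meta Sample metadata (rows matching `rownames(rel)` by
#'   `sample_id`).
#' @param group_col Metadata column defining groups.
#' @param group_a,group_b The two levels to compare (fold change is a/b).
#' @param min_fc Minimum absolute log2 fold change to flag (default 1).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param pseudo Pseudo-count for fold changes (default 1e-6).
#' @return Data frame sorted by `q` then `-|log2_fc|`: `taxon`, `mean_a`,
#'   `mean_b`, `log2_fc`, `p`, `q`, `flagged`.
#' @export
responder_screen <- function(rel, meta, group_col, group_a, group_b,
                             min_fc = 1, alpha = 0.05, pseudo = 1e-6) {
  g <- meta[[group_col]][match(rownames(rel), meta$sample_id)]
  ia <- which(g == group_a)
  ib <- which(g == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each group needs >= 2 samples (got ", length(ia), " and ",
         length(ib), ")", call. = FALSE)
  }
  res <- lapply(colnames(rel), function(tx) {
    a <- rel[ia, tx]
    b <- rel[ib, tx]
    p <- if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) 1 else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
    data.frame(taxon = tx, mean_a = mean(a), mean_b = mean(b),
               log2_fc = log2((mean(a) + pseudo) / (mean(b) + pseudo)),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- abs(out$log2_fc) >= min_fc & out$q <= alpha
  out <- out[order(out$q, -abs(out$log2_fc)), ]
  rownames(out) <- NULL
  out
}
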