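# Tabular I/O and validation for the shared data model: count tables with
# taxonomy, sample metadata, and per-sample covariate/process tables.
# Internal convention: count matrices are samples x taxa everywhere.

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus")

#' Construct and validate a count table
#'
#' The central community container: an integer matrix of samples x taxa
#' (ASVs) plus a taxonomy map. Validation enforces non-negative integer
#' counts, unique identifiers, and taxonomy coverage of every observed
#' taxon. Taxa that are all-zero are retained and listed in the validation
#' report attached as an attribute.
#'
#' @param counts Integer matrix, samples in rows, taxa in columns; dimnames
#'   give sample and taxon identifiers.
#' @param taxonomy Data frame with column `taxon_id` plus rank columns
#'   (`domain` ... `genus`); missing ranks may be `NA`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix), `taxonomy` (data frame), and attribute
#'   `validation` (list with `empty_taxa`).
#' @export
count_table <- function(counts, taxonomy) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample (row) and taxon (column) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate taxon identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("count at sample '%s', taxon '%s' is not a non-negative integer",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!"taxon_id" %in% names(taxonomy)) {
    stop("taxonomy must have a 'taxon_id' column", call. = FALSE)
  }
  observed <- colnames(counts)[colSums(counts) > 0]
  missing_tax <- setdiff(observed, taxonomy$taxon_id)
  if (length(missing_tax)) {
    stop("taxa with nonzero counts absent from taxonomy: ",
         paste(utils::head(missing_tax, 5), collapse = ", "), call. = FALSE)
  }
  empty <- colnames(counts)[colSums(counts) == 0]
  obj <- list(counts = counts, taxonomy = taxonomy)
  attr(obj, "validation") <- list(empty_taxa = empty)
  class(obj) <- "count_table"
  obj
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, total %d counts\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read a count table and its taxonomy from TSV
#'
#' Accepts either orientation; the amplicon-conventional taxa-as-rows layout
#' is the default and is transposed to the internal samples x taxa form.
#' Non-integer or negative counts abort with a diagnostic naming the cell.
#'
#' @param path Count matrix TSV; first column holds row identifiers.
#' @param taxonomy_path Two-column TSV `taxon_id<TAB>lineage`, lineage
#'   semicolon-delimited `domain;phylum;...;genus` (trailing ranks may be
#'   omitted or empty).
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, taxonomy_path,
                             orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- read_tsv_raw(path)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop(path, ": duplicate row identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- sapply(names(raw)[-1], function(cn) parse_counts(raw[[cn]], cn, file = path))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(ids),
                                   dimnames = list(NULL, names(raw)[-1]))
  rownames(m) <- ids
  if (orientation == "taxa_rows") m <- t(m)
  taxonomy <- read_taxonomy(taxonomy_path)
  count_table(m, taxonomy)
}

#' Read a taxonomy TSV (taxon_id, semicolon-delimited lineage)
#' @param path Taxonomy TSV path.
#' @return Data frame with `taxon_id` and one column per rank.
#' @export
read_taxonomy <- function(path) {
  raw <- read_tsv_raw(path)
  if (ncol(raw) < 2) stop(path, ": expected taxon_id and lineage columns", call. = FALSE)
  lin <- strsplit(raw[[2]], ";", fixed = TRUE)
  out <- data.frame(taxon_id = raw[[1]], stringsAsFactors = FALSE)
  for (i in seq_along(TAXONOMIC_RANKS)) {
    v <- vapply(lin, function(l) {
      x <- if (length(l) >= i) trimws(l[i]) else NA_character_
      if (is.na(x) || x == "") NA_character_ else x
    }, character(1))
    out[[TAXONOMIC_RANKS[i]]] <- v
  }
  out
}

#' Write a count table (+ taxonomy) to TSV
#' @param x A [count_table()].
#' @param path Count TSV path (written taxa-as-rows).
#' @param taxonomy_path Optional taxonomy TSV path.
#' @export
write_count_table <- function(x, path, taxonomy_path = NULL) {
  m <- t(x$counts)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_commented(df, path, "counts: integer reads, taxa as rows")
  if (!is.null(taxonomy_path)) {
    lin <- apply(as.matrix(x$taxonomy[TAXONOMIC_RANKS]), 1L, function(r) {
      paste(ifelse(is.na(r), "", r), collapse = ";")
    })
    write_tsv_commented(
      data.frame(taxon_id = x$taxonomy$taxon_id, lineage = lin,
                 stringsAsFactors = FALSE),
      taxonomy_path, "taxonomy: semicolon lineage domain;phylum;class;order;family;genus")
  }
  invisible(path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `land_use`, `diversity_level`, `stress`,
#' `replicate`. Diversity levels are ordered D0 < D1 < D2 by default.
#'
#' @param path Metadata TSV.
#' @param diversity_levels Ordered level set for the dilution factor.
#' @param stress_levels Allowed stress levels.
#' @return Data frame, one row per sample, `diversity_level` an ordered factor.
#' @export
read_sample_metadata <- function(path,
                                 diversity_levels = c("D0", "D1", "D2"),
                                 stress_levels = c("control", "stressed")) {
  raw <- read_tsv_raw(path)
  need <- c("sample_id", "land_use", "diversity_level", "stress", "replicate")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop(path, ": missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  validate_sample_metadata(
    data.frame(sample_id = raw$sample_id,
               land_use = raw$land_use,
               diversity_level = raw$diversity_level,
               stress = raw$stress,
               replicate = parse_numeric(raw$replicate, "replicate", file = path),
               stringsAsFactors = FALSE),
    diversity_levels, stress_levels, file = path)
}

#' Validate a sample metadata frame against the declared design
#' @param meta Data frame with the metadata columns.
#' @param diversity_levels,stress_levels Declared level sets.
#' @param file Label used in diagnostics.
#' @return The validated frame with `diversity_level` as an ordered factor.
#' @export
validate_sample_metadata <- function(meta,
                                     diversity_levels = c("D0", "D1", "D2"),
                                     stress_levels = c("control", "stressed"),
                                     file = "<in-memory>") {
  if (anyDuplicated(meta$sample_id)) {
    stop(file, ": duplicate sample_id in metadata", call. = FALSE)
  }
  bad <- setdiff(unique(as.character(meta$diversity_level)), diversity_levels)
  if (length(bad)) stop(file, ": undeclared diversity_level: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(as.character(meta$stress)), stress_levels)
  if (length(bad)) stop(file, ": undeclared stress level: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(is.na(meta$replicate)) || any(meta$replicate < 1)) {
    stop(file, ": replicate must be >= 1", call. = FALSE)
  }
  meta$diversity_level <- factor(meta$diversity_level, levels = diversity_levels,
                                 ordered = TRUE)
  meta$replicate <- as.integer(meta$replicate)
  meta
}

#' Read a per-sample covariate/process table
#'
#' All non-identifier columns are numeric; `NA` marks explicitly missing
#' measurements (never silently zero). Units are carried in `#` header
#' comments of the file and are not interpreted.
#' @param path Process TSV.
#' @return Data frame with `sample_id` and numeric measurement columns.
#' @export
read_process_table <- function(path) {
  raw <- read_tsv_raw(path)
  if (!"sample_id" %in% names(raw)) {
    stop(path, ": missing sample_id column", call. = FALSE)
  }
  out <- data.frame(sample_id = raw$sample_id, stringsAsFactors = FALSE)
  for (cn in setdiff(names(raw), "sample_id")) {
    out[[cn]] <- parse_numeric(raw[[cn]], cn, col = cn, file = path)
  }
  if (anyDuplicated(out$sample_id)) stop(path, ": duplicate sample_id", call. = FALSE)
  out
}

#' Inner-join count table, metadata, and process table on sample id
#'
#' Rows are sorted by `sample_id` for deterministic downstream order; samples
#' dropped from either side are reported, an empty intersection errors.
#'
#' @param counts A [count_table()].
#' @param meta Sample metadata frame.
#' @param proc Optional process table frame.
#' @return List with `counts` (subset count_table), `meta`, `proc` (or NULL),
#'   and `report` listing dropped sample ids per source.
#' @export
join_sample_frames <- function(counts, meta, proc = NULL) {
  ids <- intersect(rownames(counts$counts), meta$sample_id)
  if (!is.null(proc)) ids <- intersect(ids, proc$sample_id)
  if (!length(ids)) stop("no samples shared across inputs", call. = FALSE)
  ids <- sort(ids)
  report <- list(
    dropped_counts = sort(setdiff(rownames(counts$counts), ids)),
    dropped_meta = sort(setdiff(meta$sample_id, ids)),
    dropped_proc = if (is.null(proc)) character() else sort(setdiff(proc$sample_id, ids))
  )
  sub <- counts
  sub$counts <- counts$counts[ids, , drop = FALSE]
  meta2 <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta2) <- NULL
  proc2 <- if (is.null(proc)) NULL else {
    p <- proc[match(ids, proc$sample_id), , drop = FALSE]
    rownames(p) <- NULL
    p
  }
  list(counts = sub, meta = meta2, proc = proc2, report = report)
}

#' Assemble a run configuration
#'
#' Collects the tunables every stage consumes: rarefaction depth and
#' iterations, null-model iterations, forest size, shuffle repetitions,
#' permutation counts, and the master seed recorded in all outputs.
#'
#' @param rarefaction_depth Depth (reads) for repeated rarefaction; `NULL`
#'   means the minimum retained sample total.
#' @param rarefaction_iters Rarefaction iterations (default 1000).
#' @param null_iters Null-model iterations for RC-Bray (default 1000).
#' @param n_trees Random-forest trees (default 10000).
#' @param n_shuffles Permutation-importance shuffle repetitions (default 30).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param pcoa_axes Ordination axes exported as predictors (default 3).
#' @param seed Master seed.
#' @param out_dir Output directory for file-writing entry points.
#' @return A `run_config` list.
#' @export
run_config <- function(rarefaction_depth = NULL, rarefaction_iters = 1000L,
                       null_iters = 1000L, n_trees = 10000L, n_shuffles = 30L,
                       n_perm = 999L, pcoa_axes = 3L, seed = 1L,
                       out_dir = ".") {
  cfg <- list(rarefaction_depth = rarefaction_depth,
              rarefaction_iters = as.integer(rarefaction_iters),
              null_iters = as.integer(null_iters),
              n_trees = as.integer(n_trees),
              n_shuffles = as.integer(n_shuffles),
              n_perm = as.integer(n_perm),
              pcoa_axes = as.integer(pcoa_axes),
              seed = as.integer(seed),
              out_dir = out_dir)
  for (f in c("rarefaction_iters", "null_iters", "n_trees", "n_shuffles",
              "n_perm", "pcoa_axes")) {
    if (cfg[[f]] < 1L) stop(f, " must be >= 1", call. = FALSE)
  }
  if (!is.null(cfg$rarefaction_depth) && cfg$rarefaction_depth < 1) {
    stop("rarefaction_depth must be >= 1", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop(path, ": unknown config keys: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}
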