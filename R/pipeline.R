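# End-to-end analysis: counts + metadata + process table in, diversity,
# RC-Bray ordination, PERMANOVA, derived functions, resistance,
# multifunctionality, and predictor-importance rankings out.

#' Run the full analysis pipeline
#'
#' Stages, in order: repeated-rarefaction diversity; phylum-level
#' aggregation and the Proteobacteria:Actinobacteria ratio; Bray-Curtis and
#' (optionally) RC-Bray dissimilarity; PCoA; PERMANOVA on land use,
#' diversity level, and stress; derived function table; resistance table;
#' multifunctionality; tuned random-forest importance for every response.
#' Every stage draws from deterministic substreams of `config$seed`.
#'
#' @param counts A [count_table()].
#' @param meta Sample metadata.
#' @param proc Process table.
#' @param config A [run_config()].
#' @param dissimilarity `"rc_bray"` (default) or `"bray"`; which matrix
#'   feeds the ordination and PERMANOVA.
#' @return List with elements `diversity`, `phylum_rel`, `pa_ratio`,
#'   `bray`, `rc` (or NULL), `ordination`, `permanova`, `functions`,
#'   `multifunctionality`, `resistance`, `importance`, `config`.
#' @export
run_pipeline <- function(counts, meta, proc, config = run_config(),
                         dissimilarity = c("rc_bray", "bray")) {
  dissimilarity <- match.arg(dissimilarity)
  joined <- join_sample_frames(counts, meta, proc)
  counts <- joined$counts
  meta <- joined$meta
  proc <- joined$proc

  div <- repeated_rarefaction(counts, depth = config$rarefaction_depth,
                              n_iter = config$rarefaction_iters,
                              seed = seed_stream(config$seed, "diversity"))
  if (length(attr(div, "excluded"))) {
    keep <- setdiff(rownames(counts$counts), attr(div, "excluded"))
    counts$counts <- counts$counts[keep, , drop = FALSE]
    meta <- meta[meta$sample_id %in% keep, , drop = FALSE]
    proc <- proc[proc$sample_id %in% keep, , drop = FALSE]
  }

  phylum_rel <- aggregate_rank(counts, "phylum")
  pa <- phylum_ratio(phylum_rel, "Proteobacteria", "Actinobacteriota")

  bray <- bray_curtis_matrix(counts)
  rc <- NULL
  dmat <- bray
  if (dissimilarity == "rc_bray") {
    rc <- rc_bray_matrix(counts, n_null = config$null_iters,
                         seed = seed_stream(config$seed, "rcbray"))
    dmat <- rc
  }
  ord <- pcoa(dmat)
  perm <- permanova(dmat, meta, c("land_use", "diversity_level", "stress"),
                    n_perm = config$n_perm,
                    seed = seed_stream(config$seed, "permanova"))

  funcs <- function_table(proc)
  multi <- multifunctionality(funcs)
  resist <- resistance_table(funcs, meta)
  imp <- run_all_models(funcs, multi, div, ord, proc, pa, config = config)

  list(diversity = div, phylum_rel = phylum_rel, pa_ratio = pa,
       bray = bray, rc = rc, ordination = ord, permanova = perm,
       functions = funcs, multifunctionality = multi, resistance = resist,
       importance = imp, config = config)
}

#' Write pipeline results to a directory of TSV files
#' @param res Result of [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_cm <- paste0("seed: ", res$config$seed)
  write_tsv_commented(as.data.frame(res$diversity),
                      file.path(dir, "diversity.tsv"),
                      c(sprintf("repeated rarefaction: depth %d, %d iterations",
                                attr(res$diversity, "depth"),
                                attr(res$diversity, "n_iter")),
                        "shannon in nats", seed_cm))
  write_dissimilarity(res$bray, file.path(dir, "bray.tsv"))
  if (!is.null(res$rc)) write_dissimilarity(res$rc, file.path(dir, "rcbray.tsv"))
  coords <- data.frame(sample_id = rownames(res$ordination$coordinates),
                       res$ordination$coordinates, check.names = FALSE)
  write_tsv_commented(coords, file.path(dir, "coordinates.tsv"), seed_cm)
  write_tsv_commented(data.frame(axis = seq_along(res$ordination$eigenvalues),
                                 eigenvalue = res$ordination$eigenvalues),
                      file.path(dir, "eigenvalues.tsv"))
  write_tsv_commented(as.data.frame(res$permanova),
                      file.path(dir, "permanova.tsv"),
                      c(paste0("permutations: ", attr(res$permanova, "n_perm")),
                        seed_cm))
  write_tsv_commented(res$functions, file.path(dir, "functions.tsv"),
                      c("units: c_mineralization/sir ug CO2-C g-1 d-1;",
                        "qco2 per unit biomass; total_enzyme nmol g-1 h-1;",
                        "N rates mg N kg-1 d-1"))
  write_tsv_commented(res$multifunctionality,
                      file.path(dir, "multifunctionality.tsv"),
                      "mean of z-scaled function rates (sample sd)")
  write_tsv_commented(res$resistance, file.path(dir, "resistance.tsv"),
                      "resistance = 1 - 2|D0|/(|C0| + |D0|), D0 = C0 - P0")
  comb <- attr(res$importance, "combined")
  if (!is.null(comb)) {
    write_tsv_commented(comb, file.path(dir, "importance.tsv"), seed_cm)
  }
  for (resp in names(res$importance)) {
    imp <- res$importance[[resp]]
    if (is.null(imp)) next
    write_tsv_commented(as.data.frame(imp),
                        file.path(dir, paste0("importance_", resp, ".tsv")),
                        c(sprintf("mtry: %d; trees: %d; shuffles: %d",
                                  attr(imp, "mtry"), attr(imp, "n_trees"),
                                  attr(imp, "n_shuffles")), seed_cm))
    write_tsv_commented(attr(imp, "tuning"),
                        file.path(dir, paste0("tuning_", resp, ".tsv")))
  }
  invisible(dir)
}
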