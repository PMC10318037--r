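# In-code fixtures shared across tests.

# Minimal count table: counts is a samples x taxa integer matrix; taxonomy
# is synthesized with the given phyla/genera (recycled over taxa).
make_table <- function(counts, phylum = "Proteobacteria", genus = NA) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("t", seq_len(ncol(counts)))
  }
  tax <- data.frame(taxon_id = colnames(counts),
                    domain = "Bacteria",
                    phylum = rep_len(phylum, ncol(counts)),
                    class = NA_character_, order = NA_character_,
                    family = NA_character_,
                    genus = rep_len(genus, ncol(counts)),
                    stringsAsFactors = FALSE)
  count_table(counts, tax)
}

# Balanced two-group metadata for n samples named s1..sn.
make_meta <- function(n, land_use = "cultivated", diversity = "D0") {
  data.frame(sample_id = paste0("s", seq_len(n)),
             land_use = land_use,
             diversity_level = diversity,
             stress = rep(c("control", "stressed"), length.out = n),
             replicate = rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)],
             stringsAsFactors = FALSE)
}

# A small scenario for fast end-to-end tests: full 2x3x2 design with 2
# replicates (24 samples), modest pool and depth.
small_scenario <- function(seed = 1, ...) {
  args <- list(pool_size = 150L, depth_mean = 5000, n_replicates = 2L,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_scenario, args)
}
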