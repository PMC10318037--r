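# Synthetic dilution-to-extinction experiment generator.
#
# Emulates the structure of a two-land-use soil microcosm study: distinct
# taxon pools per land use, serial-dilution inocula that strip rare taxa,
# regrowth to similar biomass, a stressor whose community and functional
# effects are confined to the lowest-diversity treatment, and ecosystem
# process rates generated from planted drivers (biomass, community
# membership, nitrifier abundance, a single responsive genus) plus noise.
# Ground truth (guilds, coefficients, seed) is emitted for recovery tests.

#' Define a simulation scenario
#'
#' Defaults describe the reference design: 2 land uses x 3 dilution levels
#' (D0 undiluted, D1 ~1e-3, D2 ~1e-6) x 2 stress levels x 5 replicates = 60
#' samples. Dilution is modelled as the number of cells transferred to the
#' sterile microcosm (1e6 / 1e3 / 1e2), which with a ~600-taxon lognormal
#' pool produces roughly 45-55% stepwise richness loss. Stress multipliers
#' act on guild members only in stressed D2 samples.
#'
#' @param land_uses Character vector of land-use labels.
#' @param pool_size Taxa per land-use pool.
#' @param pool_overlap Fraction of the pool shared between land uses.
#' @param abund_meanlog,abund_sdlog Lognormal parameters of pool relative
#'   abundances (sdlog controls evenness, hence dilution-driven richness loss).
#' @param dilution_cells Named vector of inoculum cell counts per diversity
#'   level, decreasing; names become the ordered diversity levels.
#' @param depth_mean,depth_dispersion Negative-binomial sequencing depth
#'   (mean reads and size parameter).
#' @param n_replicates Replicates per land use x level x stress cell.
#' @param guild_fractions Named fractions of the pool tagged
#'   `stress_sensitive`, `stress_tolerant`, `nitrifier`.
#' @param stress_multipliers Named abundance multipliers applied to guild
#'   members in stressed lowest-dilution samples.
#' @param regrowth_sdlog Lognormal sd of post-dilution regrowth noise.
#' @param biomass_base Named per-land-use mean microbial biomass (ug C g-1).
#' @param biomass_sdlog Lognormal sd of biomass across samples.
#' @param stress_biomass_multiplier Biomass multiplier in stressed
#'   lowest-dilution samples (default 1.69: biomass rises under stress even
#'   as activity falls).
#' @param beta Named list of per-function driver coefficient vectors; driver
#'   names are `biomass`, `membership`, `nitrifier`, `sir_genus` (see
#'   [simulate_processes()]).
#' @param noise_sd Named per-function Gaussian noise sd.
#' @param interval_days Incubation interval for the inorganic-N time points.
#' @param seed Master seed; recorded in all outputs.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(
    land_uses = c("cultivated", "prairie"),
    pool_size = 400L,
    pool_overlap = 0.25,
    abund_meanlog = 0,
    abund_sdlog = 1.8,
    dilution_cells = c(D0 = 1e6, D1 = 1e3, D2 = 1e2),
    depth_mean = 2e4,
    depth_dispersion = 20,
    n_replicates = 5L,
    guild_fractions = c(stress_sensitive = 0.25, stress_tolerant = 0.10,
                        nitrifier = 0.05),
    stress_multipliers = c(stress_sensitive = 0.15, stress_tolerant = 3,
                           nitrifier = 0.72),
    regrowth_sdlog = 0.5,
    biomass_base = c(cultivated = 250, prairie = 400),
    biomass_sdlog = 0.25,
    stress_biomass_multiplier = 1.69,
    beta = list(
      respiration = c(biomass = 0.05),
      sir = c(sir_genus = 300),
      enzyme = c(biomass = 0.05, membership = 8),
      n_mineralization = c(biomass = 0.002, membership = 0.15),
      nitrification = c(nitrifier = 1e-7)
    ),
    noise_sd = c(respiration = 1, sir = 1, enzyme = 2,
                 n_mineralization = 0.05, nitrification = 0.03),
    interval_days = 14,
    seed = 1L) {
  scn <- as.list(environment())
  if (any(dilution_cells < 1)) {
    stop("dilution cell counts must be >= 1 (a zero inoculum has no community)",
         call. = FALSE)
  }
  if (is.null(names(dilution_cells))) stop("dilution_cells must be named", call. = FALSE)
  if (pool_overlap < 0 || pool_overlap > 1) stop("pool_overlap must be in [0,1]",
                                                 call. = FALSE)
  if (any(guild_fractions < 0) || sum(guild_fractions) > 1) {
    stop("guild_fractions must be non-negative and sum to <= 1", call. = FALSE)
  }
  if (any(stress_multipliers <= 0)) stop("stress multipliers must be > 0", call. = FALSE)
  if (!all(land_uses %in% names(biomass_base))) {
    stop("biomass_base must be named for every land use", call. = FALSE)
  }
  known_drivers <- c("biomass", "membership", "nitrifier", "sir_genus")
  for (fn in names(beta)) {
    bad <- setdiff(names(beta[[fn]]), known_drivers)
    if (length(bad)) stop("unknown driver in beta$", fn, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  scn$seed <- as.integer(seed)
  class(scn) <- "simulation_scenario"
  scn
}

# Build the regional pools: taxon ids, per-land-use relative abundances,
# guilds, synthesized taxonomy, and 16S operon copy numbers.
build_pools <- function(scn) {
  n_shared <- round(scn$pool_size * scn$pool_overlap)
  n_total <- 2L * scn$pool_size - n_shared
  taxon_id <- sprintf("ASV%04d", seq_len(n_total))
  # pool membership: first block shared, then land-use-specific blocks
  in_pool <- list()
  in_pool[[scn$land_uses[1]]] <- c(seq_len(n_shared),
                                   n_shared + seq_len(scn$pool_size - n_shared))
  in_pool[[scn$land_uses[2]]] <- c(seq_len(n_shared),
                                   scn$pool_size + seq_len(scn$pool_size - n_shared))
  guilds <- names(scn$guild_fractions)
  guild <- sample(c(guilds, "none"), n_total, replace = TRUE,
                  prob = c(scn$guild_fractions, 1 - sum(scn$guild_fractions)))
  phylum <- character(n_total)
  pools_by_guild <- list(
    stress_sensitive = c("Proteobacteria", "Bacteroidota"),
    stress_tolerant = c("Actinobacteriota", "Firmicutes"),
    nitrifier = c("Nitrososphaerota", "Proteobacteria"),
    none = c("Acidobacteriota", "Verrucomicrobiota", "Chloroflexi",
             "Planctomycetota", "Proteobacteria", "Actinobacteriota")
  )
  for (g in names(pools_by_guild)) {
    idx <- which(guild == g)
    if (length(idx)) phylum[idx] <- sample(pools_by_guild[[g]], length(idx),
                                           replace = TRUE)
  }
  # genera: small clusters of taxa; one sensitive-guild genus is designated
  # as the SIR driver and named after the classic copiotroph it emulates
  genus <- sprintf("Genus%03d", ceiling(seq_len(n_total) / 5))
  sens <- which(guild == "stress_sensitive")
  sir_taxa <- sens[seq_len(min(8L, length(sens)))]
  genus[sir_taxa] <- "Pseudomonas"
  phylum[sir_taxa] <- "Proteobacteria"
  # fast growers (stress tolerant) carry more rRNA operons
  copy_number <- ifelse(guild == "stress_tolerant",
                        sample(4:7, n_total, replace = TRUE),
                        sample(1:4, n_total, replace = TRUE))
  rel <- matrix(0, n_total, 2, dimnames = list(taxon_id, scn$land_uses))
  for (lu in scn$land_uses) {
    idx <- in_pool[[lu]]
    ab <- stats::rlnorm(length(idx), scn$abund_meanlog, scn$abund_sdlog)
    rel[idx, lu] <- ab / sum(ab)
  }
  list(taxon_id = taxon_id, rel = rel, guild = guild, phylum = phylum,
       genus = genus, copy_number = copy_number, sir_genus = "Pseudomonas")
}

#' Simulate communities for every sample in the design
#'
#' For each land use a lognormal taxon pool is drawn; each replicate x
#' dilution level samples its inoculum as a multinomial draw of the level's
#' cell count, survivors regrow with lognormal noise, guild-specific stress
#' multipliers act only in stressed lowest-dilution samples, and sequencing
#' counts are drawn at a sample-specific negative-binomial depth. Expected
#' richness decreases monotonically across dilution levels.
#'
#' @param scn A [simulation_scenario()].
#' @return List: `counts` (a [count_table()]), `meta` (sample metadata),
#'   `truth` (per-taxon data frame: guild, phylum, genus, copy number,
#'   per-land-use pool relative abundance) and `sir_genus`.
#' @export
simulate_communities <- function(scn) {
  stopifnot(inherits(scn, "simulation_scenario"))
  with_seed(seed_stream(scn$seed, "communities"), {
    pools <- build_pools(scn)
    levels_d <- names(scn$dilution_cells)
    design <- expand.grid(replicate = seq_len(scn$n_replicates),
                          stress = c("control", "stressed"),
                          diversity_level = levels_d,
                          land_use = scn$land_uses,
                          stringsAsFactors = FALSE)
    design <- design[, c("land_use", "diversity_level", "stress", "replicate")]
    design$sample_id <- sprintf("%s_%s_%s_r%d", design$land_use,
                                design$diversity_level,
                                substr(design$stress, 1, 4), design$replicate)
    d2 <- levels_d[length(levels_d)]
    n_taxa <- length(pools$taxon_id)
    counts <- matrix(0L, nrow(design), n_taxa,
                     dimnames = list(design$sample_id, pools$taxon_id))
    true_rel <- matrix(0, nrow(design), n_taxa,
                       dimnames = list(design$sample_id, pools$taxon_id))
    for (i in seq_len(nrow(design))) {
      lu <- design$land_use[i]
      cells <- scn$dilution_cells[[design$diversity_level[i]]]
      inoc <- stats::rmultinom(1, cells, prob = pools$rel[, lu])[, 1]
      surv <- inoc > 0
      if (!any(surv)) stop("inoculum contained no cells", call. = FALSE)
      ab <- inoc * stats::rlnorm(n_taxa, 0, scn$regrowth_sdlog)
      ab[!surv] <- 0
      if (design$stress[i] == "stressed" && design$diversity_level[i] == d2) {
        for (g in names(scn$stress_multipliers)) {
          ab[pools$guild == g] <- ab[pools$guild == g] * scn$stress_multipliers[[g]]
        }
      }
      p <- ab / sum(ab)
      true_rel[i, ] <- p
      depth <- max(1000L, stats::rnbinom(1, mu = scn$depth_mean,
                                         size = scn$depth_dispersion))
      counts[i, ] <- stats::rmultinom(1, depth, prob = p)[, 1]
    }
    taxonomy <- data.frame(taxon_id = pools$taxon_id,
                           domain = "Bacteria",
                           phylum = pools$phylum,
                           class = NA_character_, order = NA_character_,
                           family = NA_character_, genus = pools$genus,
                           stringsAsFactors = FALSE)
    meta <- validate_sample_metadata(design[, c("sample_id", "land_use",
                                                "diversity_level", "stress",
                                                "replicate")],
                                     diversity_levels = levels_d)
    truth <- data.frame(taxon_id = pools$taxon_id, guild = pools$guild,
                        phylum = pools$phylum, genus = pools$genus,
                        copy_number = pools$copy_number,
                        stringsAsFactors = FALSE)
    for (lu in scn$land_uses) truth[[paste0("pool_rel_", lu)]] <- pools$rel[, lu]
    list(counts = count_table(counts, taxonomy), meta = meta, truth = truth,
         true_rel = true_rel, sir_genus = pools$sir_genus)
  })
}

#' Simulate covariates and process measurements from planted drivers
#'
#' Biomass is drawn per sample (inflated in stressed lowest-dilution
#' samples); qPCR covariates (16S, ITS, AOA/AOB, tetW/tetM) are derived from
#' biomass, dilution level, and the realized nitrifier guild abundance; each
#' ecosystem function is a stated linear combination of planted drivers plus
#' Gaussian noise. The generating coefficients are returned as ground truth.
#' Inorganic-N pools at two time points are back-computed so the planted net
#' N-mineralization and nitrification rates are exactly recoverable from the
#' pool differences.
#'
#' @param sim Output of [simulate_communities()].
#' @param scn The same [simulation_scenario()].
#' @return List: `proc` (process table data frame), `truth` (list with
#'   `beta`, `noise_sd`, per-sample driver values, seed).
#' @export
simulate_processes <- function(sim, scn) {
  stopifnot(inherits(scn, "simulation_scenario"))
  meta <- sim$meta
  n <- nrow(meta)
  levels_d <- levels(meta$diversity_level)
  d2 <- levels_d[length(levels_d)]
  with_seed(seed_stream(scn$seed, "processes"), {
    is_d2s <- meta$diversity_level == d2 & meta$stress == "stressed"
    biomass <- stats::rlnorm(n, log(scn$biomass_base[meta$land_use]),
                             scn$biomass_sdlog)
    biomass[is_d2s] <- biomass[is_d2s] * scn$stress_biomass_multiplier
    dna_yield <- biomass * 0.02 * stats::rlnorm(n, 0, 0.2)
    abund_16s <- biomass * 5e4 * stats::rlnorm(n, 0, 0.3)
    # fungi fail to establish in the diluted, re-inoculated microcosms
    abund_its <- ifelse(meta$diversity_level == levels_d[1],
                        1e6 * stats::rlnorm(n, 0, 0.5),
                        1e3 * stats::rlnorm(n, 0, 0.5))
    rel <- sim$true_rel
    nit_rel <- rowSums(rel[, sim$truth$guild == "nitrifier", drop = FALSE])
    aoa <- 0.4 * nit_rel * abund_16s * stats::rlnorm(n, 0, 0.2)
    aob <- 0.6 * nit_rel * abund_16s * stats::rlnorm(n, 0, 0.2)
    dil_idx <- as.integer(meta$diversity_level) - 1L
    tetw <- 1e5 * 10^(-1.8 * dil_idx) * stats::rlnorm(n, 0, 0.4)
    tetm <- 6e4 * 10^(-1.8 * dil_idx) * stats::rlnorm(n, 0, 0.4)
    copy <- sim$truth$copy_number
    mean_operon <- as.numeric(rel %*% copy)
    # membership gradient: the latent community axis functions respond to
    membership <- (meta$land_use == scn$land_uses[2]) * 1 + 0.5 * dil_idx
    sir_rel <- rowSums(rel[, sim$truth$genus == sim$sir_genus, drop = FALSE])
    drivers <- cbind(biomass = biomass, membership = membership,
                     nitrifier = aoa + aob, sir_genus = sir_rel)
    lin <- function(fn, intercept) {
      b <- scn$beta[[fn]]
      mu <- rep(intercept, n)
      for (d in names(b)) mu <- mu + b[[d]] * drivers[, d]
      mu + stats::rnorm(n, 0, scn$noise_sd[[fn]])
    }
    respiration <- lin("respiration", 5)
    sir <- pmax(0.1, lin("sir", 2))
    enz_total <- pmax(1, lin("enzyme", 30))
    # split total enzyme activity into the four hydrolases
    shares <- c(bg = 0.4, lap = 0.25, nag = 0.2, ap = 0.15)
    enz <- sapply(names(shares), function(s) {
      pmax(0, enz_total * shares[[s]] * stats::rlnorm(n, 0, 0.05))
    })
    n_min_rate <- lin("n_mineralization", 0.4)
    nitrif_rate <- lin("nitrification", 0.2)
    days <- scn$interval_days
    nh4_t0 <- rep(15, n)
    no3_t0 <- rep(10, n)
    no3_t1 <- pmax(0, no3_t0 + nitrif_rate * days)
    nh4_t1 <- pmax(0, nh4_t0 + (n_min_rate - nitrif_rate) * days)
    proc <- data.frame(sample_id = meta$sample_id,
                       biomass = biomass, dna_yield = dna_yield,
                       abund_16s = abund_16s, abund_its = abund_its,
                       aoa = aoa, aob = aob, tetw = tetw, tetm = tetm,
                       mean_operon_number = mean_operon,
                       respiration = respiration, sir = sir,
                       enzyme_bg = enz[, "bg"], enzyme_lap = enz[, "lap"],
                       enzyme_nag = enz[, "nag"], enzyme_ap = enz[, "ap"],
                       nh4_t0 = nh4_t0, no3_t0 = no3_t0,
                       nh4_t1 = nh4_t1, no3_t1 = no3_t1,
                       interval_days = days,
                       stringsAsFactors = FALSE)
    truth <- list(beta = scn$beta, noise_sd = scn$noise_sd,
                  drivers = data.frame(sample_id = meta$sample_id, drivers,
                                       stringsAsFactors = FALSE),
                  seed = scn$seed)
    list(proc = proc, truth = truth)
  })
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: [simulate_communities()] then [simulate_processes()].
#' @param scn A [simulation_scenario()].
#' @return List with `counts`, `meta`, `proc`, `truth` (community and
#'   process ground truth), `sir_genus`, and `scenario`.
#' @export
simulate_experiment <- function(scn = simulation_scenario()) {
  comm <- simulate_communities(scn)
  pr <- simulate_processes(comm, scn)
  list(counts = comm$counts, meta = comm$meta, proc = pr$proc,
       truth = list(community = comm$truth, process = pr$truth),
       sir_genus = comm$sir_genus, scenario = scn)
}

#' Write a simulated experiment to a directory of TSV files
#'
#' Emits `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `processes.tsv`, and
#' `truth.tsv` (per-taxon guilds) plus `truth_beta.tsv` (generating
#' coefficients and seed).
#' @param sim Output of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"),
                    file.path(dir, "taxonomy.tsv"))
  write_tsv_commented(as.data.frame(sim$meta), file.path(dir, "metadata.tsv"),
                      c("synthetic sample metadata",
                        paste0("seed: ", sim$scenario$seed)))
  write_tsv_commented(sim$proc, file.path(dir, "processes.tsv"),
                      c("synthetic covariates and process measurements",
                        "units: biomass ug C g-1; gene abundances copies g-1;",
                        "respiration/sir ug CO2-C g-1 d-1; enzymes nmol g-1 h-1;",
                        "N pools mg N kg-1; interval_days d",
                        paste0("seed: ", sim$scenario$seed)))
  write_tsv_commented(sim$truth$community, file.path(dir, "truth.tsv"),
                      c("synthetic ground truth: per-taxon guilds and pools",
                        paste0("seed: ", sim$scenario$seed)))
  beta_long <- do.call(rbind, lapply(names(sim$truth$process$beta), function(fn) {
    b <- sim$truth$process$beta[[fn]]
    data.frame(func = fn, driver = names(b), beta = unname(b),
               stringsAsFactors = FALSE)
  }))
  write_tsv_commented(beta_long, file.path(dir, "truth_beta.tsv"),
                      c("synthetic ground truth: generating coefficients",
                        paste0("seed: ", sim$scenario$seed)))
  invisible(dir)
}
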