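test_that("simulation is bit-reproducible and structurally valid", {
  scn <- small_scenario(seed = 12)
  a <- simulate_experiment(scn)
  b <- simulate_experiment(scn)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$proc, b$proc)
  expect_identical(a$meta, b$meta)

  # design: 2 land uses x 3 levels x 2 stress x n replicates
  expect_equal(nrow(a$meta), 2 * 3 * 2 * 2)
  expect_s3_class(a$counts, "count_table")
  # every observed taxon has taxonomy with a phylum
  obs <- colnames(a$counts$counts)[colSums(a$counts$counts) > 0]
  tax <- a$counts$taxonomy
  expect_true(all(!is.na(tax$phylum[match(obs, tax$taxon_id)])))
  # different seed, different data
  c2 <- simulate_experiment(small_scenario(seed = 13))
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("default design yields 60 samples with a monotone dilution gradient", {
  sim <- simulate_communities(simulation_scenario(seed = 1))
  expect_equal(nrow(sim$meta), 60)
  rich <- rowSums(sim$counts$counts > 0)
  for (lu in unique(sim$meta$land_use)) {
    r <- tapply(rich[sim$meta$land_use == lu],
                droplevels(sim$meta$diversity_level[sim$meta$land_use == lu]),
                mean)
    expect_true(r["D0"] > r["D1"] && r["D1"] > r["D2"])
  }
})

test_that("richness ordering D0 > D1 > D2 holds in at least 19 of 20 seeds", {
  ok <- 0L
  for (s in 1:20) {
    sim <- simulate_communities(small_scenario(seed = 200 + s))
    r <- tapply(rowSums(sim$counts$counts > 0), sim$meta$diversity_level, mean)
    ok <- ok + (r["D0"] > r["D1"] && r["D1"] > r["D2"])
  }
  expect_gte(ok, 19)
})

test_that("equal dilution cell counts remove the richness gradient", {
  sim <- simulate_communities(small_scenario(
    seed = 31, dilution_cells = c(D0 = 1e6, D1 = 1e6, D2 = 1e6)))
  rich <- rowSums(sim$counts$counts > 0)
  fit <- anova(lm(rich ~ sim$meta$diversity_level))
  expect_gt(fit$`Pr(>F)`[1], 0.01)
})

test_that("unit stress multipliers make stressed and control D2 exchangeable", {
  n_sig <- 0L
  for (s in 1:20) {
    sim <- simulate_communities(small_scenario(
      seed = 300 + s, n_replicates = 3L,
      stress_multipliers = c(stress_sensitive = 1, stress_tolerant = 1,
                             nitrifier = 1)))
    m <- sim$counts$counts
    sens <- sim$truth$taxon_id[sim$truth$guild == "stress_sensitive"]
    rel <- rowSums(m[, intersect(colnames(m), sens), drop = FALSE]) / rowSums(m)
    d2 <- sim$meta$diversity_level == "D2"
    p <- stats::t.test(rel[d2 & sim$meta$stress == "stressed"],
                       rel[d2 & sim$meta$stress == "control"])$p.value
    n_sig <- n_sig + (p < 0.01)
  }
  expect_lte(n_sig, 2)
})

test_that("stress effects are confined to D2 and raise biomass there", {
  sim <- simulate_experiment(simulation_scenario(seed = 3))
  m <- sim$counts$counts
  sens <- sim$truth$community$taxon_id[sim$truth$community$guild == "stress_sensitive"]
  rel <- rowSums(m[, intersect(colnames(m), sens), drop = FALSE]) / rowSums(m)
  meta <- sim$meta
  mean_by <- function(lv, st) mean(rel[meta$diversity_level == lv & meta$stress == st])
  # big depletion in D2, none planted in D0
  expect_lt(mean_by("D2", "stressed") / mean_by("D2", "control"), 0.6)
  expect_gt(mean_by("D0", "stressed") / mean_by("D0", "control"), 0.8)
  # biomass inflated ~1.69x in stressed D2 only
  d2 <- meta$diversity_level == "D2"
  bio_ratio <- mean(sim$proc$biomass[d2 & meta$stress == "stressed"]) /
    mean(sim$proc$biomass[d2 & meta$stress == "control"])
  expect_gt(bio_ratio, 1.3)
  d0 <- meta$diversity_level == "D0"
  bio_ratio0 <- mean(sim$proc$biomass[d0 & meta$stress == "stressed"]) /
    mean(sim$proc$biomass[d0 & meta$stress == "control"])
  expect_lt(abs(log(bio_ratio0)), log(1.3))
  # fungal establishment fails in diluted treatments
  expect_lt(median(sim$proc$abund_its[meta$diversity_level != "D0"]),
            0.01 * median(sim$proc$abund_its[meta$diversity_level == "D0"]))
})

test_that("relative-abundance expectations are depth-consistent", {
  sim <- simulate_communities(small_scenario(seed = 17))
  p <- sim$true_rel[1, ]
  top <- which.max(p)
  set.seed(99)
  d <- 5e4
  rel1 <- mean(replicate(200, rmultinom(1, d, p)[top] / d))
  rel2 <- mean(replicate(200, rmultinom(1, 2 * d, p)[top] / (2 * d)))
  expect_lt(abs(rel1 - rel2) / p[top], 0.01)
})

test_that("ground truth bookkeeping matches the generating scenario", {
  scn <- small_scenario(seed = 8)
  sim <- simulate_experiment(scn)
  expect_identical(sim$truth$process$beta, scn$beta)
  expect_identical(sim$truth$process$seed, scn$seed)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  expect_true(all(file.exists(file.path(d, c("counts.tsv", "taxonomy.tsv",
                                             "metadata.tsv", "processes.tsv",
                                             "truth.tsv", "truth_beta.tsv")))))
  beta_back <- utils::read.table(file.path(d, "truth_beta.tsv"), sep = "\t",
                                 header = TRUE, comment.char = "#")
  # written coefficients equal those used for generation
  b <- unlist(scn$beta)
  expect_equal(sort(beta_back$beta), sort(unname(b)))
  # count round-trip through the simulation writer
  back <- read_count_table(file.path(d, "counts.tsv"), file.path(d, "taxonomy.tsv"))
  expect_identical(back$counts[rownames(sim$counts$counts),
                               colnames(sim$counts$counts)],
                   sim$counts$counts)
})

test_that("scenario contracts reject impossible designs", {
  expect_error(simulation_scenario(dilution_cells = c(D0 = 1e6, D1 = 0, D2 = 1)),
               "zero inoculum")
  expect_error(simulation_scenario(pool_overlap = 1.2), "pool_overlap")
  expect_error(simulation_scenario(beta = list(sir = c(bogus_driver = 1))),
               "unknown driver")
  expect_error(simulation_scenario(stress_multipliers = c(stress_sensitive = 0,
                                                          stress_tolerant = 1,
                                                          nitrifier = 1)),
               "> 0")
})
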