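test_that("rank aggregation conserves counts and pools unassigned taxa", {
  m <- rbind(s1 = c(3L, 7L, 0L), s2 = c(30L, 30L, 40L))
  colnames(m) <- c("t1", "t2", "t3")
  tb <- make_table(m, phylum = c("Proteobacteria", "Proteobacteria", NA))
  rel <- aggregate_rank(tb, "phylum")
  expect_equal(rel["s1", "Proteobacteria"], 1.0)
  expect_equal(unname(rel["s2", c("Proteobacteria", "Unclassified")]),
               c(0.6, 0.4))
  expect_equal(unname(rowSums(rel)), c(1, 1))
  # aggregated counts conserve sample totals
  expect_equal(unname(rowSums(attr(rel, "agg_counts"))), unname(rowSums(m)))
  expect_error(aggregate_rank(tb, "kingdom"), "unknown rank")
  m0 <- rbind(s1 = c(1L, 1L), s2 = c(0L, 0L))
  expect_error(aggregate_rank(make_table(m0), "phylum"), "zero total")
})

test_that("phylum ratio is finite, symmetric at equality, and monotone", {
  rel <- rbind(s1 = c(A = 0.5, B = 0.5), s2 = c(A = 0.5, B = 0))
  expect_equal(unname(phylum_ratio(rel, "A", "B", pseudo = 0.1)[1]), 1)
  r2 <- phylum_ratio(rel, "A", "B", pseudo = 1e-6)
  expect_equal(unname(r2[2]), 0.5 / 1e-6, tolerance = 1e-5)
  # absent label behaves as zero; both zero -> 1
  relz <- rbind(s1 = c(A = 0, B = 0))
  expect_equal(unname(phylum_ratio(relz, "A", "B")[1]), 1)
  expect_error(phylum_ratio(rel, "A", "B", pseudo = -1), "non-negative")
  # monotone in the numerator at fixed denominator
  grid <- seq(0, 1, by = 0.1)
  vals <- (grid + 1e-6) / (0.3 + 1e-6)
  expect_true(all(diff(vals) > 0))
})

test_that("community-mean operon number renormalizes over known taxa", {
  m <- rbind(s1 = c(10L, 10L, 5L))
  colnames(m) <- c("t1", "t2", "t3")
  tb <- make_table(m)
  # constant map -> constant mean regardless of composition
  expect_equal(mean_operon_number(tb, c(t1 = 4, t2 = 4, t3 = 4))$mean_operon_number, 4)
  # two taxa at equal relative abundance, copies 1 and 7 -> 4
  m2 <- rbind(s1 = c(5L, 5L))
  res <- mean_operon_number(make_table(m2), c(t1 = 1, t2 = 7))
  expect_equal(res$mean_operon_number, 4)
  # unknown taxon: renormalized over known subset, coverage < 1
  res3 <- mean_operon_number(tb, c(t1 = 2, t2 = 6))
  expect_equal(res3$mean_operon_number, (10 * 2 + 10 * 6) / 20)
  expect_equal(res3$coverage, 20 / 25)
  expect_error(mean_operon_number(tb, c(zzz = 3)), "no taxon")
  expect_error(mean_operon_number(tb, c(t1 = 0.5)), ">= 1")
})

test_that("responder screen flags a planted shift and respects contracts", {
  # identical groups: all fold changes zero, nothing flagged
  rel <- matrix(0.25, 8, 4, dimnames = list(paste0("s", 1:8), paste0("t", 1:4)))
  meta <- make_meta(8)
  scr <- responder_screen(rel, meta, "stress", "control", "stressed")
  expect_true(all(scr$log2_fc == 0))
  expect_false(any(scr$flagged))

  # planted 8-fold shift in one taxon with small noise is recovered
  hits <- 0; false_hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 10
    base <- matrix(abs(rnorm(2 * n * 6, 0.1, 0.005)), 2 * n, 6,
                   dimnames = list(paste0("s", seq_len(2 * n)), paste0("t", 1:6)))
    meta2 <- make_meta(2 * n)
    g <- meta2$stress[match(rownames(base), meta2$sample_id)]
    base[g == "stressed", 1] <- base[g == "stressed", 1] * 8
    scr2 <- responder_screen(base, meta2, "stress", "stressed", "control",
                             min_fc = 1, alpha = 0.05)
    hits <- hits + scr2$flagged[scr2$taxon == "t1"]
    false_hits <- false_hits + sum(scr2$flagged & scr2$taxon != "t1")
  }
  expect_gte(hits, 19)
  expect_lte(false_hits / (20 * 5), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))

  # group with < 2 samples errors
  meta1 <- make_meta(8)
  meta1$stress <- c("control", rep("stressed", 7))
  expect_error(responder_screen(rel, meta1, "stress", "control", "stressed"),
               ">= 2 samples")
})

test_that("responder screen false-flag rate under the null stays at alpha", {
  flags <- 0L; tests <- 0L
  for (s in 1:60) {
    set.seed(1000 + s)
    rel <- matrix(abs(rnorm(16 * 5, 0.2, 0.05)), 16, 5,
                  dimnames = list(paste0("s", 1:16), paste0("t", 1:5)))
    meta <- make_meta(16)
    scr <- responder_screen(rel, meta, "stress", "control", "stressed",
                            min_fc = 0, alpha = 0.05)
    flags <- flags + sum(scr$flagged)
    tests <- tests + nrow(scr)
  }
  rate <- flags / tests
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / tests))
})
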