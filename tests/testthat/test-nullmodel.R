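test_that("bray-curtis matches hand values and rejects zero vectors", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_equal(bray_curtis(c(1, 2, 3), c(3, 2, 1)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(1, 1)), "zero-total")
  expect_error(bray_curtis(c(1, 1), c(1, 1, 1)), "length")

  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(rpois(4 * 12, 8), 4, dimnames = list(paste0("s", 1:4), NULL))
  colnames(m) <- paste0("t", 1:12)
  ours <- bray_curtis_matrix(make_table(m))
  ref <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(unclass(ours)[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("null assembly preserves richness and totals on every draw", {
  set.seed(11)
  m <- matrix(rpois(6 * 40, 5), 6, dimnames = list(paste0("s", 1:6), NULL))
  colnames(m) <- paste0("t", 1:40)
  pool <- null_pool(make_table(m))
  for (i in 1:200) {
    pr <- assemble_null_pair(pool, s_x = 12, n_x = 300, s_y = 5, n_y = 5)
    expect_equal(sum(pr$x > 0), 12)
    expect_equal(sum(pr$x), 300)
    # N = S forces all counts exactly 1
    expect_true(all(pr$y[pr$y > 0] == 1))
    expect_equal(sum(pr$y), 5)
  }
  # S = pool size: every eligible taxon drawn
  n_elig <- sum(pool$occurrence > 0)
  pr <- assemble_null_pair(pool, n_elig, n_elig + 10, 2, 2)
  expect_equal(sum(pr$x > 0), n_elig)
  expect_error(assemble_null_pair(pool, n_elig + 1, n_elig + 2, 2, 2),
               "exceeds")
})

test_that("occurrence-weighted draw matches enumeration of the sequential scheme", {
  # pool of 3 taxa, occurrence (1, 1, 0.5), draw S = 2 without replacement:
  # P(taxon 3 included) enumerated over draw orderings
  w <- c(1, 1, 0.5)
  p_incl3 <- w[3] / sum(w) +
    sum(vapply(1:2, function(i) w[i] / sum(w) * w[3] / (sum(w) - w[i]),
               numeric(1)))
  pool <- list(occurrence = w, rel_abund = rep(1 / 3, 3),
               taxon_ids = c("t1", "t2", "t3"))
  set.seed(21)
  n_draw <- 1e4
  hits <- sum(vapply(seq_len(n_draw), function(i) {
    assemble_null_pair(pool, 2, 2, 2, 2)$x[3] > 0
  }, numeric(1)))
  se <- sqrt(p_incl3 * (1 - p_incl3) / n_draw)
  expect_lt(abs(hits / n_draw - p_incl3), 3 * se)
})

test_that("rc pair hits the trivial extremes", {
  set.seed(3)
  m <- matrix(rpois(8 * 30, 6) + 1L, 8, dimnames = list(paste0("s", 1:8), NULL))
  colnames(m) <- paste0("t", 1:30)
  pool <- null_pool(make_table(m))
  # identical samples: obs = 0 below every null draw -> RC = -1
  x <- m[1, ]
  expect_equal(as.numeric(rc_bray_pair(x, x, pool, n_null = 50, seed = 1)), -1)
  # observed above every achievable null: disjoint supports across a pool
  # whose nulls always overlap heavily
  y1 <- c(rep(50L, 15), rep(0L, 15))
  y2 <- c(rep(0L, 15), rep(50L, 15))
  names(y1) <- names(y2) <- colnames(m)
  rc <- rc_bray_pair(y1, y2, pool, n_null = 50, seed = 2)
  expect_equal(attr(rc, "obs_bray"), 1)
  expect_gt(as.numeric(rc), 0.9)
})

test_that("rc matrix is symmetric, bounded, deterministic, label-invariant", {
  sim <- simulate_communities(small_scenario(seed = 4))
  tb <- sim$counts
  tb$counts <- tb$counts[1:6, colSums(tb$counts[1:6, ]) > 0]
  rc1 <- rc_bray_matrix(tb, n_null = 60, seed = 9)
  rc2 <- rc_bray_matrix(tb, n_null = 60, seed = 9)
  expect_identical(unclass(rc1)[, ], unclass(rc2)[, ])
  expect_true(all(rc1 >= -1 & rc1 <= 1))
  expect_equal(max(abs(rc1 - t(rc1))), 0)
  expect_equal(unname(diag(rc1)), rep(-1, 6))
  # permuting sample order permutes the matrix (substreams keyed by id)
  tbp <- tb
  tbp$counts <- tb$counts[6:1, ]
  rc3 <- rc_bray_matrix(tbp, n_null = 60, seed = 9)
  expect_equal(unclass(rc3)[rownames(rc1), colnames(rc1)], unclass(rc1)[, ],
               ignore_attr = TRUE)
  # duplicated sample rows: off-diagonal RC of the duplicate pair is -1
  tbd <- tb
  tbd$counts <- rbind(tb$counts[1:3, ], dup = tb$counts[1, ])
  rcd <- rc_bray_matrix(tbd, n_null = 60, seed = 9)
  expect_equal(rcd[rownames(tb$counts)[1], "dup"], -1)
})

test_that("doubling n_null moves RC by less than the binomial bound", {
  sim <- simulate_communities(small_scenario(seed = 6))
  tb <- sim$counts
  x <- tb$counts[1, ]
  y <- tb$counts[8, ]
  pool <- null_pool(tb)
  r1 <- as.numeric(rc_bray_pair(x, y, pool, n_null = 400, seed = 5))
  r2 <- as.numeric(rc_bray_pair(x, y, pool, n_null = 800, seed = 6))
  expect_lt(abs(r1 - r2), 2 / sqrt(400) + 2 / sqrt(800))
})
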