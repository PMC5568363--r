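# Trial engine: randomization schemes, sample-size regimes, realization,
# allocation enumeration.

test_that("complete-balanced randomization balances arm sizes", {
  s <- four_subjects()
  des <- trial_design(4, "complete-balanced")
  for (sd in 1:10) {
    a <- randomize(s, des, seed = sd)
    expect_equal(sum(a), 2L)
  }
  # odd n: sizes differ by at most 1
  s5 <- four_subjects(c(1, 2, 3, 4, 5))
  a5 <- randomize(s5, trial_design(5, "complete-balanced"), seed = 1)
  expect_true(sum(a5) %in% c(2L, 3L))
})

test_that("simple-coin arm-1 fraction matches the binomial oracle", {
  s <- data.frame(subject_id = 1:10000, cluster_id = 1:10000,
                  category = "c", y_arm0 = 0, y_arm1 = 0)
  a <- randomize(s, trial_design(10000, "simple-coin"), seed = 2)
  expect_lt(abs(mean(a) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("permuted blocks are internally balanced, partial block truncated", {
  n <- 8
  s <- four_subjects(seq_len(n))
  des <- trial_design(n, "permuted-block", block_length = 4)
  for (sd in 1:10) {
    a <- randomize(s, des, seed = sd)
    expect_equal(sum(a[1:4]), 2L)
    expect_equal(sum(a[5:8]), 2L)
  }
  # 10 subjects, b = 4: final partial block of 2 has at most 2 on one arm
  s10 <- four_subjects(seq_len(10))
  a10 <- randomize(s10, trial_design(10, "permuted-block", block_length = 4),
                   seed = 3)
  expect_true(sum(a10[9:10]) %in% 0:2)
  expect_error(trial_design(8, "permuted-block", block_length = 3), "even")
})

test_that("sample-size regimes match their oracles", {
  m <- iid_normal_model()
  s <- sample_subjects(m, 10000, seed = 41)

  # q = 1 keeps everyone
  des1 <- trial_design(10000, regime = "dropout", retention = 1)
  expect_equal(nrow(apply_sample_size_regime(s, des1, seed = 1)), 10000)

  # q = 0.8: retained count within 3 binomial SE of 8000
  des08 <- trial_design(10000, regime = "dropout", retention = 0.8)
  kept <- nrow(apply_sample_size_regime(s, des08, seed = 2))
  expect_lt(abs(kept - 8000), 3 * sqrt(10000 * 0.8 * 0.2))

  # Poisson-total: mean retained within 3 MC SE of lambda
  desP <- trial_design(200, regime = "poisson-total", lambda = 50)
  sP <- sample_subjects(m, 200, seed = 43)
  set.seed(44)
  ns <- vapply(1:2000, function(i)
    nrow(apply_sample_size_regime(sP, desP)), 0L)
  expect_lt(abs(mean(ns) - 50), 3 * sqrt(50 / 2000))

  # event-driven stops at the m-th event; too few events errors clearly
  se <- four_subjects(c(0, 2, 0, 3, 0, 5))
  desE <- trial_design(6, regime = "event-driven", event_threshold = 1,
                       event_target = 2)
  ret <- apply_sample_size_regime(se, desE, seed = 1)
  expect_equal(nrow(ret), 4)
  desE9 <- trial_design(6, regime = "event-driven", event_threshold = 1,
                        event_target = 9)
  expect_error(apply_sample_size_regime(se, desE9, seed = 1), "events")
})

test_that("realize_trial computes means, delta and z correctly", {
  # arm-1 responses {2, 0}, arm-0 responses {1, 1} -> delta = 0
  s <- data.frame(subject_id = 1:4, cluster_id = 1:4, category = "c",
                  y_arm0 = c(9, 1, 9, 1), y_arm1 = c(2, 9, 0, 9))
  tr <- realize_trial(s, c(1L, 0L, 1L, 0L))
  expect_equal(tr$A1, 1.0)
  expect_equal(tr$A0, 1.0)
  expect_equal(tr$delta, 0.0)

  # responses {3, 1} vs {2, 0} -> delta = 1, z vs the hand formula
  s2 <- four_subjects(c(3, 1, 2, 0))
  tr2 <- realize_trial(s2, c(1L, 1L, 0L, 0L))
  expect_equal(tr2$delta, 1.0)
  expect_equal(tr2$z, oracle_welch_z(c(3, 1, 2, 0), c(1, 1, 0, 0)))
  # delta equals difference of recomputed arm means within 1e-12
  expect_lt(abs(tr2$delta - (mean(c(3, 1)) - mean(c(2, 0)))), 1e-12)

  # degenerate arm: z flagged unavailable, delta still reported
  s3 <- four_subjects(c(1, 1, 2, 0))
  tr3 <- realize_trial(s3, c(1L, 1L, 0L, 0L))
  expect_false(tr3$z_ok)
  expect_equal(tr3$delta, 0.0)

  # re-realizing the same allocation is bit-identical
  expect_identical(realize_trial(s2, c(1L, 1L, 0L, 0L)),
                   realize_trial(s2, c(1L, 1L, 0L, 0L)))
  expect_error(realize_trial(s2, c(1L, 0L)), "cover")
})

test_that("pooled and unpooled z agree for balanced equal-variance arms", {
  y <- c(3.2, 1.5, 2.7, 0.1, 4.4, 2.2)
  s <- four_subjects(y)
  a <- c(1L, 0L, 1L, 0L, 1L, 0L)
  tu <- realize_trial(s, a, trial_design(6))
  tp <- realize_trial(s, a, trial_design(6, pooled_variance = TRUE))
  # equal arm sizes: pooled denominator <= or >= unpooled depending on
  # variance split, but both must match their textbook formulas
  y1 <- y[a == 1]; y0 <- y[a == 0]
  vp <- (var(y1) + var(y0)) / 2
  expect_equal(tp$z, (mean(y1) - mean(y0)) / sqrt(vp * (2 / 3)))
  expect_equal(tu$z, oracle_welch_z(y, a))
})

test_that("cluster-unit randomization keeps clusters intact", {
  s <- data.frame(subject_id = 1:8, cluster_id = rep(1:4, each = 2),
                  category = "c", y_arm0 = rnorm(8), y_arm1 = rnorm(8))
  des <- trial_design(8, "complete-balanced", randomization_unit = "cluster")
  for (sd in 1:10) {
    a <- randomize(s, des, seed = sd)
    # both members of every pair share an arm; clusters split 2/2
    expect_true(all(tapply(a, s$cluster_id, function(v) length(unique(v))) == 1))
    expect_equal(sum(a), 4L)
  }
  # permutation inference enumerates cluster-level assignments: C(4,2) = 6
  tr <- realize_trial(s, randomize(s, des, seed = 3), des)
  rep <- permutation_pvalue(tr, des, sided = "two-sided")
  expect_equal(rep$n_allocations_used, 6L)
  expect_true(rep$exact)
  # every enumerated allocation is constant within clusters
  enum <- permtrial:::allocation_set_for_trial(tr, des, limit = 100)
  expect_true(all(apply(enum$allocations, 1, function(a)
    all(tapply(a, s$cluster_id, function(v) length(unique(v))) == 1))))
})

test_that("exact allocation counts match the scheme combinatorics", {
  expect_equal(nrow(enumerate_allocations(
    4, trial_design(4, "complete-balanced"))$allocations), choose(4, 2))
  expect_equal(nrow(enumerate_allocations(
    3, trial_design(3, "simple-coin"))$allocations), 2^3)
  expect_equal(nrow(enumerate_allocations(
    4, trial_design(4, "permuted-block", block_length = 2))$allocations),
    2 * 2)
})

test_that("exact enumeration equals the brute-force oracle (<= 12 subjects)", {
  for (n in c(4, 6, 10, 12)) {
    des <- trial_design(n, "complete-balanced")
    enum <- enumerate_allocations(n, des)
    expect_true(enum$exact)
    oracle <- do.call(rbind, oracle_balanced_allocations(n))
    expect_identical(alloc_key(enum$allocations), alloc_key(oracle))
    expect_equal(nrow(enum$allocations), choose(n, n %/% 2))
  }
  # permuted-block b = 4, n = 8: oracle is the cross of per-block splits
  des <- trial_design(8, "permuted-block", block_length = 4)
  enum <- enumerate_allocations(8, des)
  blocks <- oracle_balanced_allocations(4, 2)
  oracle <- do.call(rbind, unlist(lapply(blocks, function(b1)
    lapply(blocks, function(b2) c(b1, b2))), recursive = FALSE))
  expect_identical(alloc_key(enum$allocations), alloc_key(oracle))
  # every enumerated row is balanced within each block
  expect_true(all(rowSums(enum$allocations[, 1:4]) == 2))
  expect_true(all(rowSums(enum$allocations[, 5:8]) == 2))
})

test_that("beyond the limit, sampling is flagged and follows the scheme", {
  des <- trial_design(30, "complete-balanced")
  enum <- enumerate_allocations(30, des, limit = 500, seed = 6)
  expect_false(enum$exact)
  expect_equal(nrow(enum$allocations), 500)
  expect_true(all(rowSums(enum$allocations) == 15))
  expect_equal(enum$count, choose(30, 15))
})

test_that("sampled complete-balanced allocations are uniform (chi-square)", {
  # n = 4: 6 admissible allocations; 1e5 draws
  des <- trial_design(4, "complete-balanced")
  s <- four_subjects()
  set.seed(55)
  draws <- vapply(1:100000, function(i)
    paste(randomize(s, des), collapse = ""), "")
  counts <- table(draws)
  expect_length(counts, 6)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})
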