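test_that("sample extrapolation rounds half-up and handles edge samples", {
  expect_equal(estimate_relevant_total(100, 5, 10000), 500L)
  expect_equal(estimate_relevant_total(1000, 26, 1000), 26L)  # census identity
  expect_equal(estimate_relevant_total(50, 0, 1000), 0L)
  expect_equal(estimate_relevant_total(3, 1, 10), 3L)   # 3.33 down
  expect_equal(estimate_relevant_total(4, 1, 10), 3L)   # 2.5 half -> up
  expect_error(estimate_relevant_total(0, 0, 10), "n_s")
  expect_error(estimate_relevant_total(5, 6, 10), "r_s")
})

test_that("count-based stop fires at the cumulative threshold", {
  tr <- lab_traj(c(1L, 0L, 1L, 0L, 0L))
  out <- apply_criterion1(tr, 2)
  expect_equal(out$stop_index, 3)
  expect_true(out$triggered)
  expect_equal(out$missed, 0)
  expect_equal(out$work_saved_pct, 40)

  never <- apply_criterion1(tr, 3)   # R_hat > R
  expect_equal(never$stop_index, 5)
  expect_false(never$triggered)
  expect_equal(never$recall, 1)

  late <- apply_criterion1(lab_traj(c(0L, 0L, 1L, 1L)), 1)
  expect_equal(late$stop_index, 3)
  expect_equal(late$missed, 1)
  expect_equal(late$recall, 0.5)

  zero <- apply_criterion1(tr, 0)
  expect_equal(zero$stop_index, 0)
  expect_equal(zero$missed, 2)
  expect_equal(zero$work_saved_pct, 100)
})

test_that("consecutive-irrelevant stop scans streaks with resets and scope", {
  out <- apply_criterion2(lab_traj(c(1L, 0L, 0L, 0L, 1L, 0L)), c = 3,
                          scope = "full")
  expect_equal(out$stop_index, 4)
  expect_equal(out$missed, 1)

  unreach <- apply_criterion2(lab_traj(c(1L, 0L, 0L, 0L, 1L, 0L)), c = 7)
  expect_equal(unreach$stop_index, 6)
  expect_false(unreach$triggered)
  expect_equal(unreach$recall, 1)

  early <- apply_criterion2(lab_traj(c(0L, 0L, 1L, 1L)), c = 2, scope = "full")
  expect_equal(early$stop_index, 2)   # fires before any relevant is seen
  expect_equal(early$found_relevant, 0)

  # active-only: the two prior-phase zeros do not feed the streak
  tr <- lab_traj(c(0L, 0L, 1L, 0L, 0L, 1L), prior_len = 2L)
  expect_equal(apply_criterion2(tr, 2, scope = "active-only")$stop_index, 5)
  expect_equal(apply_criterion2(tr, 2, scope = "full")$stop_index, 2)
})

test_that("fraction-based stop is a ceiling on screened records", {
  tr975 <- rand_traj(975, 74)
  expect_equal(apply_criterion3(tr975, 0.05)$stop_index, 49)
  full <- apply_criterion3(tr975, 1.0)
  expect_equal(full$stop_index, 975)
  expect_equal(full$recall, 1)
  expect_error(apply_criterion3(tr975, 0), "p must be")

  perfect <- lab_traj(c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(apply_criterion3(perfect, 0.5)$missed, 0)
})

test_that("largest interior gap matches its definition and scope", {
  expect_equal(minimal_safe_streak(lab_traj(c(1L, 0L, 0L, 1L)))$g, 2)
  expect_equal(minimal_safe_streak(lab_traj(c(0L, 1L, 1L, 1L, 0L, 0L)))$g, 0)
  expect_equal(minimal_safe_streak(lab_traj(c(1L, 0L, 0L, 1L)))$g_pct, 50)
  # prior-phase gaps are invisible under the default active-only scope
  tr <- lab_traj(c(1L, 0L, 0L, 0L, 1L, 1L, 0L, 1L), prior_len = 5L)
  expect_equal(minimal_safe_streak(tr)$g, 1)
  expect_equal(minimal_safe_streak(tr, scope = "full")$g, 3)
  expect_error(minimal_safe_streak(lab_traj(c(0L, 0L))), "no relevant")
})

test_that("gap distribution matches exhaustive enumeration at N=30, R=3", {
  combs <- utils::combn(30, 3)
  gs <- apply(combs, 2, function(pos) {
    labels <- integer(30); labels[pos] <- 1L
    minimal_safe_streak(lab_traj(labels))$g
  })
  oracle <- apply(combs, 2, function(pos) {
    labels <- integer(30); labels[pos] <- 1L
    bf_interior_gap(labels)
  })
  expect_identical(gs, oracle)
  expect_identical(as.integer(table(gs)), as.integer(table(oracle)))
})

test_that("g + 1 is safe and g misses, relative to the first counted relevant", {
  withr::local_seed(404)
  for (i in 1:300) {
    N <- sample(4:40, 1)
    tr <- rand_traj(N, sample.int(N - 1, 1))
    g <- minimal_safe_streak(tr, scope = "full")$g
    leading <- which(tr$label == 1L)[1] - 1L
    safe <- apply_criterion2(tr, g + 1, scope = "full")
    if (leading <= g) expect_equal(safe$missed, 0)
    if (g >= 1) {
      expect_gte(apply_criterion2(tr, g, scope = "full")$missed, 1)
    }
    # exact break-even threshold against the brute-force scanner
    expect_equal(max(leading, g) + 1L, bf_min_safe_c(tr$label))
  }
})

test_that("missed counts are monotone in the stop thresholds", {
  withr::local_seed(77)
  for (i in 1:50) {
    tr <- rand_traj(30, sample.int(10, 1))
    m2 <- sapply(1:31, function(c) apply_criterion2(tr, c, "full")$missed)
    w2 <- sapply(1:31, function(c) apply_criterion2(tr, c, "full")$work_saved_pct)
    expect_true(all(diff(m2) <= 0))
    expect_true(all(diff(w2) <= 0))
    ps <- seq(0.05, 1, by = 0.05)
    m3 <- sapply(ps, function(p) apply_criterion3(tr, p)$missed)
    expect_true(all(diff(m3) <= 0))
  }
})

test_that("estimate outcomes classify against the true count", {
  expect_equal(classify_c1_outcome(26, 26), "exact")
  expect_equal(classify_c1_outcome(25, 26), "miss_one")
  expect_equal(classify_c1_outcome(500, 26), "overestimate")
  expect_equal(classify_c1_outcome(3, 26), "miss_many")
  expect_error(classify_c1_outcome(1, 0), "R must be")
})

test_that("relative estimation error is signed toward overestimation", {
  expect_equal(relative_estimation_error(500, 500), 0)
  expect_equal(relative_estimation_error(52, 26), 100)
  expect_equal(relative_estimation_error(0, 26), -100)
  expect_error(relative_estimation_error(5, 0), "R must be")
})

test_that("stop outcomes respect their accounting identities", {
  withr::local_seed(91)
  for (i in 1:100) {
    N <- sample(5:40, 1)
    tr <- rand_traj(N, sample.int(N - 1, 1))
    out <- apply_criterion2(tr, sample.int(8, 1), "full")
    expect_true(out$stop_index <= N)
    expect_true(out$missed >= 0 && out$missed <= tr$R)
    expect_equal(out$missed == 0, out$recall == 1)
    expect_equal(out$found_relevant + out$missed, tr$R)
    expect_equal(out$work_saved_pct, (1 - out$stop_index / N) * 100)
  }
})
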