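test_that("c_index handles the canonical examples", {
  expect_equal(c_index(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 0)
  # censoring rule: only pairs whose order is known are used
  expect_equal(c_index(c(1, 5, 3), c(1, 2, 3), c(1, 0, 1)), 1)
  expect_error(c_index(1, 5, 0), "no usable pairs")
})

test_that("c_index equals explicit pair enumeration and is rank-invariant", {
  for (seed in 1:10) {
    ds <- tiny_surv(sample(5:12, 1), seed = 100 + seed, tie_times = TRUE)
    u <- rnorm(n_subjects(ds))
    expect_equal(c_index(u, ds$y, ds$delta), c_index_loop(u, ds$y, ds$delta))
    # strictly increasing transform leaves it unchanged
    expect_equal(c_index(exp(2 * u), ds$y, ds$delta),
                 c_index(u, ds$y, ds$delta))
    # complement under negation (no prediction ties)
    expect_equal(c_index(u, ds$y, ds$delta) + c_index(-u, ds$y, ds$delta), 1)
  }
})

test_that("random predictions center the c-index at 1/2", {
  set.seed(99)
  meds <- replicate(200, {
    ds <- tiny_surv(40, seed = sample.int(1e6, 1), tie_times = FALSE)
    c_index(rnorm(40), ds$y, ds$delta)
  })
  expect_lt(abs(median(meds) - 0.5), 0.03)
})

test_that("logrank_chi2 matches the hand-computed two-group statistic", {
  # groups {1,2} vs {3,4}, all events: chi2 = (7/6)^2 / (17/36)
  u <- c(1, 1.1, 2, 2.1)
  expect_equal(logrank_chi2(u, c(1, 2, 3, 4), rep(1, 4)),
               (0.5 + 2 / 3)^2 / (0.25 + 2 / 9), tolerance = 1e-10)

  # null: identical survival in both groups
  y <- rep(c(1, 2, 3, 4, 5), 2)
  d <- rep(c(1, 1, 0, 1, 1), 2)
  u2 <- rep(c(0, 1), each = 5)  # split orthogonal to survival
  expect_lt(logrank_chi2(u2, y, d), 1e-10)

  # doubling every subject roughly doubles the statistic
  set.seed(3)
  n <- 40; u3 <- rnorm(n); y3 <- rexp(n, exp(-u3)); d3 <- rbinom(n, 1, .8)
  one <- logrank_chi2(u3, y3, d3)
  two <- logrank_chi2(rep(u3, 2), rep(y3, 2), rep(d3, 2))
  expect_equal(two / one, 2, tolerance = 0.35)

  # invariant to monotone transforms of u
  expect_equal(logrank_chi2(rank(u3), y3, d3), one)
})

test_that("hazard_ratio orientation, null, cap and 1-d oracle", {
  set.seed(12)
  y <- rep(c(1, 2, 3, 4, 5, 6), 2); d <- rep(1, 12)
  u_null <- c(rep(0, 6), rep(1, 6))  # two copies of the same curve
  expect_lt(abs(hazard_ratio(u_null, y, d) - 1), 0.5)

  # strong separation: all low-u subjects die before any high-u subject
  ys <- c(1:6 / 10, 1:6 + 10)
  expect_gte(suppressWarnings(hazard_ratio(u_null, ys, d)), 50)

  # moderate two-group case matches the golden-section oracle
  set.seed(13)
  z <- rep(0:1, each = 25)
  yy <- rexp(50, rate = ifelse(z == 1, 2.5, 1))
  u2 <- ifelse(z == 1, 0, 1) + rnorm(50, sd = 1e-3)  # below-median = z group
  hr <- hazard_ratio(u2, yy, rep(1, 50))
  oracle <- exp(abs(golden_cox(yy, rep(1L, 50),
                               as.numeric(u2 <= median(u2)))))
  expect_equal(hr, oracle, tolerance = 1e-3)
})

test_that("wilcoxon_rank_sum: exact small-sample and approximate regimes", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 2 / 6)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2)), 1)   # identical samples
  # agrees with the exact reference implementation when there are no ties
  for (seed in 1:8) {
    set.seed(seed)
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    expect_equal(wilcoxon_rank_sum(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
  # large shifted samples: vanishing p
  set.seed(1)
  expect_lt(wilcoxon_rank_sum(rnorm(100) + 10, rnorm(100)), 1e-10)
  # symmetry under swapping the samples
  a <- rnorm(30); b <- rnorm(35) + 0.5
  expect_equal(wilcoxon_rank_sum(a, b), wilcoxon_rank_sum(b, a))
})

test_that("performance_triple bundles the three measures", {
  set.seed(44)
  ds <- tiny_surv(60, seed = 8, tie_times = FALSE)
  u <- rnorm(60)
  tri <- performance_triple(u, ds$y, ds$delta)
  expect_equal(tri$c_index, c_index(u, ds$y, ds$delta))
  expect_gte(tri$logrank_chi2, 0)
  expect_gte(tri$hazard_ratio, 1)
})
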