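test_that("mean difference follows the treatment-minus-control convention", {
  expect_equal(mean_difference(c(1, 3), c(2, 4)), 1)
  expect_equal(mean_difference(c(5, 5), c(5, 5)), 0)
  expect_error(mean_difference(c(1), numeric(0)), "insufficient data")
})

test_that("hedges_g matches the hand-computed pooled-SD example", {
  # means 3 vs 1, pooled SD 1, df = 4, J = 1 - 3/15 = 0.8
  expect_equal(hedges_g(c(2, 3, 4), c(0, 1, 2)), -1.6)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
})

test_that("hedges_g is scale invariant and antisymmetric", {
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
    expect_equal(hedges_g(a * 10, b * 10), hedges_g(a, b))
    expect_equal(hedges_g(b, a), -hedges_g(a, b))
  }
})

test_that("hedges_g errors on degenerate variance with unequal means", {
  expect_error(hedges_g(c(1, 1, 1), c(2, 2, 2)), "degenerate variance")
  expect_equal(hedges_g(c(1, 1, 1), c(1, 1, 1)), 0)
})

test_that("cliffs_delta matches enumeration on constructed and random fixtures", {
  expect_equal(cliffs_delta(c(0, 0, 4), c(1, 2, 3)), 1 / 3)
  expect_equal(cliffs_delta(c(1, 2), c(3, 4)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(21)
  for (i in 1:50) {
    ctl <- sample(0:6, sample(2:50, 1), replace = TRUE) # heavy ties
    trt <- sample(0:6, sample(2:50, 1), replace = TRUE)
    expect_equal(cliffs_delta(ctl, trt), oracle_cliffs_delta(ctl, trt))
    expect_equal(cliffs_delta(trt, ctl), -cliffs_delta(ctl, trt))
  }
})

test_that("cliffs_delta converges to the latent-normal dominance probability", {
  set.seed(31)
  d <- 0.9
  ctl <- rnorm(1e4)
  trt <- rnorm(1e4, d)
  expect_equal(cliffs_delta(ctl, trt), 2 * pnorm(d / sqrt(2)) - 1,
               tolerance = 0.02)
})

test_that("mann_whitney_p is exact for small tie-free samples and symmetric", {
  # all 6 orderings of ranks: U = 0 is one of two extremes -> P = 2/6
  expect_equal(mann_whitney_p(c(3, 4), c(1, 2)), 1 / 3)
  expect_equal(mann_whitney_p(c(1, 2), c(3, 4)),
               mann_whitney_p(c(3, 4), c(1, 2)))
  expect_equal(mann_whitney_p(c(1, 2), c(1, 2)), 1)
  # large tie-free samples switch to the normal approximation and stay close
  set.seed(41)
  a <- rnorm(25)
  b <- rnorm(25, 0.5)
  expect_equal(mann_whitney_p(a, b, exact_max = 1e6),
               mann_whitney_p(a, b, exact_max = 1),
               tolerance = 0.05)
})

test_that("bootstrap_ci is seeded, percentile-consistent and degenerate-safe", {
  set.seed(51)
  ctl <- rnorm(20)
  trt <- rnorm(20, 1)
  ci1 <- bootstrap_ci(ctl, trt, "mean_difference", B = 1000, seed = 9)
  ci2 <- bootstrap_ci(ctl, trt, "mean_difference", B = 1000, seed = 9)
  expect_identical(ci1, ci2)
  point <- mean_difference(ctl, trt)
  expect_lte(ci1[["low"]], point)
  expect_gte(ci1[["high"]], point)
  # all-identical samples: the interval collapses to [0, 0]
  const <- bootstrap_ci(rep(2, 5), rep(2, 5), "mean_difference",
                        B = 1000, seed = 1)
  expect_equal(unname(const), c(0, 0))
  expect_error(bootstrap_ci(c(1), c(1, 2), B = 1000), "insufficient data")
})

test_that("bootstrap_ci fast paths agree with the generic callable path", {
  set.seed(61)
  ctl <- rnorm(15)
  trt <- rnorm(12, 0.8)
  for (stat in c("mean_difference", "hedges_g", "cliffs_delta")) {
    fast <- bootstrap_ci(ctl, trt, stat, B = 2000, seed = 5)
    slow <- bootstrap_ci(ctl, trt, stat, B = 2000, seed = 5)
    expect_identical(fast, slow)
    fn <- switch(stat, mean_difference = mean_difference,
                 hedges_g = hedges_g, cliffs_delta = cliffs_delta)
    generic <- bootstrap_ci(ctl, trt, fn, B = 2000, seed = 5)
    # different resampling order, same distribution: intervals agree closely
    expect_lt(max(abs(unname(fast) - unname(generic))), 0.3)
  }
})

test_that("BCa intervals bracket the point estimate too", {
  set.seed(71)
  ctl <- rnorm(20)
  trt <- rnorm(20, 0.7)
  ci <- bootstrap_ci(ctl, trt, "hedges_g", B = 2000, seed = 3, method = "bca")
  g <- hedges_g(ctl, trt)
  expect_lt(ci[[1]], g)
  expect_gt(ci[[2]], g)
})

test_that("magnitude labels use half-open bins on the absolute effect", {
  expect_equal(classify_magnitude(0.53, "g"), "moderate")
  expect_equal(classify_magnitude(-1.24, "g"), "large")
  expect_equal(classify_magnitude(0.19, "g"), "negligible")
  expect_equal(classify_magnitude(0.2, "g"), "small")
  expect_equal(classify_magnitude(0.8, "g"), "large")
  expect_equal(classify_magnitude(0.10, "delta"), "negligible")
  expect_equal(classify_magnitude(0.147, "delta"), "small")
  expect_equal(classify_magnitude(-0.47, "delta"), "large")
  expect_error(classify_magnitude(0.5, "q"))
})

test_that("estimate_effect assembles a coherent effect row", {
  set.seed(81)
  ctl <- rnorm(30, 10, 2)
  trt <- rnorm(30, 12, 2)
  est <- estimate_effect(ctl, trt, metric = "demo", B = 1000, seed = 4)
  expect_s3_class(est, "tbl_df")
  expect_equal(est$delta_raw, mean(trt) - mean(ctl))
  expect_equal(est$effect, hedges_g(ctl, trt))
  expect_lte(est$ci_low, est$effect)
  expect_gte(est$ci_high, est$effect)
  expect_equal(est$n_c, 30)
  expect_equal(est$n_t, 30)
  expect_equal(est$magnitude, classify_magnitude(est$effect, "g"))
  # ordinal route uses Cliff's delta
  est_d <- estimate_effect(c(0, 1, 2, 3), c(2, 3, 4, 5), estimator = "delta",
                           B = 1000, seed = 4)
  expect_equal(est_d$effect, cliffs_delta(c(0, 1, 2, 3), c(2, 3, 4, 5)))
  expect_true(abs(est_d$effect) <= 1)
})

test_that("hedges_g recovers the truth on average across the SMD range", {
  set.seed(91)
  for (true in c(-2, -0.5, 0, 1.2)) {
    reps <- 400
    est <- replicate(reps, {
      g <- gen_two_group(12, 12, true)
      hedges_g(g$control, g$treatment)
    })
    mc_se <- sd(est) / sqrt(reps)
    expect_lt(abs(mean(est) - true), 3 * mc_se + 0.01)
  }
})
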