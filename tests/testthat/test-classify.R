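test_that("recruitment geometry follows the definitions", {
  p <- recruitment_pattern(c(5.0, 5.1, 5.3))
  expect_equal(unname(p$t), c(0, 0.1, 0.3))
  expect_equal(p$r, 0.3)
  expect_equal(p$l, 0.2)

  p2 <- recruitment_pattern(rep(4.2, 6))
  expect_equal(p2$r, 0)
  expect_equal(p2$l, 0)

  # the lag into the last channel dominates
  p3 <- recruitment_pattern(c(0, 0.1, 0.15, 1.2) + 5)
  expect_equal(p3$l, 1.05)
  expect_equal(p3$r, 1.2)

  expect_error(recruitment_pattern(c(5, NA, 6)), "filter")
  expect_true(p3$l <= p3$r)
})

test_that("printed discriminant boundaries classify the exemplars", {
  # direct evaluation of the published coefficients
  expect_equal(classify_domino(0.2, 0.05), "fast")
  expect_equal(classify_domino(3.0, 0.1), "slow")
  expect_equal(classify_domino(1.0, 0.8), "multi")
  # vectorised
  expect_equal(classify_domino(c(0.2, 3, 1), c(0.05, 0.1, 0.8)),
               c("fast", "slow", "multi"))
})

test_that("classification is a total partition of the (r, l) plane", {
  rs <- seq(0, 5, length.out = 60)
  for (r in rs) {
    ls <- seq(0, r, length.out = 25)
    cls <- classify_domino(rep(r, length(ls)), ls)
    expect_true(all(cls %in% c("fast", "slow", "multi")))
    cls2 <- classify_domino(rep(r, length(ls)), ls)
    expect_identical(cls, cls2)
  }
})

test_that("initial thresholds implement the 0.5 s / 0.4 s rule", {
  expect_equal(initial_grouping(0.3, 0.1), "fast")
  expect_equal(initial_grouping(0.8, 0.2), "slow")
  expect_equal(initial_grouping(1.2, 0.6), "multi")
  # lag takes precedence even for small r
  expect_equal(initial_grouping(0.45, 0.42), "multi")
  # deep-region exemplars agree between the seed rule and the
  # published discriminants
  ex <- rbind(c(0.2, 0.05), c(3, 0.1), c(1, 0.8))
  expect_equal(initial_grouping(ex[, 1], ex[, 2]),
               classify_domino(ex[, 1], ex[, 2]))
})

test_that("refitted discriminants separate well-separated clouds", {
  set.seed(5)
  n <- 40
  r <- c(rnorm(n, 0.2, 0.04), rnorm(n, 3.0, 0.3), rnorm(n, 1.0, 0.2))
  l <- c(rnorm(n, 0.05, 0.01), rnorm(n, 0.1, 0.02), rnorm(n, 0.8, 0.1))
  lab <- rep(c("fast", "slow", "multi"), each = n)
  b <- fit_lda_boundaries(r, l, lab)
  # each pairwise line separates its own pair perfectly
  L1 <- b$c1[1] + b$c1[2] * r + b$c1[3] * l
  expect_true(all(L1[lab == "fast"] > 0))
  expect_true(all(L1[lab == "slow"] < 0))
  L2 <- b$c2[1] + b$c2[2] * r + b$c2[3] * l
  expect_true(all(L2[lab == "fast"] > 0))
  expect_true(all(L2[lab == "multi"] < 0))
  # sign structure matches the published boundaries
  expect_lt(b$c1[2], 0)   # L1 decreases with r
  expect_lt(b$c1[3], 0)   # and with l
  expect_lt(b$c2[3], 0)   # L2 decreases with l
})

test_that("refitting on threshold-labelled data is self-consistent", {
  set.seed(6)
  r <- runif(600, 0, 3)
  l <- runif(600) * r
  lab <- initial_grouping(r, l)
  b <- fit_lda_boundaries(r, l, lab)
  # pairwise agreement away from the threshold lines: each refit line
  # reproduces its own threshold decision
  fs <- lab != "multi" & abs(r - 0.5) > 0.35
  L1 <- b$c1[1] + b$c1[2] * r[fs] + b$c1[3] * l[fs]
  expect_gte(mean((L1 > 0) == (lab[fs] == "fast")), 0.95)
  fm <- lab != "slow" & abs(l - 0.4) > 0.3
  L2 <- b$c2[1] + b$c2[2] * r[fm] + b$c2[3] * l[fm]
  expect_gte(mean((L2 > 0) == (lab[fm] == "fast")), 0.95)
})

test_that("fitted boundaries match a pooled-covariance oracle", {
  set.seed(7)
  n <- 60
  r <- c(rnorm(n, 0.3, 0.1), rnorm(n, 2.5, 0.4))
  l <- c(rnorm(n, 0.05, 0.02), rnorm(n, 0.1, 0.03))
  lab <- rep(c("fast", "slow"), each = n)
  b <- fit_lda_boundaries(r, l, lab)
  expect_equal(attr(b, "refitted"), "L1")
  expect_equal(b$c2, lda_boundaries()$c2)   # missing pair keeps default

  # independent Fisher discriminant: w = S_pooled^{-1} (mu1 - mu2)
  X <- cbind(r, l)
  mu1 <- colMeans(X[lab == "fast", ]); mu2 <- colMeans(X[lab == "slow", ])
  S <- ((n - 1) * cov(X[lab == "fast", ]) +
        (n - 1) * cov(X[lab == "slow", ])) / (2 * n - 2)
  w <- solve(S, mu1 - mu2)
  a <- -sum(w * (mu1 + mu2) / 2)
  # same boundary up to positive scale
  scale_ratio <- b$c1[2] / w[1]
  expect_gt(scale_ratio, 0)
  expect_equal(b$c1 / scale_ratio, unname(c(a, w)), tolerance = 1e-6)

  expect_error(fit_lda_boundaries(r[1:2], l[1:2], lab[1:2]), "at least")
})
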