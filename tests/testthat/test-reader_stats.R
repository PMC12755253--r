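# Kruskal-Wallis, Dunn/Holm, the Likert winner rule, preference rates and
# the exact binomial test.

test_that("Kruskal-Wallis: hand-computed H, degenerate guard, identical
           groups", {
  kw <- kruskalWallis(list(c(1, 2), c(3, 4)))
  expect_equal(kw$H, 2.4, tolerance = 1e-12)  # 12/20 * (2*1 + 2*1)
  expect_identical(kw$df, 1L)
  kw0 <- kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw0$H, 0, tolerance = 1e-12)
  deg <- kruskalWallis(list(c(5, 5), c(5, 5, 5)))
  expect_true(deg$degenerate)
  expect_equal(deg$H, 0)
  expect_error(kruskalWallis(list(1:3)), "groups")
})

test_that("Kruskal-Wallis matches stats::kruskal.test on random instances", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      round(rnorm(sample(3:12, 1), mean = j * runif(1)), sample(0:2, 1)))
    if (length(unique(unlist(groups))) < 2) next
    mine <- kruskalWallis(groups)
    ref <- kruskal.test(groups)
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("Holm step-down follows the textbook arithmetic and p.adjust", {
  dh <- dunnHolm(list(rnorm(5), rnorm(5, 2), rnorm(5, 4)))
  expect_identical(nrow(dh), 3L)
  expect_true(all(dh$p_holm >= dh$p_raw - 1e-15))
  expect_true(all(dh$p_holm <= 1))
  expect_equal(MambaSR:::.holm(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(MambaSR:::.holm(c(0.4)), 0.4)  # single pair: no correction
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:6, 1))
    expect_equal(MambaSR:::.holm(p), p.adjust(p, "holm"), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(MambaSR:::.holm(p)[o]) >= -1e-15))
  }
})

test_that("Dunn z statistics match a direct rank computation with ties", {
  # 3 groups with ties; z computed from first principles here as oracle
  g <- list(a = c(1, 2, 2, 5), b = c(2, 3, 6), c = c(4, 6, 6, 7, 8))
  x <- unlist(g)
  r <- rank(x)
  Rbar <- tapply(r, rep(1:3, lengths(g)), mean)
  n <- length(x)
  tie <- table(x)
  sig2 <- n * (n + 1) / 12 - sum(tie^3 - tie) / (12 * (n - 1))
  zExp <- (Rbar[1] - Rbar[2]) / sqrt(sig2 * (1 / 4 + 1 / 3))
  dh <- dunnHolm(g)
  expect_equal(dh$z[dh$group1 == "a" & dh$group2 == "b"], unname(zExp),
               tolerance = 1e-12)
  expect_equal(dh$p_raw, 2 * pnorm(-abs(dh$z)), tolerance = 1e-12)
})

test_that("the winner rule follows the three branches exactly", {
  expect_identical(likertWinner(5, 3), "a")
  expect_identical(likertWinner(2, 4), "b")
  expect_identical(likertWinner(3, 3), "tie")
})

test_that("preference rate reproduces the published head-to-head values", {
  expect_equal(round(preferenceRate(28, 5), 3), 0.848)
  expect_equal(round(preferenceRate(22, 4), 3), 0.846)
  expect_equal(preferenceRate(7, 7), 0.5)
  expect_error(preferenceRate(0, 0), "ties")
})

test_that("exact binomial test: published p-values, closed forms, symmetry", {
  expect_equal(exactBinomialTwoSided(28, 33), 6.6e-5, tolerance = 0.01)
  expect_equal(exactBinomialTwoSided(22, 26), 5.3e-4, tolerance = 0.01)
  expect_equal(exactBinomialTwoSided(3, 3), 0.25)   # 2 * (1/2)^3
  expect_equal(exactBinomialTwoSided(0, 1), 1)
  expect_equal(exactBinomialTwoSided(5, 10), 1)
  set.seed(9)
  for (i in 1:25) {
    n <- sample(1:60, 1)
    k <- sample(0:n, 1)
    p <- exactBinomialTwoSided(k, n)
    expect_equal(p, exactBinomialTwoSided(n - k, n), tolerance = 1e-14)
    expect_equal(p, binom.test(k, n, 0.5)$p.value, tolerance = 1e-10)
    expect_true(p > 0 && p <= 1)
  }
  expect_error(exactBinomialTwoSided(5, 3), "<=")
})

test_that("preference analysis enumerates winners, rates, ties and the
           matrix convention", {
  tab <- data.frame(dataset = "d", reader = 1,
                    case = rep(1:3, each = 2),
                    method = rep(c("A", "B"), 3),
                    score = c(5, 3, 4, 4, 2, 1))
  res <- preferenceAnalysis(tab)
  pr <- res$pairs
  expect_identical(pr$wins_a, 2L)
  expect_identical(pr$wins_b, 0L)
  expect_identical(pr$ties, 1L)
  expect_equal(pr$preference_rate, 1.0)
  expect_equal(res$matrix["A", "B"], 1.0)
  expect_equal(res$matrix["B", "A"], 0.0)
  expect_equal(unname(diag(res$matrix)), c(0.5, 0.5))
  expect_equal(res$overall$overall_rate[res$overall$method == "A"], 1)
  # descriptives: sample SD and interpolated quartiles
  dA <- res$descriptives[res$descriptives$method == "A", ]
  expect_equal(dA$mean, mean(c(5, 4, 2)))
  expect_equal(dA$sd, sd(c(5, 4, 2)))
  expect_equal(dA$median, 4)
})

test_that("preference analysis: invariants on synthetic multi-method tables", {
  spec <- syntheticReaderSpec(methods = c("m1", "m2", "m3"),
                              nCases = 25, nReaders = 3,
                              qualityMeans = c(2.0, 3.2, 4.4), seed = 3)
  res <- preferenceAnalysis(generateLikertTable(spec))
  pr <- res$pairs
  for (i in seq_len(nrow(pr))) {
    # conservation: wins + losses + ties == shared instances (75)
    expect_identical(pr$wins_a[i] + pr$wins_b[i] + pr$ties[i], 75L)
    # antisymmetry through the matrix
    a <- pr$method_a[i]; b <- pr$method_b[i]
    if (!is.na(res$matrix[a, b]))
      expect_equal(res$matrix[a, b] + res$matrix[b, a], 1)
  }
  expect_error(preferenceAnalysis(
    data.frame(dataset = 1, reader = 1, case = 1, method = "x", score = 9)),
    "1..5", fixed = TRUE)
  # single method: descriptives only
  one <- preferenceAnalysis(data.frame(dataset = 1, reader = 1, case = 1:4,
                                       method = "x", score = c(1, 3, 3, 5)))
  expect_identical(nrow(one$pairs), 0L)
  expect_identical(one$descriptives$n, 4L)
})
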