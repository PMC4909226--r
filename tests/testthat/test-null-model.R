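test_that("mutation burden is unique positions over length, with saturation", {
  p <- newProfile("G", "T", 600, stats::setNames(rep(1, 12), 1:12))
  expect_equal(mutationBurden(p), 0.02)
  sat <- newProfile("G", "T", 3, stats::setNames(rep(2, 3), 1:3))
  expect_equal(mutationBurden(sat), 1)
})

test_that("gamma is the mean of per-gene alpha/mu coefficients", {
  # gene 1: alpha = 0.2, mu = 0.02 -> coefficient 10
  g1 <- newProfile("G1", "T", 500, stats::setNames(rep(1, 10), 1:10),
                   matchedPositions = 1:2)
  # gene 2: alpha = 0.1, mu = 0.005 -> coefficient 20
  g2 <- newProfile("G2", "T", 2000, stats::setNames(rep(1, 10), 1:10),
                   matchedPositions = 1L)
  m <- estimateGamma(list(g1, g2))[["T"]]
  expect_equal(gammaHat(m), 15)
  expect_equal(unname(alphaBackground(m, "G1")), 15 * 10 / 500)
  expect_equal(m@geneTable$alpha_obs, c(0.2, 0.1))
})

test_that("degenerate zero-match data floors the background rate instead of zeroing it", {
  g <- newProfile("G1", "T", 500, stats::setNames(rep(1, 10), 1:10))
  m <- estimateGamma(list(g))[["T"]]
  expect_equal(gammaHat(m), 0)
  expect_equal(unname(alphaBackground(m, "G1")), 1e-6)
  expect_true(m@geneTable$floored)
  # so an observed positive score is not infinitely significant
  nd <- sampleNullDistribution(g, alphaBackground(m, "G1"), nMin = 1000,
                               nMax = 1000, seed = 1, observedS = 0.5)
  expect_gt(permutationPvalue(0.5, nd), 0)
})

test_that("background rates clamp into [epsilon, 1] and gamma can be fixed", {
  g <- newProfile("G1", "T", 100,
                  stats::setNames(rep(1, 50), 1:50), matchedPositions = 1:10)
  m <- estimateGamma(list(g), gamma = 10)[["T"]]
  expect_equal(gammaHat(m), 10)
  expect_equal(unname(alphaBackground(m, "G1")), 1)  # 10 * 0.5 clamped
  expect_true(m@geneTable$clamped)
})

test_that("expressed-only gamma estimation selects genes by expression value", {
  g1 <- newProfile("G1", "T", 500, stats::setNames(rep(1, 10), 1:10), 1:2)
  g2 <- newProfile("G2", "T", 2000, stats::setNames(rep(1, 10), 1:10), 1L)
  expr <- data.frame(gene = c("G1", "G2"), study = "T", value = c(8, 0.2),
                     expressed = c(TRUE, FALSE))
  m_all <- estimateGamma(list(g1, g2), expr, genes = "all")[["T"]]
  m_expr <- estimateGamma(list(g1, g2), expr, genes = "expressed")[["T"]]
  expect_equal(gammaHat(m_all), 15)
  expect_equal(gammaHat(m_expr), 10)   # only G1 (value 8 >= cutoff 1)
  expect_error(estimateGamma(list(g1, g2), expr, exprCutoff = 100,
                             genes = "expressed"),
               "no contributing genes")
})

test_that("the exact enumeration reproduces the hand-computed four-point null", {
  # counts {3, 1}, alpha = 0.5: S in {0, .25, .75, 1} each with mass 1/4
  p <- newProfile("G", "T", 100, c("10" = 3, "20" = 1))
  e <- enumerateNullExact(p, 0.5)
  expect_equal(e$S, c(0, 0.25, 0.75, 1))
  expect_equal(e$prob, rep(0.25, 4))
  expect_equal(exactTailProbability(e, 0.75), 0.5)

  # alpha = 0 is a point mass at zero
  e0 <- enumerateNullExact(p, 0)
  expect_equal(e0, data.frame(S = 0, prob = 1), ignore_attr = TRUE)

  # uniform counts reduce to the plain binomial over k/n
  pu <- newProfile("G", "T", 100, stats::setNames(rep(2, 6), 1:6))
  eu <- enumerateNullExact(pu, 0.3)
  expect_equal(eu$S, (0:6) / 6)
  expect_equal(eu$prob, dbinom(0:6, 6, 0.3))
})

test_that("the enumeration DP agrees with a brute-force subset oracle", {
  set.seed(7)
  for (i in 1:10) {
    p <- random_profile(n_max = 7)
    alpha <- runif(1)
    e <- enumerateNullExact(p, alpha)
    o <- brute_force_null(unname(p@caseCounts), alpha)
    expect_equal(e$S, o$S, tolerance = 1e-12)
    expect_equal(e$prob, o$prob, tolerance = 1e-12)
    expect_equal(sum(e$prob), 1, tolerance = 1e-12)
  }
})

test_that("enumeration refuses large profiles and bad alpha", {
  big <- newProfile("G", "T", 100, stats::setNames(rep(1, 25), 1:25))
  expect_error(enumerateNullExact(big, 0.5), "sampleNullDistribution")
  p <- newProfile("G", "T", 100, c("10" = 1))
  expect_error(enumerateNullExact(p, 1.2), "alpha")
  expect_error(sampleNullDistribution(p, -0.1), "alpha")
})

test_that("sampled null matches the exact distribution and its mean", {
  p <- newProfile("G", "T", 100, c("5" = 3, "9" = 1, "44" = 2))
  e <- enumerateNullExact(p, 0.4)
  nd <- sampleNullDistribution(p, 0.4, nMin = 2e4, nMax = 2e4, seed = 9)
  expect_equal(nd@nDraws, 2e4)
  exact_mean <- sum(e$S * e$prob)
  se <- sqrt(sum((e$S - exact_mean)^2 * e$prob) / nd@nDraws)
  expect_lt(abs(mean(nd@draws) - exact_mean), 3 * se)
  # per-atom frequencies converge too
  for (i in seq_len(nrow(e))) {
    f <- mean(abs(nd@draws - e$S[i]) < 1e-9)
    expect_lt(abs(f - e$prob[i]),
              3 * sqrt(e$prob[i] * (1 - e$prob[i]) / nd@nDraws) + 1e-9)
  }
})

test_that("degenerate alphas give constant null scores", {
  p <- newProfile("G", "T", 100, c("5" = 3, "9" = 1))
  nd0 <- sampleNullDistribution(p, 0, nMin = 500, nMax = 500, seed = 1)
  expect_true(all(nd0@draws == 0))
  nd1 <- sampleNullDistribution(p, 1, nMin = 500, nMax = 500, seed = 1)
  expect_true(all(nd1@draws == 1))
})

test_that("the adaptive rule stops early for clearly null genes and escalates for extreme ones", {
  p <- newProfile("G", "T", 200,
                  stats::setNames(rep(1, 20), 1:20), matchedPositions = 1:20)
  # observed S = 1 under alpha = 0.05: exceedances essentially never occur,
  # so sampling runs to the maximum
  ndhi <- sampleNullDistribution(p, 0.05, nMin = 1000, nMax = 5000, seed = 2,
                                 keepDraws = FALSE)
  expect_equal(ndhi@nDraws, 5000L)
  # observed S = 0 stops at the minimum with every draw an exceedance
  ndlo <- sampleNullDistribution(p, 0.05, nMin = 1000, nMax = 5000, seed = 2,
                                 observedS = 0, keepDraws = FALSE)
  expect_equal(ndlo@nDraws, 1000L)
  expect_equal(ndlo@exceedances, 1000L)
})

test_that("permutation p-values use the add-one estimator on the upper tail", {
  p <- newProfile("G", "T", 100, c("5" = 3, "9" = 1))
  nd <- sampleNullDistribution(p, 0.5, nMin = 1e4, nMax = 1e4, seed = 3,
                               observedS = 0.75)
  # exact tail at 0.75 is 0.5
  expect_lt(abs(permutationPvalue(null = nd) - 0.5),
            3 * sqrt(0.25 / 1e4) + 2e-4)
  # S = 0: every draw exceeds, p = 1
  expect_equal(permutationPvalue(0, nd), 1)
  # S above every draw: the estimator floor 1/(1+n)
  expect_equal(permutationPvalue(2, nd), 1 / (1 + 1e4))
})

test_that("sampled p-values agree with the exact tail within 3 binomial SEs", {
  # the dual-route check on a batch of random small profiles
  set.seed(2024)
  for (i in 1:8) {
    p <- random_profile(n_max = 8)
    alpha <- runif(1, 0.05, 0.95)
    sobs <- matchScore(p) + runif(1)  # arbitrary threshold in [0, 2]
    sobs <- min(sobs, 1)
    e <- exactTailProbability(enumerateNullExact(p, alpha), sobs)
    nd <- sampleNullDistribution(p, alpha, nMin = 1e4, nMax = 1e4,
                                 seed = 100 + i, observedS = sobs)
    se <- sqrt(e * (1 - e) / 1e4)
    expect_lt(abs(permutationPvalue(null = nd) - e), 3 * se + 2e-4)
  }
})

test_that("null p-values are conservative on matched-at-background profiles", {
  # plant matches at exactly alpha_bg per position; the add-one estimator
  # should make P(p <= x) <= x (checked at a few x over many small genes)
  set.seed(77)
  alpha <- 0.3
  pvals <- replicate(400, {
    n <- sample(4:10, 1)
    counts <- stats::setNames(1 + rpois(n, 1), sample.int(200, n))
    matched <- as.integer(names(counts))[runif(n) < alpha]
    prof <- newProfile("G", "T", 300, counts, matched)
    e <- enumerateNullExact(prof, alpha)
    exactTailProbability(e, matchScore(prof))  # exact p, no MC noise
  })
  for (x in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(pvals <= x), x + 3 * sqrt(x * (1 - x) / 400))
})
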