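test_that("the simulation panel honors its parameter ranges and unit-count rounding", {
  ds <- generateSimulationPanel(nGenes = 60, seed = 42)
  tr <- truthTable(ds)
  expect_equal(nrow(tr), 60L)
  expect_true(all(tr$L >= 10 & tr$L <= 8000))
  expect_true(all(tr$matches >= 1 & tr$matches <= 100))
  expect_true(all(tr$target_score >= 0.01 & tr$target_score <= 0.99))
  expect_true(all(tr$scale >= 1 & tr$scale <= 50))
  expect_true(all(tr$matches + tr$unmatched_positions <= tr$L))
  # achieved score equals the target within one unit case
  expect_true(all(abs(tr$achieved_score - tr$target_score) <=
                    1 / tr$unit_cases))

  # the generated tables reproduce the planted configuration exactly
  prof <- buildProfiles(ds@somatic, filterPathogenic(ds@disease),
                        ds@proteome, criterion = "exact_change")
  tab <- profileTable(prof)
  m <- match(tab$gene, tr$gene)
  expect_equal(tab$S, tr$achieved_score[m], tolerance = 1e-12)
  expect_equal(tab$m, tr$matches[m])
  expect_equal(tab$n, tr$matches[m] + tr$unmatched_positions[m])
})

test_that("panel generation is deterministic and supports empty panels", {
  a <- generateSimulationPanel(nGenes = 10, seed = 7)
  b <- generateSimulationPanel(nGenes = 10, seed = 7)
  expect_identical(a@somatic, b@somatic)
  expect_identical(truthTable(a), truthTable(b))
  c <- generateSimulationPanel(nGenes = 10, seed = 8)
  expect_false(identical(a@somatic, c@somatic))
  empty <- generateSimulationPanel(nGenes = 0, seed = 1)
  expect_equal(nrow(empty@somatic), 0L)
})

test_that("all three match criteria coincide on synthetic data", {
  ds <- generateSimulationPanel(nGenes = 15, seed = 3)
  dis <- filterPathogenic(ds@disease)
  pe <- profileTable(buildProfiles(ds@somatic, dis, ds@proteome,
                                   "exact_change"))
  pp <- profileTable(buildProfiles(ds@somatic, dis, ds@proteome,
                                   "position_only"))
  expect_equal(pe$m, pp$m)
  expect_equal(pe$S, pp$S)
})

test_that("null datasets realize the planted background match law", {
  ds <- generateNullDataset(600, gammaTrue = 10, seed = 12)
  tr <- truthTable(ds)
  expect_true(all(tr$status == "null"))
  expect_true(all(tr$alpha_true <= 1 & tr$alpha_true >= 0))
  # law of large numbers: realized m/n tracks alpha_true across genes
  expect_lt(abs(mean(tr$m_true / tr$n - tr$alpha_true)), 0.01)
  # gamma = 0 plants nothing
  ds0 <- generateNullDataset(20, gammaTrue = 0, seed = 1)
  expect_equal(nrow(ds0@disease), 0L)
  expect_equal(sum(truthTable(ds0)$m_true), 0L)
})

test_that("gamma estimation recovers the planted coefficient", {
  ds <- generateNullDataset(1000, gammaTrue = 10, seed = 31)
  prof <- buildProfiles(ds@somatic, filterPathogenic(ds@disease), ds@proteome)
  g <- gammaHat(estimateGamma(prof)[["SIMNULL"]])
  expect_lt(abs(g - 10) / 10, 0.1)
})

test_that("planted enriched genes and the saturated long-gene analog are generated as declared", {
  ds <- generateNullDataset(50, gammaTrue = 10, seed = 5, nEnriched = 8,
                            ryr2Analog = TRUE)
  tr <- truthTable(ds)
  expect_equal(sum(tr$status == "enriched"), 8L)
  expect_equal(sum(tr$status == "ryr2_analog"), 1L)
  enr <- tr[tr$status == "enriched", ]
  expect_true(all(enr$total_cases >= 5))
  expect_true(all(enr$alpha_true >= 10 * 10 * 0.004 - 1e-9 |
                    enr$alpha_true == 0.95))
  ry <- tr[tr$status == "ryr2_analog", ]
  expect_equal(ry$alpha_true, 1)        # saturated background
  expect_true(all(tr$expressed_true[tr$status != "null"]))
  # every gene appears in all four tables
  expect_true(all(tr$gene %in% ds@proteome$gene))
  expect_true(all(tr$gene %in% ds@expression$gene))
  expect_true(all(unique(ds@somatic$gene) %in% tr$gene))
})

test_that("robustness diagnostics report rank correlations with degenerate handling", {
  ds <- generateNullDataset(80, gammaTrue = 5, seed = 8)
  res <- data.frame(gene = truthTable(ds)$gene,
                    p = runif(nrow(truthTable(ds))))
  rep <- robustnessReport(ds, res)
  expect_equal(rep$variable, c("protein_length", "mutation_burden"))
  expect_true(all(abs(rep$rho) <= 1))
  expect_true(all(rep$ci_lo <= rep$rho & rep$rho <= rep$ci_hi))
  # constant lengths are reported as not applicable
  ds@truth$L <- 500L
  rep2 <- robustnessReport(ds, res)
  expect_true(is.na(rep2$rho[rep2$variable == "protein_length"]))
})
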