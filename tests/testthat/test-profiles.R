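make_inputs <- function() {
  somatic <- data.frame(
    gene = c("TP53", "TP53", "TP53", "KRAS", "KRAS", "KRAS", "ACVR1"),
    sample = c("S1", "S2", "S3", "S1", "S2", "S3", "S4"),
    study = "UCEC",
    position = c(175L, 175L, 273L, 12L, 12L, 61L, 206L),
    ref = c("R", "R", "R", "G", "G", "Q", "R"),
    alt = c("H", "H", "C", "D", "V", "H", "H"),
    variant_class = "missense", stringsAsFactors = FALSE)
  disease <- data.frame(
    gene = c("TP53", "KRAS", "ACVR1"),
    position = c(175L, 12L, 206L),
    ref = c("R", "G", "R"),
    alt = c("H", "D", "H"), stringsAsFactors = FALSE)
  proteome <- data.frame(gene = c("TP53", "KRAS", "ACVR1"),
                         length = c(393L, 189L, 509L))
  list(somatic = somatic, disease = disease, proteome = proteome)
}

test_that("profiles tally cases, classify matches, and compute the score", {
  x <- make_inputs()
  prof <- buildProfiles(x$somatic, x$disease, x$proteome,
                        criterion = "exact_change")
  expect_length(prof, 3L)

  tp53 <- prof[["TP53|UCEC"]]
  # R175H x2 matches exactly; R273C has no disease record
  expect_equal(nMutatedPositions(tp53), 2L)
  expect_equal(nMatchedPositions(tp53), 1L)
  expect_equal(totalCases(tp53), 3L)
  expect_equal(matchedCases(tp53), 2L)
  expect_equal(matchScore(tp53), 2 / 3)
  expect_equal(mutationBurden(tp53), 2 / 393)

  # all cases matched and none matched
  acvr1 <- prof[["ACVR1|UCEC"]]
  expect_equal(matchScore(acvr1), 1)
  none <- buildProfiles(x$somatic, x$disease[0, ], x$proteome)
  expect_equal(matchScore(none[["TP53|UCEC"]]), 0)
})

test_that("match criteria are nested: exact within similar within position-only", {
  x <- make_inputs()
  # KRAS position 12 carries somatic D and V; disease catalogues D only.
  exact <- buildProfiles(x$somatic, x$disease, x$proteome, "exact_change")
  posonly <- buildProfiles(x$somatic, x$disease, x$proteome, "position_only")
  simil <- buildProfiles(x$somatic, x$disease, x$proteome, "similar_change")
  for (k in names(exact)) {
    e <- exact[[k]]@matchedPositions
    s <- simil[[k]]@matchedPositions
    p <- posonly[[k]]@matchedPositions
    expect_true(all(e %in% s))
    expect_true(all(s %in% p))
  }
  # both alts at KRAS 12 share the position, so position_only matches all 2
  # cases there either way
  expect_equal(matchedCases(posonly[["KRAS|UCEC"]]), 2L)
})

test_that("similar_change follows the substitution-similarity table", {
  # somatic D10E vs disease D10Q: BLOSUM62(E, Q) = 2 > 0, so similar matches
  somatic <- data.frame(gene = "GENE1", sample = "S1", study = "T",
                        position = 10L, ref = "D", alt = "E",
                        variant_class = "missense", stringsAsFactors = FALSE)
  disease <- data.frame(gene = "GENE1", position = 10L, ref = "D", alt = "Q",
                        stringsAsFactors = FALSE)
  proteome <- data.frame(gene = "GENE1", length = 100L)
  expect_equal(nMatchedPositions(
    buildProfiles(somatic, disease, proteome, "similar_change")[[1]]), 1L)
  expect_equal(nMatchedPositions(
    buildProfiles(somatic, disease, proteome, "exact_change")[[1]]), 0L)
  # a dissimilar pair (W vs G scores < 0) matches by position only
  somatic$alt <- "W"; disease$alt <- "G"; somatic$ref <- disease$ref <- "A"
  expect_equal(nMatchedPositions(
    buildProfiles(somatic, disease, proteome, "similar_change")[[1]]), 0L)
  expect_equal(nMatchedPositions(
    buildProfiles(somatic, disease, proteome, "position_only")[[1]]), 1L)
})

test_that("genes without a protein length are skipped with a warning", {
  x <- make_inputs()
  prot <- x$proteome[x$proteome$gene != "KRAS", ]
  expect_warning(prof <- buildProfiles(x$somatic, x$disease, prot,
                                       verbose = TRUE), "KRAS")
  expect_false("KRAS|UCEC" %in% names(prof))
  expect_equal(attr(prof, "skippedGenes"), "KRAS")
})

test_that("adding cases moves the score in the right direction", {
  # monotonicity: a case at a matched position never lowers S; at an
  # unmatched position never raises it
  set.seed(42)
  for (i in 1:20) {
    p <- random_profile()
    n <- nMutatedPositions(p)
    matched <- sample(as.integer(names(p@caseCounts)), sample.int(n, 1))
    p@matchedPositions <- matched
    s0 <- matchScore(p)
    cc <- p@caseCounts
    mpos <- as.character(matched[1])
    cc1 <- cc; cc1[mpos] <- cc1[mpos] + 1L
    p1 <- newProfile(p@gene, p@study, p@L, cc1, matched)
    expect_gte(matchScore(p1), s0)
    unmatched <- setdiff(names(cc), as.character(matched))
    if (length(unmatched)) {
      cc2 <- cc; cc2[unmatched[1]] <- cc2[unmatched[1]] + 1L
      p2 <- newProfile(p@gene, p@study, p@L, cc2, matched)
      expect_lte(matchScore(p2), s0)
    }
  }
})

test_that("profile validity catches inconsistent construction", {
  expect_error(newProfile("G", "T", 5, c("10" = 2)), "protein length")
  expect_error(newProfile("G", "T", 100, c("10" = 2), matchedPositions = 11),
               "subset")
  expect_error(newProfile("G", "T", 100, c("10" = 0)), "at least one case")
  expect_error(mutationBurden(
    new("GeneStudyProfile", gene = "G", study = "T", L = 1L,
        caseCounts = c("1" = 1L, "2" = 1L)[1],  # valid single-position
        somaticAlts = list(character(0)), diseaseAlts = list(character(0)),
        matchedPositions = integer(0), criterion = "exact_change")), NA)
})

test_that("profile table export carries the score arithmetic", {
  x <- make_inputs()
  tab <- profileTable(buildProfiles(x$somatic, x$disease, x$proteome))
  expect_equal(tab$S, tab$matched_cases / tab$total_cases)
  expect_true(all(tab$m <= tab$n))
  expect_true(all(tab$matched_cases <= tab$total_cases))
})
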