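# Fixtures are built in code at test time; nothing is stored on disk.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## A small MAF-style somatic file covering the parse cases.
fixture_maf <- function(path = tempfile(fileext = ".tsv")) {
  write_tsv(data.frame(
    Hugo_Symbol = c("TP53", "TP53", "TP53", "KRAS", "KRAS", "BRAF", "EGFR"),
    Tumor_Sample_Barcode = c("S1", "S2", "S1", "S1", "S2", "S3", "S4"),
    Variant_Classification = c("Missense_Mutation", "Missense_Mutation",
                               "Missense_Mutation", "Missense_Mutation",
                               "Missense_Mutation", "Missense_Mutation",
                               "Frame_Shift_Del"),
    Protein_Change = c("p.R175H", "p.R175H", "p.R273C", "p.G12D", "p.G12V",
                       "p.M1?", "p.E746_A750del"),
    stringsAsFactors = FALSE
  ), path)
}

## HUMSAVAR flat-file dialect with the three category labels and a
## splice-affecting silent record.
fixture_humsavar <- function(path = tempfile(fileext = ".txt")) {
  writeLines(c(
    "Gene name  AC          FTId        Change          Category      dbSNP      Disease",
    "TP53       P04637      VAR_000001  p.Arg175His     Disease       rs0000001  Li-Fraumeni syndrome",
    "KRAS       P01116      VAR_000002  p.Gly12Asp      Disease       rs0000002  Noonan syndrome",
    "KRAS       P01116      VAR_000003  p.Gly12Gly      Disease       rs0000003  splicing defect disorder",
    "EGFR       P00533      VAR_000004  p.Leu858Leu     Disease       rs0000009  synonymous variant",
    "PTEN       P60484      VAR_000005  p.Ala72Val      Polymorphism  rs0000004  -",
    "BRAF       P15056      VAR_000006  p.Xle600Glu     Disease       rs0000005  bad code row",
    "SOS1       Q07889      VAR_000007  p.Met269Arg     Unclassified  rs0000006  -"
  ), path)
  path
}

fixture_clinvar <- function(path = tempfile(fileext = ".tsv")) {
  write_tsv(data.frame(
    GeneSymbol = c("TP53", "KRAS", "PTEN", "ACVR1", "ACVR1"),
    Name = c("NM_000546.5(TP53):c.524G>A (p.Arg175His)",
             "NM_004985.4(KRAS):c.35G>A (p.Gly12Asp)",
             "NM_000314.6(PTEN):c.215C>T (p.Ala72Val)",
             "NM_001105.4(ACVR1):c.617G>A (p.Arg206His)",
             "NM_001105.4(ACVR1):c.774C>G"),
    ClinicalSignificance = c("Pathogenic", "Likely pathogenic", "Benign",
                             "Pathogenic", "Pathogenic"),
    stringsAsFactors = FALSE
  ), path)
}

fixture_proteome <- function(path = tempfile(fileext = ".tsv")) {
  write_tsv(data.frame(
    gene = c("TP53", "KRAS", "BRAF", "EGFR", "PTEN", "ACVR1", "SOS1"),
    length = c(393L, 189L, 766L, 1210L, 403L, 509L, 1333L)
  ), path)
}

## Wide expression table: two studies, four samples each, one NA cell and one
## gene fully missing in one study.
fixture_expression <- function(path = tempfile(fileext = ".tsv")) {
  df <- data.frame(
    gene = c("TP53", "KRAS", "LOWEXP"),
    `A-S1` = c(10, 0, 0.2), `A-S2` = c(12, 0, 0.1),
    `A-S3` = c(NA, 4, 0.3),
    `B-S1` = c(50, NA, 0.1), `B-S2` = c(60, NA, 0.2),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

fixture_study_map <- function() {
  data.frame(sample = c("A-S1", "A-S2", "A-S3", "B-S1", "B-S2"),
             study = c("A", "A", "A", "B", "B"),
             stringsAsFactors = FALSE)
}

## Random small profile for oracle comparisons.
random_profile <- function(n_max = 8, count_max = 4) {
  n <- sample(2:n_max, 1)
  pos <- sort(sample.int(50, n))
  counts <- sample.int(count_max, n, replace = TRUE)
  newProfile(paste0("G", sample.int(1e4, 1)), "T", 60,
             stats::setNames(counts, pos))
}

## Brute-force oracle for the exact null: enumerate every subset of the
## positions with utils::combn, weight by Binomial(k; n, alpha) / C(n, k).
brute_force_null <- function(counts, alpha) {
  n <- length(counts)
  tot <- sum(counts)
  support <- list()
  for (k in 0:n) {
    sums <- if (k == 0) 0 else
      if (k == n) sum(counts) else
        utils::combn(counts, k, FUN = sum)
    w <- stats::dbinom(k, n, alpha) / choose(n, k)
    for (s in sums) {
      key <- as.character(s)
      support[[key]] <- (if (is.null(support[[key]])) 0 else support[[key]]) + w
    }
  }
  s <- as.numeric(names(support)) / tot
  o <- order(s)
  data.frame(S = s[o], prob = unlist(support)[o], row.names = NULL)
}
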