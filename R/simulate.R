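# Synthetic-data generators: the 1000-gene parameter-range panel used for
# robustness diagnostics, and burden-proportional null / planted-signal
# datasets used for calibration and power studies. Generators emit the same
# table dialects the readers parse, so synthetic data can exercise the full
# I/O path.

.random_aa <- function(n) sample(.aa1, n, replace = TRUE)

.random_alt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(.aa1, r), 1L), "")
}

.case_rows <- function(gene, study, positions, counts, ref, alt) {
  idx <- rep(seq_along(positions), counts)
  data.frame(
    gene = gene,
    sample = sprintf("%s-CASE-%04d", gene, seq_along(idx)),
    study = study,
    position = positions[idx],
    ref = ref[idx],
    alt = alt[idx],
    variant_class = "missense",
    stringsAsFactors = FALSE
  )
}

#' Generate the parameter-range simulation panel
#'
#' Draws \code{nGenes} simulated genes over the study's parameter ranges:
#' protein length 10-8000 (log-uniform), number of exact positional matches
#' 1-100, target match score 0.01-0.99, background burden from one unmatched
#' unique position to the maximum the length allows, and a case-count scale
#' factor 1-50. For each gene the unit configuration — the smallest number of
#' cases satisfying the target score given one case per mutated position —
#' is constructed first and then multiplied by the scale factor, so the
#' achieved score equals the target within unit-count rounding. Infeasible
#' draws (more matches than length minus one) are resampled and counted.
#'
#' Synthetic disease variants copy the somatic alternate residue, so all
#' three match criteria coincide on generated data.
#'
#' @param nGenes number of genes (default 1000).
#' @param ranges list overriding any of \code{length} (lo, hi),
#'   \code{matches}, \code{score}, \code{scale}.
#' @param seed integer seed; a fixed seed reproduces the dataset exactly.
#' @param study study label for the somatic table.
#' @return a \code{\linkS4class{SyntheticDataset}}; the truth table records
#'   the drawn parameters and the achieved score.
#' @export
generateSimulationPanel <- function(nGenes = 1000,
                                    ranges = list(), seed = 1,
                                    study = "SIMPANEL") {
  rg <- utils::modifyList(list(length = c(10, 8000), matches = c(1, 100),
                               score = c(0.01, 0.99), scale = c(1, 50)),
                          ranges)
  set.seed(seed)
  somatic <- vector("list", nGenes)
  disease <- vector("list", nGenes)
  truth <- vector("list", nGenes)
  proteome <- vector("list", nGenes)
  resampled <- 0L

  for (g in seq_len(nGenes)) {
    repeat {
      L <- round(10^stats::runif(1, log10(rg$length[1]), log10(rg$length[2])))
      M <- sample(rg$matches[1]:rg$matches[2], 1L)
      if (M <= L - 1L) break
      resampled <- resampled + 1L
    }
    Starget <- stats::runif(1, rg$score[1], rg$score[2])
    U <- sample.int(L - M, 1L)             # unmatched unique positions
    f <- sample(rg$scale[1]:rg$scale[2], 1L)

    ## unit configuration: one case per position, then the fewest extra cases
    ## at matched (or unmatched) positions to reach the target score
    mc <- M; uc <- U
    if (mc / (mc + uc) < Starget) {
      mc <- mc + max(0, ceiling((Starget * (M + U) - M) / (1 - Starget)))
    } else {
      uc <- uc + max(0, ceiling(M / Starget - M - U))
    }
    achieved <- mc / (mc + uc)

    gene <- sprintf("SIMG%04d", g)
    positions <- sample.int(L, M + U)
    counts <- rep(1L, M + U)
    ## spread the extra unit cases round-robin, then scale
    extraM <- mc - M
    if (extraM > 0)
      counts[seq_len(M)] <- counts[seq_len(M)] +
        tabulate((seq_len(extraM) - 1L) %% M + 1L, nbins = M)
    extraU <- uc - U
    if (extraU > 0)
      counts[M + seq_len(U)] <- counts[M + seq_len(U)] +
        tabulate((seq_len(extraU) - 1L) %% U + 1L, nbins = U)
    counts <- counts * f
    ref <- .random_aa(M + U)
    alt <- .random_alt(ref)

    somatic[[g]] <- .case_rows(gene, study, positions, counts, ref, alt)
    disease[[g]] <- data.frame(
      gene = gene, position = positions[seq_len(M)],
      ref = ref[seq_len(M)], alt = alt[seq_len(M)],
      disease_label = "simulated disease", category = "disease-pathogenic",
      source_dialect = "humsavar", splice_affecting = FALSE,
      stringsAsFactors = FALSE
    )
    proteome[[g]] <- data.frame(gene = gene, length = L,
                                stringsAsFactors = FALSE)
    truth[[g]] <- data.frame(
      gene = gene, status = "planted", L = L, matches = M,
      target_score = Starget, achieved_score = achieved,
      unit_cases = mc + uc, unmatched_positions = U, scale = f,
      burden = (M + U) / L, alpha_true = M / (M + U),
      stringsAsFactors = FALSE
    )
  }

  truth <- if (nGenes) do.call(rbind, truth) else data.frame(gene = character(0))
  expression <- if (nGenes)
    data.frame(gene = truth$gene, study = study, value = 100,
               expressed = TRUE, stringsAsFactors = FALSE)
  else data.frame(gene = character(0), study = character(0),
                  value = numeric(0), expressed = logical(0))
  new("SyntheticDataset",
      somatic = if (nGenes) do.call(rbind, somatic) else
        .empty_somatic(),
      disease = if (nGenes) do.call(rbind, disease) else .empty_disease(),
      proteome = if (nGenes) do.call(rbind, proteome) else
        data.frame(gene = character(0), length = integer(0)),
      expression = if (nGenes) expression else
        data.frame(gene = character(0), study = character(0),
                   value = numeric(0), expressed = logical(0)),
      truth = if (nGenes) truth else data.frame(gene = character(0)),
      params = list(nGenes = nGenes, ranges = rg, seed = seed, study = study,
                    resampled = resampled))
}

.empty_somatic <- function() data.frame(
  gene = character(0), sample = character(0), study = character(0),
  position = integer(0), ref = character(0), alt = character(0),
  variant_class = character(0))

.empty_disease <- function() data.frame(
  gene = character(0), position = integer(0), ref = character(0),
  alt = character(0), disease_label = character(0), category = character(0),
  source_dialect = character(0), splice_affecting = logical(0))

#' Generate a burden-proportional null (or planted-signal) dataset
#'
#' Every gene's disease positions are planted independently with per-position
#' probability \code{clamp(gamma_true * n/L, 0, 1)} — exactly the background
#' model's generative law, with no enrichment beyond background. Protein
#' lengths are log-uniform on 200-5000, per-gene burden is uniform on
#' \code{muRange} (default 0.01-0.08, so at gamma = 10 the background rate
#' spans 0.1-0.8 without clamping), per-position case counts are
#' 1 + Poisson(1), and the expressed flag is Bernoulli(0.5) independent of
#' gene architecture (expressed values log-uniform 1-1000, nonexpressed
#' uniform 0-0.5, so cutoffs 1/5/10 select slightly different sets).
#'
#' Optionally plants \code{nEnriched} low-burden signal genes whose true
#' per-position match probability is \code{min(0.95, fold * gamma_true * mu)}
#' with per-position counts 2 + Poisson(1) (at least five reported cases), and
#' one "RYR2 analog": a very long, heavily mutated null gene (L = 5000,
#' n = 600, burden 0.12) whose background rate saturates at 1 under
#' gamma = 10 — the model's own account of why extreme-burden genes match
#' everywhere by chance.
#'
#' @param nGenes number of null genes.
#' @param gammaTrue true proportionality coefficient.
#' @param seed integer seed.
#' @param nEnriched number of planted enriched genes (default 0).
#' @param enrichFold enrichment of the planted genes over background
#'   (default 10).
#' @param ryr2Analog add the saturated long-gene analog (default FALSE).
#' @param muRange burden range for null genes.
#' @param study study label.
#' @return a \code{\linkS4class{SyntheticDataset}}; truth status is one of
#'   "null", "enriched", "ryr2_analog".
#' @export
generateNullDataset <- function(nGenes, gammaTrue, seed = 1, nEnriched = 0,
                                enrichFold = 10, ryr2Analog = FALSE,
                                muRange = c(0.01, 0.08), study = "SIMNULL") {
  stopifnot(gammaTrue >= 0)
  set.seed(seed)
  total <- nGenes + nEnriched + as.integer(ryr2Analog)
  somatic <- vector("list", total)
  disease <- vector("list", total)
  truth <- vector("list", total)
  proteome <- vector("list", total)

  make_gene <- function(g, status) {
    if (status == "ryr2_analog") {
      L <- 5000L; n <- 600L
      alphaTrue <- .clamp01(gammaTrue * n / L)
      counts <- 1L + stats::rpois(n, 1)
      expressed <- TRUE
    } else if (status == "enriched") {
      L <- round(10^stats::runif(1, log10(1000), log10(5000)))
      mu <- stats::runif(1, 0.004, 0.008)
      n <- max(2L, round(mu * L))
      alphaTrue <- min(0.95, enrichFold * gammaTrue * n / L)
      counts <- 2L + stats::rpois(n, 1)
      expressed <- TRUE
    } else {
      L <- round(10^stats::runif(1, log10(200), log10(5000)))
      mu <- stats::runif(1, muRange[1], muRange[2])
      n <- max(2L, round(mu * L))
      alphaTrue <- .clamp01(gammaTrue * n / L)
      counts <- 1L + stats::rpois(n, 1)
      expressed <- stats::runif(1) < 0.5
    }
    gene <- sprintf("%s%04d", switch(status, null = "NULLG",
                                     enriched = "ENRG",
                                     ryr2_analog = "RYR2LIKE"), g)
    positions <- sample.int(L, n)
    ref <- .random_aa(n)
    alt <- .random_alt(ref)
    matched <- stats::runif(n) < alphaTrue
    somatic[[g]] <<- .case_rows(gene, study, positions, counts, ref, alt)
    disease[[g]] <<- if (any(matched)) data.frame(
      gene = gene, position = positions[matched], ref = ref[matched],
      alt = alt[matched], disease_label = "simulated disease",
      category = "disease-pathogenic", source_dialect = "humsavar",
      splice_affecting = FALSE, stringsAsFactors = FALSE
    ) else .empty_disease()
    proteome[[g]] <<- data.frame(gene = gene, length = L,
                                 stringsAsFactors = FALSE)
    truth[[g]] <<- data.frame(
      gene = gene, status = status, L = L, n = n, burden = n / L,
      alpha_true = alphaTrue, m_true = sum(matched),
      total_cases = sum(counts), expressed_true = expressed,
      stringsAsFactors = FALSE
    )
    expressed
  }

  expressed <- logical(total)
  g <- 0L
  for (i in seq_len(nEnriched)) { g <- g + 1L; expressed[g] <- make_gene(g, "enriched") }
  if (ryr2Analog) { g <- g + 1L; expressed[g] <- make_gene(g, "ryr2_analog") }
  for (i in seq_len(nGenes)) { g <- g + 1L; expressed[g] <- make_gene(g, "null") }

  truth <- if (total) do.call(rbind, truth) else
    data.frame(gene = character(0), status = character(0))
  value <- numeric(total)
  value[expressed] <- 10^stats::runif(sum(expressed), 0, 3)
  value[!expressed] <- stats::runif(sum(!expressed), 0, 0.5)
  expression <- if (total) data.frame(gene = truth$gene, study = study,
                                      value = value, expressed = expressed,
                                      stringsAsFactors = FALSE)
  else data.frame(gene = character(0), study = character(0),
                  value = numeric(0), expressed = logical(0))

  new("SyntheticDataset",
      somatic = if (total) do.call(rbind, somatic) else .empty_somatic(),
      disease = if (total) do.call(rbind, disease) else .empty_disease(),
      proteome = if (total) do.call(rbind, proteome) else
        data.frame(gene = character(0), length = integer(0)),
      expression = expression, truth = truth,
      params = list(nGenes = nGenes, gammaTrue = gammaTrue, seed = seed,
                    nEnriched = nEnriched, enrichFold = enrichFold,
                    ryr2Analog = ryr2Analog, muRange = muRange,
                    study = study))
}

#' Rank-correlation diagnostics of nominal p-values vs gene architecture
#'
#' Reports the Spearman correlation of nominal p-values with protein length
#' and with mutation burden, each with an approximate 95% confidence interval
#' (Fisher z with variance 1.06/(n-3)). A well-calibrated burden-scaled null
#' should show essentially no correlation with length and at most a minimal
#' negative correlation with burden.
#'
#' @param dataset the \code{\linkS4class{SyntheticDataset}} analyzed.
#' @param results results data.frame with columns gene, p.
#' @return data.frame with one row per diagnostic (variable, rho, ci_lo,
#'   ci_hi, n); a variable with no variation is reported as NA
#'   (not applicable).
#' @export
robustnessReport <- function(dataset, results) {
  truth <- truthTable(dataset)
  idx <- match(results$gene, truth$gene)
  if (anyNA(idx)) stop("results contain genes absent from the truth table")
  L <- truth$L[idx]
  burden <- truth$n[idx] / truth$L[idx]
  one <- function(name, x) {
    if (length(unique(x)) < 2L)
      return(data.frame(variable = name, rho = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, n = length(x)))
    rho <- stats::cor(results$p, x, method = "spearman")
    n <- length(x)
    z <- atanh(rho); se <- sqrt(1.06 / (n - 3))
    data.frame(variable = name, rho = rho, ci_lo = tanh(z - 1.96 * se),
               ci_hi = tanh(z + 1.96 * se), n = n)
  }
  rbind(one("protein_length", L), one("mutation_burden", burden))
}

#' Write a synthetic dataset in the dialects the readers parse
#'
#' Writes somatic.maf.tsv (MAF-style), disease.humsavar.txt (HUMSAVAR flat
#' dialect), proteome.tsv, expression.tsv (wide RSEM-like, four samples per
#' study) + expression_samples.tsv (sample-to-study map), and truth.tsv.
#'
#' @param dataset a \code{\linkS4class{SyntheticDataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(somatic = file.path(dir, "somatic.maf.tsv"),
             disease = file.path(dir, "disease.humsavar.txt"),
             proteome = file.path(dir, "proteome.tsv"),
             expression = file.path(dir, "expression.tsv"),
             studyMap = file.path(dir, "expression_samples.tsv"),
             truth = file.path(dir, "truth.tsv"))

  som <- dataset@somatic
  maf <- data.frame(Hugo_Symbol = som$gene,
                    Tumor_Sample_Barcode = som$sample,
                    Variant_Classification =
                      c(missense = "Missense_Mutation", silent = "Silent",
                        nonsense = "Nonsense_Mutation", splice = "Splice_Site",
                        other = "Other")[som$variant_class],
                    Protein_Change = sprintf("p.%s%d%s", som$ref,
                                             som$position, som$alt),
                    stringsAsFactors = FALSE)
  utils::write.table(maf, paths["somatic"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  dis <- dataset@disease
  aa3 <- stats::setNames(as.character(Biostrings::AMINO_ACID_CODE),
                         names(Biostrings::AMINO_ACID_CODE))
  lines <- c(
    "Gene      AC          FTId        Change          Category      dbSNP    Disease",
    if (nrow(dis)) sprintf("%-9s P%05d      VAR_%06d  p.%s%d%s  %s  -  %s",
                           dis$gene, seq_len(nrow(dis)), seq_len(nrow(dis)),
                           aa3[dis$ref], dis$position, aa3[dis$alt],
                           c("disease-pathogenic" = "Disease",
                             "polymorphism" = "Polymorphism",
                             "unclassified" = "Unclassified")[dis$category],
                           ifelse(nchar(dis$disease_label) > 0,
                                  dis$disease_label, "-")))
  writeLines(lines, paths["disease"])

  utils::write.table(dataset@proteome, paths["proteome"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## wide RSEM-like table: four samples per study around each gene's value
  expr <- dataset@expression
  studies <- unique(expr$study)
  samples <- unlist(lapply(studies, function(st) paste0(st, "-S", 1:4)))
  wide <- data.frame(gene = unique(expr$gene), stringsAsFactors = FALSE)
  for (st in studies) {
    sub <- expr[expr$study == st, , drop = FALSE]
    v <- sub$value[match(wide$gene, sub$gene)]
    for (j in 1:4) wide[[paste0(st, "-S", j)]] <- v
  }
  utils::write.table(wide, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = samples,
                                study = rep(studies, each = 4)),
                     paths["studyMap"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset@truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
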