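# End-to-end pipeline: profiles -> background model -> bootstrap SNR ->
# permutation p -> BH -> expression-stratified cutoff -> hits.

#' Run the full overlap analysis
#'
#' Takes harmonized somatic and pathogenic disease tables (see
#' \code{\link{readSomaticMaf}}, \code{\link{readDiseaseVariants}},
#' \code{\link{filterPathogenic}}, \code{\link{reconcileReferenceResidues}}),
#' builds per-gene-per-study profiles, estimates the burden-proportional
#' background per study (unless a fixed gamma is supplied), computes the
#' bootstrap signal-to-noise ratio and the permutation p-value for every
#' profile, adjusts p-values (pooled across all pairs by default), derives the
#' expression-stratified adjusted-p cutoff (unless given explicitly), and
#' applies the final hit filter.
#'
#' Randomness is fully reproducible: every profile draws from a substream
#' seeded deterministically from (seed, gene, study), so results do not depend
#' on iteration order.
#'
#' @param somatic harmonized somatic table.
#' @param disease harmonized, pathogenic-only disease table.
#' @param proteome data.frame(gene, length).
#' @param expression optional data.frame(gene, study, value, expressed); when
#'   NULL all pairs count as expressed and \code{explicitCutoff} is required.
#' @param criterion match criterion (default \code{"exact_change"}).
#' @param exprCutoff expression cutoff applied to \code{expression$value}
#'   (default 1).
#' @param explicitCutoff adjusted-p cutoff; NULL (default) derives it from the
#'   nonexpressed stratum via \code{\link{expressionCutoff}}.
#' @param bootReps bootstrap replicates (default 1000).
#' @param permMin,permMax minimum / maximum permutation draws (defaults 1e4 /
#'   1e6).
#' @param minExceed adaptive early-stopping exceedance target (default 50).
#' @param snrForm \code{"s_over_var"} (default) or \code{"s_over_sd"}.
#' @param snrMin SNR threshold for hits (default 2).
#' @param minCases minimum reported cases for hits (default 2).
#' @param casesOn count \code{"total"} (default) or \code{"matched"} cases.
#' @param gamma optional fixed proportionality coefficient (skips estimation).
#' @param gammaGenes estimate gamma from \code{"all"} (default) or
#'   \code{"expressed"} genes.
#' @param quantileType quantile rule for the cutoff quartile (default 7).
#' @param bhScope \code{"pooled"} (default) or \code{"per_study"} adjustment.
#' @param seed integer seed (default 1).
#' @param outDir optional directory; when given, results/hits/eCDF TSVs and a
#'   run manifest are written there.
#' @param verbose print stage progress.
#' @return an \code{\linkS4class{OverlapResults}}.
#' @export
runOverlap <- function(somatic, disease, proteome, expression = NULL,
                       criterion = c("exact_change", "position_only",
                                     "similar_change"),
                       exprCutoff = 1, explicitCutoff = NULL,
                       bootReps = 1000, permMin = 1e4, permMax = 1e6,
                       minExceed = 50,
                       snrForm = c("s_over_var", "s_over_sd"),
                       snrMin = 2, minCases = 2,
                       casesOn = c("total", "matched"),
                       gamma = NULL, gammaGenes = c("all", "expressed"),
                       quantileType = 7,
                       bhScope = c("pooled", "per_study"),
                       seed = 1, outDir = NULL, verbose = FALSE) {
  criterion <- match.arg(criterion)
  snrForm <- match.arg(snrForm)
  casesOn <- match.arg(casesOn)
  gammaGenes <- match.arg(gammaGenes)
  bhScope <- match.arg(bhScope)

  .msg(verbose, "building profiles (criterion = ", criterion, ")")
  profiles <- buildProfiles(somatic, disease, proteome, criterion = criterion)
  if (!length(profiles)) stop("no profiles could be built")

  .msg(verbose, "estimating background model")
  models <- estimateGamma(profiles, expression = expression,
                          exprCutoff = exprCutoff, genes = gammaGenes,
                          gamma = gamma)

  .msg(verbose, "scoring ", length(profiles), " gene-study pairs")
  rows <- lapply(profiles, function(p) {
    model <- models[[p@study]]
    gt <- model@geneTable
    arow <- gt[gt$gene == p@gene, ]
    s <- matchScore(p)
    set.seed(.substream_seed(seed, p@gene, p@study))
    boot <- bootstrapScores(p, nReps = bootReps)
    sn <- snr(s, boot, form = snrForm)
    null <- sampleNullDistribution(p, arow$alpha_bg, nMin = permMin,
                                   nMax = permMax, observedS = s,
                                   minExceed = minExceed, keepDraws = FALSE)
    data.frame(
      gene = p@gene, study = p@study, L = p@L,
      n = nMutatedPositions(p), m = nMatchedPositions(p),
      total_cases = totalCases(p), matched_cases = matchedCases(p),
      S = s, mu_hat = arow$mu_hat, alpha_obs = arow$alpha_obs,
      alpha_bg = arow$alpha_bg,
      score_sd = sn$score_sd, snr = sn$snr, degenerate = sn$degenerate,
      n_draws = null@nDraws, exceedances = null@exceedances,
      p = permutationPvalue(null = null),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  if (bhScope == "pooled") {
    res$p_adj <- bhAdjust(res$p)
  } else {
    res$p_adj <- NA_real_
    for (st in unique(res$study))
      res$p_adj[res$study == st] <- bhAdjust(res$p[res$study == st])
  }

  if (is.null(expression)) {
    res$expressed <- TRUE
    if (is.null(explicitCutoff))
      stop("without an expression table an explicit cutoff is required")
  } else {
    key <- paste(res$gene, res$study)
    ekey <- paste(expression$gene, expression$study)
    val <- expression$value[match(key, ekey)]
    res$expressed <- !is.na(val) & val >= exprCutoff
  }

  cutoff <- if (is.null(explicitCutoff))
    expressionCutoff(res, quantileType = quantileType) else explicitCutoff
  res <- filterHits(res, cutoff, snrMin = snrMin, minCases = minCases,
                    casesOn = casesOn)

  out <- new("OverlapResults", results = res, cutoff = cutoff,
             criterion = criterion,
             params = list(exprCutoff = exprCutoff, bootReps = bootReps,
                           permMin = permMin, permMax = permMax,
                           minExceed = minExceed, snrForm = snrForm,
                           snrMin = snrMin, minCases = minCases,
                           casesOn = casesOn, bhScope = bhScope, seed = seed,
                           gamma = vapply(models, gammaHat, 0)))
  if (!is.null(outDir)) .write_run(out, res, outDir)
  out
}

.write_run <- function(out, res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res, file.path(outDir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res[res$is_hit, , drop = FALSE],
                     file.path(outDir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rep <- tryCatch(ecdfReport(res), warning = function(w) NULL)
  if (!is.null(rep))
    utils::write.table(rep$table, file.path(outDir, "ecdf.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  manifest <- c(
    paste0("package_version: ",
           as.character(utils::packageVersion("VariantOverlay"))),
    paste0("criterion: ", out@criterion),
    paste0("cutoff: ", format(out@cutoff, digits = 10)),
    paste0("n_results: ", nrow(res)),
    paste0("n_hits: ", sum(res$is_hit)),
    vapply(names(out@params), function(k)
      paste0(k, ": ", paste(format(out@params[[k]], digits = 10),
                            collapse = ",")), "")
  )
  writeLines(manifest, file.path(outDir, "run_manifest.txt"))
  invisible(NULL)
}

#' Run the overlap pipeline directly on a synthetic dataset
#'
#' Convenience wrapper used throughout the calibration and power studies:
#' unpacks a \code{\linkS4class{SyntheticDataset}} and calls
#' \code{\link{runOverlap}}.
#'
#' @param dataset a \code{\linkS4class{SyntheticDataset}}.
#' @param ... passed to \code{\link{runOverlap}}.
#' @return an \code{\linkS4class{OverlapResults}}.
#' @export
runOverlapOnDataset <- function(dataset, ...) {
  runOverlap(dataset@somatic, filterPathogenic(dataset@disease),
             dataset@proteome, dataset@expression, ...)
}
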