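#' @include AllGenerics.R
NULL

#' GeneStudyProfile: per-gene, per-study mutation profile
#'
#' Holds everything the overlap statistic needs for one gene in one tumor
#' study: the per-position somatic case counts, the somatic and disease
#' alternate residues seen at each position, the canonical protein length, and
#' the set of positions matched under the active criterion.
#'
#' @slot gene gene symbol.
#' @slot study tumor-type / study label.
#' @slot L canonical protein length in residues.
#' @slot caseCounts named integer vector; names are 1-based residue positions,
#'   values are numbers of reported somatic cases at that position.
#' @slot somaticAlts list parallel to \code{caseCounts}: alternate residues
#'   observed somatically at each position.
#' @slot diseaseAlts list parallel to \code{caseCounts}: pathogenic alternate
#'   residues catalogued at each position (empty where none).
#' @slot matchedPositions integer vector, subset of the mutated positions.
#' @slot criterion one of \code{"position_only"}, \code{"exact_change"},
#'   \code{"similar_change"}.
#'
#' @aliases GeneStudyProfile
#' @exportClass GeneStudyProfile
setClass("GeneStudyProfile",
  representation(
    gene = "character",
    study = "character",
    L = "integer",
    caseCounts = "integer",
    somaticAlts = "list",
    diseaseAlts = "list",
    matchedPositions = "integer",
    criterion = "character"
  )
)

setValidity("GeneStudyProfile", function(object) {
  msg <- character(0)
  pos <- suppressWarnings(as.integer(names(object@caseCounts)))
  if (length(object@caseCounts) < 1L)
    msg <- c(msg, "profile must have at least one mutated position")
  if (anyNA(pos) || any(pos < 1L))
    msg <- c(msg, "caseCounts names must be positions >= 1")
  if (length(object@L) != 1L || is.na(object@L) || object@L < 1L)
    msg <- c(msg, "L must be a single positive integer")
  if (any(pos > object@L))
    msg <- c(msg, "mutated position exceeds protein length")
  if (any(object@caseCounts < 1L))
    msg <- c(msg, "every mutated position must carry at least one case")
  if (!all(object@matchedPositions %in% pos))
    msg <- c(msg, "matchedPositions must be a subset of mutated positions")
  if (anyDuplicated(pos))
    msg <- c(msg, "duplicate positions in caseCounts")
  if (!object@criterion %in% c("position_only", "exact_change", "similar_change"))
    msg <- c(msg, "unknown match criterion")
  if (length(msg)) msg else TRUE
})

#' BackgroundModel: burden-proportional background match rates for one study
#'
#' Stores the tumor-type-specific proportionality coefficient
#' \eqn{\hat\gamma_t} and, per gene, the burden \eqn{\hat\mu = n/L}, the
#' observed match rate \eqn{\hat\alpha = m/n}, and the background rate
#' \eqn{\alpha_{bg} = \mathrm{clamp}(\hat\gamma\,\hat\mu, \epsilon, 1)}.
#'
#' @slot study study label.
#' @slot gammaHat estimated proportionality coefficient (nonnegative).
#' @slot geneTable data.frame with columns gene, n, L, mu_hat, alpha_obs,
#'   alpha_bg, clamped, floored.
#' @slot epsilon lower floor applied to alpha_bg.
#'
#' @aliases BackgroundModel
#' @exportClass BackgroundModel
setClass("BackgroundModel",
  representation(
    study = "character",
    gammaHat = "numeric",
    geneTable = "data.frame",
    epsilon = "numeric"
  )
)

setValidity("BackgroundModel", function(object) {
  tab <- object@geneTable
  need <- c("gene", "n", "L", "mu_hat", "alpha_obs", "alpha_bg")
  if (!all(need %in% names(tab)))
    return(paste("geneTable must have columns:", paste(need, collapse = ", ")))
  if (length(object@gammaHat) != 1L || is.na(object@gammaHat) ||
      object@gammaHat < 0)
    return("gammaHat must be a single nonnegative number")
  if (nrow(tab)) {
    if (any(tab$alpha_obs < 0 | tab$alpha_obs > 1))
      return("alpha_obs outside [0,1]")
    if (any(tab$alpha_bg < 0 | tab$alpha_bg > 1))
      return("alpha_bg outside [0,1]")
    if (any(tab$mu_hat <= 0 | tab$mu_hat > 1))
      return("mu_hat outside (0,1]")
  }
  TRUE
})

#' NullDistribution: sampled empirical null of the match score
#'
#' @slot gene,study identifiers.
#' @slot alphaBg background match rate used for the binomial match counts.
#' @slot nDraws number of permutation draws performed.
#' @slot exceedances number of draws with null score >= the observed score.
#' @slot observedS the observed match score the exceedances refer to.
#' @slot draws the sampled null scores (may be empty when only the summary was
#'   retained, e.g. inside the pipeline).
#'
#' @aliases NullDistribution
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(
    gene = "character",
    study = "character",
    alphaBg = "numeric",
    nDraws = "integer",
    exceedances = "integer",
    observedS = "numeric",
    draws = "numeric"
  )
)

setValidity("NullDistribution", function(object) {
  if (object@nDraws < 1L) return("nDraws must be >= 1")
  if (object@exceedances < 0L || object@exceedances > object@nDraws)
    return("exceedances must lie in [0, nDraws]")
  if (length(object@draws) &&
      (min(object@draws) < -1e-12 || max(object@draws) > 1 + 1e-12))
    return("null draws must lie in [0,1]")
  TRUE
})

#' OverlapResults: one row per gene-study pair with all overlap statistics
#'
#' @slot results data.frame with columns gene, study, L, n, m, total_cases,
#'   matched_cases, S, mu_hat, alpha_obs, alpha_bg, score_sd, snr, degenerate,
#'   n_draws, exceedances, p, p_adj, expressed, is_hit.
#' @slot cutoff adjusted-p cutoff used for hit calling (NA when hits were not
#'   called).
#' @slot criterion match criterion the profiles were built under.
#' @slot params list of run parameters (bootstrap reps, permutation bounds,
#'   SNR form and threshold, minimum cases, BH scope, seed, gamma per study).
#'
#' @aliases OverlapResults
#' @exportClass OverlapResults
setClass("OverlapResults",
  representation(
    results = "data.frame",
    cutoff = "numeric",
    criterion = "character",
    params = "list"
  )
)

#' SyntheticDataset: generated somatic/disease/proteome/expression bundle
#'
#' The generator writes the same table dialects the readers parse, so synthetic
#' data can exercise the full I/O path. The truth table records, per gene, the
#' planted status (null / enriched / ryr2_analog) and the true per-position
#' match probability.
#'
#' @slot somatic harmonized somatic variant table (one row per reported case).
#' @slot disease harmonized pathogenic disease variant table.
#' @slot proteome data.frame(gene, length).
#' @slot expression data.frame(gene, study, value, expressed).
#' @slot truth data.frame keyed by gene with the planted ground truth.
#' @slot params generator parameters, including the seed.
#'
#' @aliases SyntheticDataset
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(
    somatic = "data.frame",
    disease = "data.frame",
    proteome = "data.frame",
    expression = "data.frame",
    truth = "data.frame",
    params = "list"
  )
)

setValidity("SyntheticDataset", function(object) {
  g <- unique(object@somatic$gene)
  if (nrow(object@truth) && !all(g %in% object@truth$gene))
    return("truth table must cover every generated gene")
  if (nrow(object@somatic) && !all(g %in% object@proteome$gene))
    return("proteome table must cover every generated gene")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "GeneStudyProfile", function(object) {
  cat("GeneStudyProfile:", object@gene, "/", object@study, "\n")
  cat("  L =", object@L,
      "| n =", length(object@caseCounts),
      "| m =", length(object@matchedPositions),
      "| cases =", sum(object@caseCounts),
      "| matched cases =",
      sum(object@caseCounts[as.character(object@matchedPositions)]), "\n")
  cat("  criterion =", object@criterion,
      "| S =", format(matchScore(object), digits = 4), "\n")
})

setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel for study", object@study, "\n")
  cat("  gammaHat =", format(object@gammaHat, digits = 5),
      "| genes =", nrow(object@geneTable),
      "| epsilon =", object@epsilon, "\n")
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution:", object@gene, "/", object@study, "\n")
  cat("  alphaBg =", format(object@alphaBg, digits = 4),
      "| draws =", object@nDraws,
      "| exceedances >= S_obs =", object@exceedances, "\n")
})

setMethod("show", "OverlapResults", function(object) {
  r <- object@results
  cat("OverlapResults:", nrow(r), "gene-study pairs,",
      length(unique(r$study)), "studies, criterion =", object@criterion, "\n")
  if (!is.na(object@cutoff))
    cat("  adjusted-p cutoff =", format(object@cutoff, digits = 4),
        "| hits =", sum(r$is_hit), "\n")
  if (nrow(r)) {
    top <- r[order(r$p_adj, r$p), , drop = FALSE]
    print(utils::head(top[, c("gene", "study", "S", "snr", "p", "p_adj",
                              "expressed", "is_hit")], 5))
  }
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", nrow(object@truth), "genes,",
      nrow(object@somatic), "somatic case rows,",
      nrow(object@disease), "disease variants\n")
  if (nrow(object@truth) && "status" %in% names(object@truth))
    print(table(object@truth$status))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for GeneStudyProfile
#'
#' @param x a \code{\linkS4class{GeneStudyProfile}}.
#' @return scalar summaries of the profile.
#' @name GeneStudyProfile-accessors
NULL

#' @rdname GeneStudyProfile-accessors
#' @export
setMethod("totalCases", "GeneStudyProfile", function(x) sum(x@caseCounts))

#' @rdname GeneStudyProfile-accessors
#' @export
setMethod("matchedCases", "GeneStudyProfile", function(x)
  sum(x@caseCounts[as.character(x@matchedPositions)]))

#' @rdname GeneStudyProfile-accessors
#' @export
setMethod("nMutatedPositions", "GeneStudyProfile", function(x)
  length(x@caseCounts))

#' @rdname GeneStudyProfile-accessors
#' @export
setMethod("nMatchedPositions", "GeneStudyProfile", function(x)
  length(x@matchedPositions))

#' @rdname GeneStudyProfile-accessors
#' @export
setMethod("proteinLength", "GeneStudyProfile", function(x) x@L)

#' Accessors for BackgroundModel
#'
#' @param x a \code{\linkS4class{BackgroundModel}}.
#' @param gene gene symbol(s) to look up.
#' @name BackgroundModel-accessors
NULL

#' @rdname BackgroundModel-accessors
#' @export
setMethod("gammaHat", "BackgroundModel", function(x) x@gammaHat)

#' @rdname BackgroundModel-accessors
#' @export
setMethod("alphaBackground", "BackgroundModel", function(x, gene) {
  idx <- match(gene, x@geneTable$gene)
  if (anyNA(idx)) stop("gene(s) not in background model: ",
                       paste(gene[is.na(idx)], collapse = ", "))
  stats::setNames(x@geneTable$alpha_bg[idx], gene)
})

#' Accessors for OverlapResults
#'
#' @param x an \code{\linkS4class{OverlapResults}}.
#' @name OverlapResults-accessors
NULL

#' @rdname OverlapResults-accessors
#' @export
setMethod("resultsTable", "OverlapResults", function(x) x@results)

#' @rdname OverlapResults-accessors
#' @export
setMethod("hits", "OverlapResults", function(x)
  x@results[x@results$is_hit, , drop = FALSE])

#' Accessors for SyntheticDataset
#'
#' @param x a \code{\linkS4class{SyntheticDataset}}.
#' @name SyntheticDataset-accessors
NULL

#' @rdname SyntheticDataset-accessors
#' @export
setMethod("truthTable", "SyntheticDataset", function(x) x@truth)
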