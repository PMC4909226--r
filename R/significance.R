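# Multiple-testing correction, the expression-stratified significance cutoff,
# final hit filtering, and the expressed-vs-nonexpressed eCDF diagnostic.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone, capped at 1), pooled across all
#' gene-study pairs analyzed together. Thin validated wrapper around
#' \code{stats::p.adjust}.
#'
#' @param pvalues numeric vector of nominal p-values in [0, 1].
#' @return adjusted p-values, same length.
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Expression-stratified adjusted-p cutoff
#'
#' The significance cutoff is the first quartile of the adjusted p-values of
#' the nonexpressed gene-study results, pooled across studies: nonexpressed
#' genes are treated as a false-positive stratum, and hits must be at least as
#' significant as its lower quartile. (On the original pan-cancer data this
#' construction produced 0.062; that number depends on the full data and is
#' documentation, not a constant of the method.)
#'
#' @param results data.frame with columns p_adj and expressed (e.g.
#'   \code{resultsTable()} of an \code{\linkS4class{OverlapResults}}).
#' @param quantileType quantile rule for the quartile (default 7, linear
#'   interpolation).
#' @return the cutoff (a single number).
#' @export
expressionCutoff <- function(results, quantileType = 7) {
  nonexpr <- results$p_adj[!results$expressed]
  if (!length(nonexpr))
    stop("no nonexpressed results: supply an explicit cutoff instead")
  unname(stats::quantile(nonexpr, 0.25, type = quantileType))
}

#' Final hit filter
#'
#' A gene-study pair is a hit when it is expressed, has at least
#' \code{minCases} reported cases, a signal-to-noise ratio greater than
#' \code{snrMin}, and an adjusted p-value at or below the cutoff. With
#' \code{casesOn = "matched"} the case filter counts matched cases instead of
#' total reported cases.
#'
#' @param results results data.frame (columns expressed, total_cases,
#'   matched_cases, snr, p_adj).
#' @param cutoff adjusted-p cutoff in [0, 1].
#' @param snrMin SNR threshold (default 2, exclusive).
#' @param minCases minimum reported cases (default 2, inclusive).
#' @param casesOn \code{"total"} (default) or \code{"matched"}.
#' @return the data.frame with a logical \code{is_hit} column filled in.
#' @export
filterHits <- function(results, cutoff, snrMin = 2, minCases = 2,
                       casesOn = c("total", "matched")) {
  casesOn <- match.arg(casesOn)
  stopifnot(cutoff >= 0, cutoff <= 1)
  cases <- if (casesOn == "total") results$total_cases else
    results$matched_cases
  results$is_hit <- results$expressed &
    cases >= minCases &
    results$snr > snrMin &
    results$p_adj <= cutoff
  results
}

#' Expressed vs nonexpressed eCDF diagnostic
#'
#' Returns the empirical CDFs of the nominal p-values for the expressed and
#' nonexpressed strata together with a one-sided two-sample
#' Kolmogorov-Smirnov statistic for the expressed stratum dominating at small
#' p (the expected signature of real signal: a longer small-p tail among
#' expressed genes).
#'
#' @param results results data.frame (columns p, expressed).
#' @return list(ecdf_expressed, ecdf_nonexpressed, ks_statistic, ks_p, table)
#'   where table tabulates both eCDFs on the pooled support; NULL (with a
#'   warning) when either stratum is empty.
#' @export
ecdfReport <- function(results) {
  pe <- results$p[results$expressed]
  pn <- results$p[!results$expressed]
  if (!length(pe) || !length(pn)) {
    warning("one expression stratum is empty; eCDF report skipped")
    return(NULL)
  }
  Fe <- stats::ecdf(pe); Fn <- stats::ecdf(pn)
  ## one-sided D+ = sup_x (Fe - Fn): expressed stratum stochastically smaller
  ## (in stats::ks.test terms, the CDF of x lies above that of y: "greater")
  ks <- suppressWarnings(stats::ks.test(pe, pn, alternative = "greater"))
  grid <- sort(unique(c(pe, pn)))
  list(ecdf_expressed = Fe, ecdf_nonexpressed = Fn,
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       table = data.frame(p = grid, F_expressed = Fe(grid),
                          F_nonexpressed = Fn(grid)))
}
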