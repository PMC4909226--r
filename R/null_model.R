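# Burden-proportional background model and the permutation empirical null.
#
# The background match rate for gene i in study t is modeled linearly in the
# mutation burden, alpha = gamma_t * mu, with mu = n/L and gamma_t estimated
# as the mean over genes of the per-gene coefficient alpha_obs/mu = (m/n)/(n/L).
# The null distribution of the match score is the convolution over k of the
# score distribution given k matches, with k ~ Binomial(n, alpha): per draw a
# binomial number of matches is assigned uniformly (without replacement) to
# the observed mutated positions and the score recomputed.

#' Estimate the background proportionality coefficient per study
#'
#' \eqn{\hat\gamma_t} is the mean over contributing genes of
#' \eqn{\hat\alpha_{i,t} / \hat\mu_{i,t}}, where \eqn{\hat\alpha = m/n} is the
#' observed per-position match rate and \eqn{\hat\mu = n/L} the burden. The
#' contributing set is either all profiled genes or the expressed subset (to
#' reproduce the expression-cutoff stability check). Genes with zero matches
#' contribute zero coefficients by default.
#'
#' The per-gene background rate \eqn{\alpha_{bg} = \hat\gamma\hat\mu} is
#' clamped to [floor, 1]: the linear model can exceed 1 for extreme burden,
#' and a degenerate \eqn{\hat\gamma = 0} must not make every positive score
#' infinitely significant, so a small floor (default 1e-6) is applied.
#'
#' @param profiles list of \code{\linkS4class{GeneStudyProfile}} (one or more
#'   studies).
#' @param expression optional data.frame(gene, study, value, expressed).
#' @param exprCutoff cutoff re-applied to expression values when
#'   \code{genes = "expressed"} (so stability across cutoffs 1/5/10 can be
#'   probed on one table).
#' @param genes use \code{"all"} profiled genes or \code{"expressed"} only.
#' @param includeZeroMatch include genes with m = 0 (coefficient 0) in the
#'   mean, default TRUE.
#' @param gamma optional fixed coefficient; when given, estimation is skipped
#'   and the model is built at this gamma (used for the synthetic-data
#'   diagnostics which fix gamma = 10).
#' @param epsilon lower floor for alpha_bg.
#' @return named list of \code{\linkS4class{BackgroundModel}}, one per study.
#' @export
estimateGamma <- function(profiles, expression = NULL, exprCutoff = 1,
                          genes = c("all", "expressed"),
                          includeZeroMatch = TRUE, gamma = NULL,
                          epsilon = 1e-6) {
  genes <- match.arg(genes)
  if (!length(profiles)) stop("no profiles supplied")
  tab <- data.frame(
    gene = vapply(profiles, slot, "", "gene"),
    study = vapply(profiles, slot, "", "study"),
    n = vapply(profiles, nMutatedPositions, 0L),
    L = vapply(profiles, proteinLength, 0L),
    m = vapply(profiles, nMatchedPositions, 0L),
    stringsAsFactors = FALSE
  )
  tab$mu_hat <- tab$n / tab$L
  tab$alpha_obs <- tab$m / tab$n

  expressed <- rep(TRUE, nrow(tab))
  if (!is.null(expression)) {
    key <- paste(tab$gene, tab$study)
    ekey <- paste(expression$gene, expression$study)
    val <- expression$value[match(key, ekey)]
    expressed <- !is.na(val) & val >= exprCutoff
  }

  lapply(stats::setNames(nm = unique(tab$study)), function(st) {
    sub <- tab[tab$study == st, , drop = FALSE]
    use <- rep(TRUE, nrow(sub))
    if (genes == "expressed") use <- expressed[tab$study == st]
    if (!includeZeroMatch) use <- use & sub$m > 0
    if (is.null(gamma)) {
      if (!any(use))
        stop("no contributing genes for gamma estimation in study ", st)
      g <- mean(sub$alpha_obs[use] / sub$mu_hat[use])
    } else {
      g <- gamma
    }
    raw <- g * sub$mu_hat
    sub$alpha_bg <- pmin(1, pmax(epsilon, raw))
    sub$clamped <- raw > 1
    sub$floored <- raw < epsilon
    new("BackgroundModel", study = st, gammaHat = g,
        geneTable = sub[, c("gene", "n", "L", "mu_hat", "alpha_obs",
                            "alpha_bg", "clamped", "floored")],
        epsilon = epsilon)
  })
}

#' Sample the empirical null distribution of the match score
#'
#' Each draw takes \eqn{k \sim \mathrm{Binomial}(n, \alpha_{bg})} matches,
#' assigns them uniformly at random (without replacement) to the gene's
#' mutated positions, and recomputes the score. Sampling proceeds in batches
#' of \code{nMin} draws up to \code{nMax}, stopping early once the number of
#' draws at or above the observed score reaches \code{minExceed} (the
#' adaptive rule: genes that are clearly not significant stop at the minimum).
#'
#' @param profile a \code{\linkS4class{GeneStudyProfile}}.
#' @param alphaBg background match rate in [0, 1].
#' @param nMin,nMax minimum and maximum number of draws (defaults 1e4 / 1e6).
#' @param seed optional integer seed set before drawing.
#' @param observedS observed score the exceedance count refers to; defaults to
#'   \code{matchScore(profile)}.
#' @param minExceed early-stopping exceedance target (default 50).
#' @param keepDraws retain the sampled scores in the returned object (default
#'   TRUE; the pipeline switches this off to bound memory).
#' @return a \code{\linkS4class{NullDistribution}}.
#' @export
sampleNullDistribution <- function(profile, alphaBg, nMin = 1e4, nMax = 1e6,
                                   seed = NULL, observedS = NULL,
                                   minExceed = 50, keepDraws = TRUE) {
  if (alphaBg < 0 || alphaBg > 1) stop("alphaBg outside [0,1]")
  stopifnot(nMin >= 1, nMax >= nMin)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(observedS)) observedS <- matchScore(profile)
  counts <- unname(profile@caseCounts)

  nDraws <- 0L; exceed <- 0L
  draws <- if (keepDraws) vector("list", 0L) else NULL
  while (nDraws < nMax) {
    batch <- as.integer(min(nMin, nMax - nDraws))
    x <- cpp_null_scores(counts, alphaBg, batch)
    nDraws <- nDraws + batch
    exceed <- exceed + cpp_count_exceedances(x, observedS)
    if (keepDraws) draws[[length(draws) + 1L]] <- x
    if (exceed >= minExceed) break
  }
  new("NullDistribution", gene = profile@gene, study = profile@study,
      alphaBg = alphaBg, nDraws = nDraws, exceedances = as.integer(exceed),
      observedS = observedS,
      draws = if (keepDraws) unlist(draws) else numeric(0))
}

#' Exact null distribution of the match score by enumeration
#'
#' Computes \eqn{P(S = s) = \sum_k \mathrm{Bin}(k; n, \alpha)\,
#' \#\{k\text{-subsets with case sum } s \cdot \mathrm{total}\} / \binom{n}{k}}
#' exactly, via a subset-sum dynamic program over the positions. Enforced for
#' n <= 20; larger genes must use \code{\link{sampleNullDistribution}}.
#'
#' @param profile a \code{\linkS4class{GeneStudyProfile}}.
#' @param alphaBg background match rate in [0, 1].
#' @param limit refusal threshold on n (default 20).
#' @return data.frame(S, prob) over the achievable scores, with the total case
#'   count as attribute \code{totalCases}.
#' @export
enumerateNullExact <- function(profile, alphaBg, limit = 20L) {
  if (alphaBg < 0 || alphaBg > 1) stop("alphaBg outside [0,1]")
  counts <- as.integer(unname(profile@caseCounts))
  n <- length(counts)
  if (n > limit)
    stop("n = ", n, " exceeds the enumeration limit (", limit,
         "); use sampleNullDistribution()")
  tot <- sum(counts)
  ## M[k+1, s+1] = number of k-subsets of positions with case sum s
  M <- matrix(0, n + 1L, tot + 1L)
  M[1L, 1L] <- 1
  for (cc in counts) {
    shifted <- M[seq_len(n), seq_len(tot + 1L - cc), drop = FALSE]
    M[2:(n + 1L), (cc + 1L):(tot + 1L)] <-
      M[2:(n + 1L), (cc + 1L):(tot + 1L), drop = FALSE] + shifted
  }
  pk <- stats::dbinom(0:n, n, alphaBg)
  probS <- as.vector(t(M) %*% (pk / choose(n, 0:n)))
  keep <- probS > 0
  out <- data.frame(S = (0:tot)[keep] / tot, prob = probS[keep])
  attr(out, "totalCases") <- tot
  out
}

#' Upper-tail permutation p-value
#'
#' Uses the add-one estimator \eqn{p = (1 + \#\{draws \ge S_{obs}\}) /
#' (1 + n_{draws})}, which can never return zero.
#'
#' @param observedS observed match score; defaults to the score the null
#'   object was built against.
#' @param null a \code{\linkS4class{NullDistribution}}.
#' @return p-value in (0, 1].
#' @export
permutationPvalue <- function(observedS = NULL, null) {
  stopifnot(is(null, "NullDistribution"))
  if (is.null(observedS) ||
      isTRUE(all.equal(observedS, null@observedS, tolerance = 1e-12))) {
    exceed <- null@exceedances
  } else {
    if (!length(null@draws))
      stop("draws were not retained; rebuild the null for a different ",
           "observed score")
    exceed <- cpp_count_exceedances(null@draws, observedS)
  }
  (1 + exceed) / (1 + null@nDraws)
}

#' Exact upper-tail probability from an enumerated null
#'
#' @param enum output of \code{\link{enumerateNullExact}}.
#' @param observedS observed score.
#' @return \eqn{P(S \ge S_{obs})} under the exact null.
#' @export
exactTailProbability <- function(enum, observedS) {
  sum(enum$prob[enum$S >= observedS - 1e-9])
}
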