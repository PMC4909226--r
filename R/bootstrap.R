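# Bootstrap confidence in the match score and the signal-to-noise ratio.

#' Bootstrap match scores over reported cases
#'
#' Each replicate resamples \code{totalCases(profile)} cases with replacement
#' from the profile's case list — every case carries its position's
#' matched/unmatched label — and recomputes the match score. Because the cases
#' are exchangeable given their labels, the number of matched cases in a
#' replicate is exactly Binomial(total cases, S), which is how the resampling
#' is realised.
#'
#' @param profile a \code{\linkS4class{GeneStudyProfile}}.
#' @param nReps number of bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return numeric vector of replicate scores in [0, 1].
#' @export
bootstrapScores <- function(profile, nReps = 1000, seed = NULL) {
  stopifnot(nReps >= 1)
  if (!is.null(seed)) set.seed(seed)
  tot <- totalCases(profile)
  if (tot < 1L) stop("profile has no cases")
  s <- matchScore(profile)
  stats::rbinom(nReps, tot, s) / tot
}

#' Signal-to-noise ratio of the match score
#'
#' The default form is the score over the bootstrap variance,
#' \eqn{SNR = S / \sigma(S)^2}, with \eqn{\sigma} the sample (n-1) standard
#' deviation of the replicates; \code{form = "s_over_sd"} gives \eqn{S/\sigma}
#' for sensitivity analysis. When \eqn{\sigma = 0} the ratio is degenerate:
#' reported as \code{Inf} for a positive score (passes any finite threshold)
#' and 0 for a zero score.
#'
#' @param observedS observed match score.
#' @param replicateScores nonempty vector of bootstrap replicate scores.
#' @param form \code{"s_over_var"} (default) or \code{"s_over_sd"}.
#' @return list(snr, score_sd, degenerate).
#' @export
snr <- function(observedS, replicateScores,
                form = c("s_over_var", "s_over_sd")) {
  form <- match.arg(form)
  stopifnot(length(replicateScores) >= 1)
  sdev <- stats::sd(replicateScores)
  if (is.na(sdev)) sdev <- 0          # single replicate
  if (sdev == 0) {
    return(list(snr = if (observedS > 0) Inf else 0,
                score_sd = 0, degenerate = TRUE))
  }
  denom <- if (form == "s_over_var") sdev^2 else sdev
  list(snr = observedS / denom, score_sd = sdev, degenerate = FALSE)
}
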