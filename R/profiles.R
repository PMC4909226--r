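# Per-gene, per-study mutation profiles and the match score.

#' @include AllClasses.R
NULL

#' Build gene-study mutation profiles
#'
#' Collects, for every (gene, study) with at least one somatic case, the
#' per-position case counts and the pathogenic disease residues at those
#' positions, then classifies each mutated position under the chosen match
#' criterion:
#' \itemize{
#'   \item \code{position_only}: the position carries any pathogenic variant;
#'   \item \code{exact_change}: some pathogenic variant at the position has the
#'     same alternate residue as a somatic case there (the headline criterion —
#'     the same amino-acid alteration at the same site);
#'   \item \code{similar_change}: exact, or some somatic/pathogenic alternate
#'     pair at the position scores > 0 in the substitution-similarity table
#'     (BLOSUM62 by default).
#' }
#' Matched sets are nested: exact is a subset of similar, similar of
#' position-only.
#'
#' Only single-residue missense substitutions enter the statistic; silent,
#' nonsense, splice and other classes are parsed upstream but excluded here.
#'
#' @param somatic harmonized somatic table (gene, sample, study, position,
#'   ref, alt, variant_class).
#' @param disease harmonized, pathogenic-only disease table (gene, position,
#'   ref, alt).
#' @param proteome data.frame(gene, length).
#' @param criterion match criterion, default \code{"exact_change"}.
#' @param simMatrix substitution-similarity matrix for
#'   \code{similar_change}; defaults to BLOSUM62 from Biostrings.
#' @param verbose warn per gene skipped for a missing protein length.
#' @return named list of \code{\linkS4class{GeneStudyProfile}} objects, keyed
#'   "gene|study".
#' @export
buildProfiles <- function(somatic, disease, proteome,
                          criterion = c("exact_change", "position_only",
                                        "similar_change"),
                          simMatrix = NULL, verbose = FALSE) {
  criterion <- match.arg(criterion)
  if (criterion == "similar_change" && is.null(simMatrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    simMatrix <- e$BLOSUM62
  }
  som <- somatic[somatic$variant_class == "missense" &
                   !is.na(somatic$position) & !is.na(somatic$alt), ,
                 drop = FALSE]
  if (!nrow(som)) return(list())
  Lmap <- stats::setNames(proteome$length, proteome$gene)

  dsplit <- split(disease[, c("position", "alt")], disease$gene)

  som$key <- paste(som$gene, som$study, sep = "\r")
  rowidx <- split(seq_len(nrow(som)), som$key)
  skipped <- character(0)
  profiles <- list()
  for (k in names(rowidx)) {
    rows <- som[rowidx[[k]], , drop = FALSE]
    gene <- rows$gene[1]; study <- rows$study[1]
    L <- Lmap[gene]
    if (is.na(L)) { skipped <- c(skipped, gene); next }
    counts <- table(rows$position)
    pos <- as.integer(names(counts))
    if (any(pos > L)) {
      ## mutated beyond the canonical protein: inconsistent annotation,
      ## treated like a missing length
      skipped <- c(skipped, gene); next
    }
    somAlts <- lapply(split(rows$alt, rows$position), unique)
    dg <- dsplit[[gene]]
    disAlts <- lapply(pos, function(pp) {
      if (is.null(dg)) return(character(0))
      a <- dg$alt[dg$position == pp]
      unique(a[!is.na(a)])
    })
    names(disAlts) <- names(counts)
    matched <- .classify_matches(pos, somAlts, disAlts, criterion, simMatrix)
    profiles[[paste(gene, study, sep = "|")]] <- new(
      "GeneStudyProfile",
      gene = gene, study = study, L = as.integer(L),
      caseCounts = stats::setNames(as.integer(counts), names(counts)),
      somaticAlts = somAlts, diseaseAlts = disAlts,
      matchedPositions = matched, criterion = criterion
    )
  }
  if (length(skipped) && verbose)
    warning("skipped ", length(unique(skipped)),
            " gene(s) without a usable protein length: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  attr(profiles, "skippedGenes") <- unique(skipped)
  profiles
}

.classify_matches <- function(pos, somAlts, disAlts, criterion, simMatrix) {
  hit <- vapply(seq_along(pos), function(i) {
    d <- disAlts[[i]]
    if (!length(d)) return(FALSE)
    if (criterion == "position_only") return(TRUE)
    s <- somAlts[[i]]
    if (any(s %in% d)) return(TRUE)           # exact alteration shared
    if (criterion == "exact_change") return(FALSE)
    ok <- intersect(c(s, d), rownames(simMatrix))
    s2 <- intersect(s, ok); d2 <- intersect(d, ok)
    if (!length(s2) || !length(d2)) return(FALSE)
    any(simMatrix[s2, d2, drop = FALSE] > 0)
  }, logical(1))
  pos[hit]
}

#' Match score (proportion of matched cases)
#'
#' @param x a \code{\linkS4class{GeneStudyProfile}}.
#' @return matched cases / total cases, in [0, 1].
#' @export
setMethod("matchScore", "GeneStudyProfile", function(x) {
  tot <- sum(x@caseCounts)
  if (tot < 1L) stop("profile has no cases")   # validity should prevent this
  sum(x@caseCounts[as.character(x@matchedPositions)]) / tot
})

#' Mutation burden (unique mutated positions over protein length)
#'
#' @param x a \code{\linkS4class{GeneStudyProfile}}.
#' @return \eqn{\hat\mu = n / L}.
#' @export
setMethod("mutationBurden", "GeneStudyProfile", function(x) {
  n <- length(x@caseCounts)
  if (n > x@L) stop("more unique mutated positions than residues (n > L)")
  n / x@L
})

#' Export profiles as a flat table
#'
#' @param profiles list of \code{\linkS4class{GeneStudyProfile}}.
#' @return data.frame, one row per profile, with matched positions
#'   semicolon-joined.
#' @export
profileTable <- function(profiles) {
  do.call(rbind, lapply(unname(profiles), function(p) data.frame(
    gene = p@gene, study = p@study, L = p@L,
    n = nMutatedPositions(p), m = nMatchedPositions(p),
    total_cases = totalCases(p), matched_cases = matchedCases(p),
    S = matchScore(p),
    matched_positions = paste(sort(p@matchedPositions), collapse = ";"),
    stringsAsFactors = FALSE
  )))
}

#' Construct a profile directly from counts (for simulation and testing)
#'
#' @param gene,study identifiers.
#' @param L protein length.
#' @param caseCounts named numeric vector, names = positions.
#' @param matchedPositions integer vector of matched positions.
#' @param criterion criterion label to record.
#' @return a \code{\linkS4class{GeneStudyProfile}}.
#' @export
newProfile <- function(gene, study, L, caseCounts, matchedPositions = integer(0),
                       criterion = "exact_change") {
  new("GeneStudyProfile", gene = as.character(gene), study = as.character(study),
      L = as.integer(L),
      caseCounts = stats::setNames(as.integer(caseCounts), names(caseCounts)),
      somaticAlts = rep(list(character(0)), length(caseCounts)),
      diseaseAlts = rep(list(character(0)), length(caseCounts)),
      matchedPositions = as.integer(matchedPositions), criterion = criterion)
}
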