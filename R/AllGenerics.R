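#' @import methods
NULL

#' Match score of a gene-study profile
#'
#' The match score is the fraction of a gene's reported somatic cases, in one
#' tumor study, that fall at residue positions matched to the inherited-disease
#' catalogue under the active match criterion.
#'
#' @param x a \code{\linkS4class{GeneStudyProfile}}.
#' @return a number in [0, 1].
#' @export
setGeneric("matchScore", function(x) standardGeneric("matchScore"))

#' @rdname GeneStudyProfile-accessors
#' @export
setGeneric("totalCases", function(x) standardGeneric("totalCases"))

#' @rdname GeneStudyProfile-accessors
#' @export
setGeneric("matchedCases", function(x) standardGeneric("matchedCases"))

#' @rdname GeneStudyProfile-accessors
#' @export
setGeneric("nMutatedPositions", function(x) standardGeneric("nMutatedPositions"))

#' @rdname GeneStudyProfile-accessors
#' @export
setGeneric("nMatchedPositions", function(x) standardGeneric("nMatchedPositions"))

#' @rdname GeneStudyProfile-accessors
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))

#' Mutation burden of a profile
#'
#' Burden is the number of unique mutated residue positions divided by the
#' canonical protein length.
#'
#' @param x a \code{\linkS4class{GeneStudyProfile}}.
#' @return a number in (0, 1].
#' @export
setGeneric("mutationBurden", function(x) standardGeneric("mutationBurden"))

#' @rdname BackgroundModel-accessors
#' @export
setGeneric("gammaHat", function(x) standardGeneric("gammaHat"))

#' @rdname BackgroundModel-accessors
#' @export
setGeneric("alphaBackground", function(x, gene) standardGeneric("alphaBackground"))

#' @rdname OverlapResults-accessors
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @rdname OverlapResults-accessors
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname SyntheticDataset-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
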