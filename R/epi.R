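# Incidence arithmetic for cumulative unmet-need estimates across indications
# sharing a mutant gene (the ACVR1 example: FOP plus pediatric high-grade
# glioma).

#' Annual mutation-positive cases for one or more indications
#'
#' For each indication the annual case interval is
#' population x population fraction x incidence rate x [mutation fraction lo,
#' hi]. Incidence rates are per person per year.
#'
#' @param indications data.frame with columns name, population (persons),
#'   pop_fraction (in [0,1], e.g. 0.30 for the pediatric share), incidence
#'   (per person per year), mut_lo, mut_hi (mutation-positive fraction range,
#'   each in [0,1]).
#' @return the input with columns cases_lo, cases_hi appended
#'   (persons per year).
#' @export
annualCases <- function(indications) {
  need <- c("name", "population", "pop_fraction", "incidence",
            "mut_lo", "mut_hi")
  stopifnot(all(need %in% names(indications)))
  with(indications, {
    stopifnot(all(pop_fraction >= 0 & pop_fraction <= 1),
              all(mut_lo >= 0 & mut_lo <= 1),
              all(mut_hi >= 0 & mut_hi <= 1),
              all(mut_lo <= mut_hi),
              all(incidence >= 0))
  })
  base <- indications$population * indications$pop_fraction *
    indications$incidence
  indications$cases_lo <- base * indications$mut_lo
  indications$cases_hi <- base * indications$mut_hi
  indications
}

#' Cumulative annual incidence interval across indications
#'
#' @param indications data.frame as for \code{\link{annualCases}} (the
#'   per-indication intervals are computed if absent).
#' @return c(lo, hi), the interval sum across indications.
#' @export
cumulativeIncidence <- function(indications) {
  stopifnot(nrow(indications) >= 1)
  if (!all(c("cases_lo", "cases_hi") %in% names(indications)))
    indications <- annualCases(indications)
  c(lo = sum(indications$cases_lo), hi = sum(indications$cases_hi))
}

#' The fully in-package ACVR1 worked example
#'
#' Two indications sharing activating ACVR1 mutations, with all inputs
#' public epidemiology: fibrodysplasia ossificans progressiva (incidence 1 in
#' 2 million, all cases ACVR1-mutant) and pediatric high-grade glioma (total
#' incidence 0.85 per 100,000, applied to the pediatric 30% of the
#' population, with an ACVR1-mutant fraction of 20-30%). Endometrial cancer
#' is omitted because its absolute count needs the female population size,
#' which is a user input.
#'
#' @param population base population (default the 318 million US estimate).
#' @return data.frame of indications ready for \code{\link{annualCases}}.
#' @export
acvr1ExampleIndications <- function(population = 318e6) {
  data.frame(
    name = c("FOP", "pediatric HGG"),
    population = population,
    pop_fraction = c(1, 0.30),
    incidence = c(1 / 2e6, 0.85 / 1e5),
    mut_lo = c(1, 0.20),
    mut_hi = c(1, 0.30),
    stringsAsFactors = FALSE
  )
}
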