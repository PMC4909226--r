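# Internal helpers shared across modules.

#' @importFrom utils read.delim write.table head globalVariables
#' @importFrom stats rbinom rpois runif median quantile sd setNames dbinom
#'   p.adjust ks.test ecdf cor var
NULL

## One-letter <-> three-letter amino acid codes (Biostrings table, plus Ter/*).
.aa3to1 <- function() {
  tab <- Biostrings::AMINO_ACID_CODE  # names 1-letter, values 3-letter
  out <- stats::setNames(names(tab), toupper(tab))
  c(out, TER = "*")
}

.aa1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

## Parse HGVS-style protein substitutions. Accepts one-letter ("p.G12D",
## "G12D", "p.R100*", "p.G12G") and three-letter ("p.Gly12Asp") forms.
## Returns data.frame(ref, position, alt) with NA rows where unparseable.
.parse_protein_change <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^p\\.", "", x)
  ref <- rep(NA_character_, length(x))
  alt <- rep(NA_character_, length(x))
  pos <- rep(NA_integer_, length(x))

  re1 <- "^([A-Z])([0-9]+)([A-Z*])$"
  i1 <- grepl(re1, x)
  if (any(i1)) {
    ref[i1] <- sub(re1, "\\1", x[i1])
    pos[i1] <- as.integer(sub(re1, "\\2", x[i1]))
    alt[i1] <- sub(re1, "\\3", x[i1])
  }

  re3 <- "^([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|\\*)$"
  i3 <- !i1 & grepl(re3, x)
  if (any(i3)) {
    map <- .aa3to1()
    r3 <- toupper(sub(re3, "\\1", x[i3]))
    a3raw <- sub(re3, "\\3", x[i3])
    a3 <- toupper(a3raw)
    a3[a3raw == "*"] <- "TER"
    ref[i3] <- unname(map[r3])
    alt[i3] <- unname(map[a3])
    pos[i3] <- as.integer(sub(re3, "\\2", x[i3]))
  }

  ok1 <- !is.na(ref) & ref %in% c(.aa1, "*")
  okA <- !is.na(alt) & alt %in% c(.aa1, "*")
  bad <- !(ok1 & okA & !is.na(pos) & pos >= 1)
  ref[bad] <- NA_character_; alt[bad] <- NA_character_; pos[bad] <- NA_integer_
  data.frame(ref = ref, position = pos, alt = alt, stringsAsFactors = FALSE)
}

## Gene symbols are compared after uppercasing and whitespace stripping;
## an optional two-column synonym table (from, to) remaps afterwards.
.norm_symbol <- function(x, synonyms = NULL) {
  x <- toupper(gsub("\\s+", "", as.character(x)))
  if (!is.null(synonyms)) {
    stopifnot(all(c("from", "to") %in% names(synonyms)))
    key <- toupper(gsub("\\s+", "", synonyms$from))
    idx <- match(x, key)
    hit <- !is.na(idx)
    x[hit] <- toupper(gsub("\\s+", "", synonyms$to[idx[hit]]))
  }
  x
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

## Deterministic 32-bit sub-seed from (seed, gene, study) so per-gene draws
## do not depend on iteration order.
.substream_seed <- function(seed, gene, study) {
  h <- 0
  for (ch in utf8ToInt(paste(gene, study, sep = "\r")))
    h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 + h) %% 2147480009)
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
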