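# Readers and harmonization for the four input tables: somatic MAF-style TSV,
# inherited-disease variant catalogues (HUMSAVAR / ClinVar dialects), protein
# lengths, and RSEM-like expression summaries.

.maf_class_map <- c(
  "Missense_Mutation" = "missense",
  "Silent"            = "silent",
  "Nonsense_Mutation" = "nonsense",
  "Splice_Site"       = "splice",
  "Splice_Region"     = "splice"
)

#' Read somatic mutations from a MAF-style TSV
#'
#' Parses one somatic variant call per row. Rows whose protein-change string is
#' not a single-residue substitution (e.g. indels, \code{p.M1?}) are dropped
#' and counted; cases are per row, never deduplicated, because the match score
#' is a proportion of reported cases.
#'
#' @param path path to a tab-separated file with a header row.
#' @param study_id study / tumor-type label attached to every record.
#' @param columns named character vector giving the columns to use; defaults
#'   are the cBioPortal MAF names \code{Hugo_Symbol},
#'   \code{Tumor_Sample_Barcode}, \code{Variant_Classification},
#'   \code{Protein_Change}.
#' @param synonyms optional data.frame(from, to) of gene-symbol synonyms.
#' @param verbose emit per-file parse counts.
#' @return data.frame with columns gene, sample, study, position, ref, alt,
#'   variant_class, and attributes \code{nInput}, \code{nKept},
#'   \code{nSkipped}.
#' @export
readSomaticMaf <- function(path, study_id,
                           columns = c(gene = "Hugo_Symbol",
                                       sample = "Tumor_Sample_Barcode",
                                       class = "Variant_Classification",
                                       protein_change = "Protein_Change"),
                           synonyms = NULL, verbose = FALSE) {
  stopifnot(is.character(study_id), nzchar(study_id))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols))
    stop("MAF file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  parsed <- .parse_protein_change(raw[[columns[["protein_change"]]]])
  cls <- raw[[columns[["class"]]]]
  variant_class <- unname(.maf_class_map[cls])
  variant_class[is.na(variant_class)] <- "other"

  keep <- !is.na(parsed$position)
  out <- data.frame(
    gene = .norm_symbol(raw[[columns[["gene"]]]][keep], synonyms),
    sample = as.character(raw[[columns[["sample"]]]][keep]),
    study = study_id,
    position = parsed$position[keep],
    ref = parsed$ref[keep],
    alt = parsed$alt[keep],
    variant_class = variant_class[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "nInput") <- nrow(raw)
  attr(out, "nKept") <- nrow(out)
  attr(out, "nSkipped") <- nrow(raw) - nrow(out)
  .msg(verbose, "readSomaticMaf: ", nrow(raw), " rows, kept ", nrow(out),
       ", skipped ", nrow(raw) - nrow(out), " unparseable")
  out
}

.humsavar_category_map <- c(
  "DISEASE" = "disease-pathogenic",
  "POLYMORPHISM" = "polymorphism",
  "UNCLASSIFIED" = "unclassified",
  ## post-2018 HUMSAVAR labels, mapped onto the same three buckets
  "LP/P" = "disease-pathogenic",
  "LB/B" = "polymorphism",
  "US" = "unclassified"
)

.clinvar_pathogenic <- c("PATHOGENIC", "LIKELY PATHOGENIC",
                         "PATHOGENIC/LIKELY PATHOGENIC")
.clinvar_benign <- c("BENIGN", "LIKELY BENIGN", "BENIGN/LIKELY BENIGN")

#' Read inherited-disease variants (HUMSAVAR or ClinVar dialect)
#'
#' The HUMSAVAR dialect is the whitespace-delimited flat file with three-letter
#' substitution codes (\code{p.Gly12Asp}) and a Disease / Polymorphism /
#' Unclassified label. The ClinVar dialect is the variant_summary-style TSV
#' with a clinical-significance column and an HGVS name containing a
#' \code{p.} token. Rows with unknown amino-acid codes, or ClinVar names
#' without a parseable protein substitution, are skipped and counted.
#'
#' Readers retain all categories; \code{\link{filterPathogenic}} keeps only the
#' pathogenic subset.
#'
#' @param path input file.
#' @param dialect \code{"humsavar"} or \code{"clinvar"}.
#' @param columns for the clinvar dialect, named vector with entries
#'   \code{gene}, \code{name}, \code{significance} (defaults match
#'   variant_summary: GeneSymbol, Name, ClinicalSignificance).
#' @param synonyms optional gene-symbol synonym table.
#' @param verbose emit parse counts.
#' @return data.frame with columns gene, position, ref, alt, disease_label,
#'   category, source_dialect, splice_affecting; attributes \code{nInput},
#'   \code{nKept}, \code{nSkipped}.
#' @export
readDiseaseVariants <- function(path, dialect = c("humsavar", "clinvar"),
                                columns = c(gene = "GeneSymbol",
                                            name = "Name",
                                            significance = "ClinicalSignificance"),
                                synonyms = NULL, verbose = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "humsavar") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    ## data lines carry a p.Xxx123Yyy token; header/prose lines do not
    lines <- grep("p\\.[A-Za-z]{3}[0-9]+", lines, value = TRUE)
    nInput <- length(lines)
    fields <- strsplit(trimws(lines), "[ \t]+")
    gene <- vapply(fields, `[`, "", 1L)
    chg <- vapply(fields, function(f) {
      tok <- grep("^p\\.", f, value = TRUE)
      if (length(tok)) tok[1] else NA_character_
    }, "")
    cat_tok <- vapply(fields, function(f) {
      hit <- toupper(f) %in% names(.humsavar_category_map)
      if (any(hit)) toupper(f[which(hit)[1]]) else NA_character_
    }, "")
    label <- vapply(fields, function(f) {
      hit <- which(toupper(f) %in% names(.humsavar_category_map))
      if (length(hit) && hit[1] + 2 <= length(f))
        paste(f[(hit[1] + 2):length(f)], collapse = " ")  # skip dbSNP field
      else ""
    }, "")
    parsed <- .parse_protein_change(chg)
    category <- unname(.humsavar_category_map[cat_tok])
    keep <- !is.na(parsed$position) & !is.na(category)
    out <- data.frame(
      gene = .norm_symbol(gene[keep], synonyms),
      position = parsed$position[keep],
      ref = parsed$ref[keep],
      alt = parsed$alt[keep],
      disease_label = label[keep],
      category = category[keep],
      source_dialect = "humsavar",
      splice_affecting = grepl("splic", label[keep], ignore.case = TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    missing_cols <- setdiff(unname(columns), names(raw))
    if (length(missing_cols))
      stop("ClinVar file ", path, " is missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    nInput <- nrow(raw)
    ## protein change is the "(p.Xxx123Yyy)" token inside the HGVS Name
    tok <- regmatches(raw[[columns[["name"]]]],
                      regexpr("p\\.[A-Za-z*]{3}[0-9]+[A-Za-z*]{1,3}",
                              raw[[columns[["name"]]]]))
    chg <- rep(NA_character_, nrow(raw))
    chg[regexpr("p\\.[A-Za-z*]{3}[0-9]+[A-Za-z*]{1,3}",
                raw[[columns[["name"]]]]) > 0] <- tok
    parsed <- .parse_protein_change(chg)
    sig <- toupper(trimws(raw[[columns[["significance"]]]]))
    category <- rep("unclassified", nrow(raw))
    category[sig %in% .clinvar_pathogenic] <- "disease-pathogenic"
    category[sig %in% .clinvar_benign] <- "polymorphism"
    keep <- !is.na(parsed$position)
    out <- data.frame(
      gene = .norm_symbol(raw[[columns[["gene"]]]][keep], synonyms),
      position = parsed$position[keep],
      ref = parsed$ref[keep],
      alt = parsed$alt[keep],
      disease_label = raw[[columns[["name"]]]][keep],
      category = category[keep],
      source_dialect = "clinvar",
      splice_affecting = FALSE,
      stringsAsFactors = FALSE
    )
  }
  attr(out, "nInput") <- nInput
  attr(out, "nKept") <- nrow(out)
  attr(out, "nSkipped") <- nInput - nrow(out)
  .msg(verbose, "readDiseaseVariants(", dialect, "): ", nInput,
       " rows, kept ", nrow(out), ", skipped ", nInput - nrow(out))
  out
}

#' Keep only pathogenic disease variants
#'
#' Retains records in the disease-pathogenic category; polymorphisms and
#' unclassified alleles are removed. Silent substitutions (ref == alt) are
#' removed unless flagged splice-affecting, since a silent change that breaks
#' splicing is still pathogenic at the protein level it disrupts.
#'
#' @param variants a disease-variant data.frame from
#'   \code{\link{readDiseaseVariants}}.
#' @return the filtered data.frame.
#' @export
filterPathogenic <- function(variants) {
  if (!nrow(variants)) return(variants)
  keep <- variants$category == "disease-pathogenic"
  silent <- !is.na(variants$ref) & !is.na(variants$alt) &
    variants$ref == variants$alt
  keep <- keep & (!silent | variants$splice_affecting)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove (gene, position) keys whose reference residues disagree
#'
#' For every (gene, position) present in both the somatic and disease tables,
#' if the union of reference residues reported at that key has more than one
#' residue, all records at the key are removed from both tables. The operation
#' is symmetric in the two inputs and idempotent.
#'
#' @param somatic harmonized somatic table.
#' @param disease harmonized disease table.
#' @return list(somatic, disease, report) where report is a data.frame of
#'   removed keys with per-source record counts.
#' @export
reconcileReferenceResidues <- function(somatic, disease) {
  skey <- paste(somatic$gene, somatic$position, sep = "\r")
  dkey <- paste(disease$gene, disease$position, sep = "\r")
  shared <- intersect(skey, dkey)
  bad <- character(0)
  for (k in shared) {
    refs <- unique(c(somatic$ref[skey == k], disease$ref[dkey == k]))
    refs <- refs[!is.na(refs)]
    if (length(refs) > 1) bad <- c(bad, k)
  }
  srm <- skey %in% bad
  drm <- dkey %in% bad
  report <- if (length(bad)) {
    parts <- strsplit(bad, "\r", fixed = TRUE)
    data.frame(
      gene = vapply(parts, `[`, "", 1L),
      position = as.integer(vapply(parts, `[`, "", 2L)),
      n_somatic_removed = vapply(bad, function(k) sum(skey == k), 0L),
      n_disease_removed = vapply(bad, function(k) sum(dkey == k), 0L),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(gene = character(0), position = integer(0),
               n_somatic_removed = integer(0), n_disease_removed = integer(0))
  }
  s2 <- somatic[!srm, , drop = FALSE]; rownames(s2) <- NULL
  d2 <- disease[!drm, , drop = FALSE]; rownames(d2) <- NULL
  list(somatic = s2, disease = d2, report = report)
}

#' Read protein lengths from a two-column TSV or a protein FASTA
#'
#' @param path either a TSV with columns gene and length (header optional,
#'   detected), or a FASTA whose record names are gene symbols (length is the
#'   sequence length).
#' @param synonyms optional gene-symbol synonym table.
#' @return data.frame(gene, length).
#' @export
readProteinLengths <- function(path, synonyms = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    aa <- Biostrings::readAAStringSet(path)
    gene <- vapply(strsplit(names(aa), "[ |]"), `[`, "", 1L)
    out <- data.frame(gene = .norm_symbol(gene, synonyms),
                      length = Biostrings::width(aa),
                      stringsAsFactors = FALSE)
  } else {
    has_header <- !grepl("\t[0-9]+\\s*$", first)
    tab <- utils::read.delim(path, header = has_header,
                             stringsAsFactors = FALSE)
    names(tab)[1:2] <- c("gene", "length")
    out <- data.frame(gene = .norm_symbol(tab$gene, synonyms),
                      length = as.integer(tab$length),
                      stringsAsFactors = FALSE)
  }
  if (any(is.na(out$length) | out$length < 1L))
    stop("protein lengths must be positive integers")
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize expression per (gene, study) and flag expressed genes
#'
#' Reads a wide RSEM-like TSV (gene rows, sample columns), maps samples to
#' studies, and summarizes each (gene, study) as the median over that study's
#' available samples. Per-sample missing values are ignored by the median; a
#' (gene, study) pair with no values at all is imputed with the median of that
#' gene's available summaries in the other studies. The expressed flag is
#' \code{summary >= cutoff}.
#'
#' @param path wide TSV; first column gene symbols, remaining columns samples.
#' @param cutoff nonnegative expression cutoff (default 1; the companion
#'   cutoffs 5 and 10 are used for stability checks).
#' @param studyMap data.frame(sample, study); when NULL all samples form one
#'   study labeled "ALL".
#' @param synonyms optional gene-symbol synonym table.
#' @return data.frame(gene, study, value, expressed).
#' @export
loadExpression <- function(path, cutoff = 1, studyMap = NULL, synonyms = NULL) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
  wide <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  gene <- .norm_symbol(wide[[1]], synonyms)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (any(mat < 0, na.rm = TRUE))
    stop("negative expression values are not allowed")
  samples <- colnames(mat)
  if (is.null(studyMap))
    studyMap <- data.frame(sample = samples, study = "ALL",
                           stringsAsFactors = FALSE)
  studyMap <- studyMap[studyMap$sample %in% samples, , drop = FALSE]
  studies <- unique(studyMap$study)

  out <- do.call(rbind, lapply(studies, function(st) {
    cols <- studyMap$sample[studyMap$study == st]
    vals <- mat[, cols, drop = FALSE]
    data.frame(gene = gene,
               study = st,
               value = apply(vals, 1L, function(v)
                 if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  ## impute fully-missing (gene, study) pairs from the gene's other studies
  miss <- is.na(out$value)
  if (any(miss)) {
    genemed <- tapply(out$value, out$gene, stats::median, na.rm = TRUE)
    out$value[miss] <- genemed[out$gene[miss]]
  }
  out$expressed <- !is.na(out$value) & out$value >= cutoff
  rownames(out) <- NULL
  out
}

#' Build an expression table from an in-memory long data.frame
#'
#' Convenience constructor applying (or re-applying) an expressed cutoff to a
#' data.frame with columns gene, study, value.
#'
#' @param df data.frame(gene, study, value).
#' @param cutoff nonnegative expression cutoff.
#' @return data.frame(gene, study, value, expressed).
#' @export
expressionTable <- function(df, cutoff = 1) {
  stopifnot(all(c("gene", "study", "value") %in% names(df)),
            is.numeric(cutoff), cutoff >= 0)
  if (any(df$value < 0, na.rm = TRUE))
    stop("negative expression values are not allowed")
  df$expressed <- !is.na(df$value) & df$value >= cutoff
  df
}
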