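Package: VariantOverlay
Title: Residue-Level Overlap Statistics Between Somatic Cancer Mutations and
    Inherited-Disease Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests, per gene and per tumor study, whether somatic cancer
    mutations fall on the same protein residues as pathogenic variants from
    inherited-disease catalogues (UniProt HUMSAVAR, ClinVar) more often than
    expected under a mutation-burden-scaled background model. Provides a match
    score with bootstrap signal-to-noise ratios, permutation p-values against a
    binomial empirical null, an exact enumeration of that null for small genes,
    Benjamini-Hochberg correction with an expression-stratified significance
    cutoff, a synthetic-data generator for calibration and power studies, and a
    small incidence calculator for cumulative unmet-need estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'VariantOverlay-package.R'
    'bootstrap.R'
    'epi.R'
    'io.R'
    'null_model.R'
    'pipeline.R'
    'profiles.R'
    'significance.R'
    'simulate.R'
    'utils.R'
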