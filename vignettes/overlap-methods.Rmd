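---
title: "Scoring residue-level overlap between somatic mutations and inherited-disease variants"
author: "VariantOverlay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring residue-level overlap between somatic mutations and inherited-disease variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the method answers

Inherited-disease catalogues (UniProt HUMSAVAR, ClinVar) record amino-acid
substitutions with known pathogenicity. When a somatic mutation in a tumor
exome lands on the same residue — sometimes the identical substitution — it is
tempting to read that as evidence of a driver. But long, heavily mutated genes
overlap any catalogue by chance, so raw overlap is dominated by false
positives (the classic example being RYR2, enormous and heavily mutated in
many tumor types). VariantOverlay quantifies, per gene $i$ and tumor study
$t$, whether the observed overlap exceeds what a mutation-burden-scaled
background predicts.

## The model

**Match score.** For each (gene, study) with at least one reported somatic
case, cases are tallied per residue position. A position is *matched* under
one of three criteria: `position_only` (any pathogenic variant at that
residue), `exact_change` (the same alternate residue; the default, since the
headline observation is the same amino-acid alteration at the same site), or
`similar_change` (alternate pairs scoring $> 0$ in a substitution-similarity
table, BLOSUM62 by default). The score is

$$S_{i,t} = \frac{\#\{\text{matched cases}\}}{\#\{\text{total cases}\}} \in [0,1].$$

Only single-residue missense substitutions enter the statistic; indel,
nonsense and splice records are parsed and retained in the harmonized tables
but excluded from matching. Matching is evaluated per position: a position is
matched when any somatic alternate observed there satisfies the criterion
against any catalogued pathogenic alternate, and all cases at a matched
position count as matched. The three criteria are nested by construction.

**Confidence (bootstrap SNR).** The case list is resampled with replacement
($N = 1000$ by default) and the score recomputed, giving a standard deviation
$\sigma(S)$ and a signal-to-noise ratio $\mathrm{SNR} = S/\sigma(S)^2$.
Because the cases are exchangeable given their matched/unmatched labels, the
matched count in a replicate is exactly $\mathrm{Binomial}(\text{total
cases}, S)$; the implementation draws it that way rather than shuffling
labels, which is the identical distribution at a fraction of the cost. The
score-over-variance form is implemented literally; a score-over-sd switch
(`snrForm = "s_over_sd"`) is provided for sensitivity analysis because the
two readings cannot be distinguished from the source's notation. With the
default form, $\sigma^2 \approx S(1-S)/\text{cases}$, so the SNR grows with
the case count and the $\mathrm{SNR} > 2$ hit filter mostly removes
single-case and zero-score genes. When $\sigma = 0$ the ratio is degenerate
and reported as $+\infty$ for $S > 0$ (passes any finite threshold) and $0$
for $S = 0$.

**Background model.** The mutation burden is $\hat\mu_{i,t} = n_{i,t} /
L_{i,t}$ (unique mutated positions over canonical protein length), and the
background match rate is assumed linear in burden, $\alpha_{i,t} = \gamma_t\,
\mu_{i,t}$, with a study-specific coefficient estimated as the mean of
per-gene coefficients

$$\hat\gamma_t = \frac{1}{N}\sum_i \frac{\hat\alpha_{i,t}}{\hat\mu_{i,t}},
\qquad \hat\alpha_{i,t} = \frac{m_{i,t}}{n_{i,t}}.$$

Genes with $m = 0$ contribute zero coefficients (configurable). Since
$\alpha = \gamma\mu$ forces $\gamma = \alpha/\mu$, the mean is taken over
$\hat\alpha/\hat\mu$; the transposed reading is dimensionally inconsistent
with the linear model and is not offered. $\alpha_{bg} = \hat\gamma\hat\mu$
is clamped to $[\epsilon, 1]$ with $\epsilon = 10^{-6}$: the linear model can
exceed 1 for extreme burden (the clamp at 1 is also the model's account of
RYR2-like genes — at high enough burden, full overlap is expected by chance
and the gene can never be significant), and the floor prevents a degenerate
$\hat\gamma = 0$ from making every positive score infinitely significant.
Both events are flagged in the model's gene table.

**Empirical null and p-value.** The null score distribution is the
convolution over $k$ of the score given $k$ matches, with $k \sim
\mathrm{Binomial}(n, \alpha_{bg})$: per draw, $k$ distinct positions are
chosen uniformly among the $n$ mutated positions (the Bernoulli-per-position
reading, which makes the match count exactly binomial and keeps
$\hat\alpha = m/n$ in the same per-position units) and the score recomputed
from the case counts there. Draws proceed in batches of $10^4$ up to $10^6$,
stopping once 50 draws at or above the observed score have accumulated — an
adaptive rule that spends draws only on genes that might be significant
while bounding the coefficient of variation of small p-values near
$1/\sqrt{50}$. The p-value is the add-one estimator
$p = (1 + \#\{S_{null} \ge S_{obs}\})/(1 + n_{draws})$, which cannot return
zero and is mildly conservative. For genes with $n \le 20$ positions an exact
enumeration (`enumerateNullExact`, a subset-sum dynamic program over
positions) provides the same distribution in closed form; it is the oracle
against which the sampler is tested, not a second analysis route.

**Multiple testing and the expression-stratified cutoff.** Nominal p-values
are Benjamini–Hochberg adjusted, pooled across all gene-study pairs by
default (matching the pan-cancer construction of the cutoff; per-study
adjustment is a flag). The significance cutoff is the first quartile of the
adjusted p-values of *nonexpressed* gene-study pairs: nonexpressed genes
cannot plausibly be drivers, so their adjusted-p distribution is treated as a
false-positive reference and hits must beat its lower quartile. Hits must
additionally be expressed, have at least two reported cases, and
$\mathrm{SNR} > 2$. The quartile uses the type-7 (linear interpolation)
quantile; the "at least two reported cases" filter counts total cases, with a
matched-cases variant behind a flag, since the intended reading is ambiguous.

## Reproducibility

Every stochastic step (bootstrap, permutation draws) runs in a substream
seeded deterministically from (seed, gene, study), so results are identical
regardless of iteration order, and a run directory (results, hits, eCDF
table, manifest with all parameters) is written when `outDir` is given. The
permutation inner loop is compiled (Rcpp) and uses R's RNG, so `set.seed`
governs it like any R code.

## What the synthetic generators emulate

`generateSimulationPanel` reproduces the published simulation design: 1000
genes with protein length 10–8000 (log-uniform — lengths are scale-like),
1–100 exact positional matches, target score 0.01–0.99, background burden
from one unmatched position to the maximum the length allows, and case counts
scaled 1–50. The "unit measurement" construction places one case per mutated
position and adds the fewest extra cases needed to reach the target score, so
the achieved score equals the target within one unit case; the scale factor
then multiplies all counts without changing the score. Sampling
distributions over the ranges are not stated in the source; uniform
(log-uniform for length) is used and recorded in the truth table. Synthetic
disease variants copy the somatic alternate residue, so all three criteria
coincide on generated data.

`generateNullDataset` generates data from the background model itself: each
position is matched independently with probability
$\mathrm{clamp}(\gamma_{true}\, n/L, 0, 1)$. Defaults, chosen once as
realistic for cohort-scale exome data: lengths log-uniform 200–5000, per-gene
burden uniform 0.01–0.08 (at $\gamma = 10$ the background rate spans 0.1–0.8
without clamping, so the binomial null is exercised away from its degenerate
edges), case counts $1 + \mathrm{Poisson}(1)$ per position, and an expressed
flag drawn Bernoulli(0.5) *independent of gene architecture*, with expressed
values log-uniform 1–1000 (so read cutoffs 1/5/10 select slightly different
gene sets) and nonexpressed values below 0.5. Planted enriched genes use low
burden (0.004–0.008) with a tenfold (configurable) match-probability
enrichment and at least two cases per position, hence five or more reported
cases. The optional RYR2 analog is a 5000-residue gene with 600 mutated
positions: at $\gamma = 10$ its background rate saturates at 1, so its
p-value is exactly 1 — the model's own explanation of why extreme-burden
genes are not significant however much they overlap.

Real data differ in ways the generators deliberately do not model:
mutational signatures and trinucleotide context, codon-level hotspots,
inter-gene correlation of burden, expression that correlates with mutation
rate (transcription-coupled repair), and catalogue curation noise. Passing
calibration and power checks on synthetic data therefore shows the
statistics are internally correct under the stated model, not that the model
captures every property of tumor exomes.

## Problem sizes used by the test suite

The repeated-seed checks run at reduced sizes chosen to keep the full suite
comfortably inside a desktop run: single calibration runs use the stated
2000 (calibration fraction) and 1000 genes (coefficient recovery,
architecture diagnostics); the repeated-seed hit-count and power checks use
20 seeds at 700 and 310 genes per seed, with permutation draws capped at
$10^5$. The acceptance script repeats the same computations at 10 seeds.

## A known degeneracy of the derived cutoff

On *fully null* data the nonexpressed-quartile cutoff has no signal to
anchor it: expressed and nonexpressed results then follow the same
distribution, so by the definition of a quantile roughly a quarter of the
expressed stratum falls at or below the nonexpressed first quartile, and
Benjamini–Hochberg ties can push the cutoff to 1.0, making it vacuous. The
stratified cutoff is a guard against miscalibration *relative to a
false-positive stratum* — the regime it was designed for, where expressed
genes carry real signal and the nonexpressed quartile is small — not a
family-wise error control under a global null. The package reports the
derived cutoff in every run manifest; users analyzing data they believe to
be signal-free should prefer an explicit cutoff (`explicitCutoff`).

## Numerical and edge-case choices

Scores are ratios of small integers; exceedance comparisons use a $10^{-9}$
absolute tolerance so equal rationals compare equal. Profiles require every
mutated position to carry a case and $n \le L$; a gene annotated beyond its
canonical length is skipped like a gene with no length. Reference-residue
reconciliation removes *all* records at a (gene, position) key where the
union of reference residues across both sources has more than one residue —
symmetric and idempotent. Expression summaries are per-(gene, study) medians;
per-sample missing values are ignored by the median and a fully missing
(gene, study) pair is imputed with the median of that gene's summaries in the
other studies. Three-letter amino-acid codes are mapped through the
Biostrings code table; rows with unknown codes are skipped and counted, and
every reader reports input = kept + skipped.
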