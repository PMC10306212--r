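---
title: "Rare-variant burden testing against public control summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden testing against public control summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The problem and the model

Family-based rare-variant association studies compare a small cohort of
jointly-called, exome-sequenced cases against very large public control
databases (gnomAD, ExAC) that publish only per-variant summary statistics:
allele count (AC), allele number (AN), homozygote count and filter status
for a cohort of known size. Because per-individual control genotypes are
unavailable, per-variant tests are replaced by *collapsing (burden) tests*:
qualifying rare deleterious variants are pooled within a unit (a gene, or a
gene set from KEGG/Reactome/Biocarta), each cohort is reduced to a carrier
count, and the 2×2 table

|            | carriers | non-carriers |
|------------|----------|--------------|
| cases      | a        | n_cases − a  |
| controls   | c        | n_controls − c |

is tested with a two-sided Fisher's exact test. On the case side, a carrier
under the dominant model is an individual with summed alt-allele dosage ≥ 1
across the unit's qualifying variants (each person counted once). On the
control side, the carrier count is approximated by the summed allele counts
capped at the cohort size; at qualifying frequencies (≤ 1%) double-carrier
controls are rare enough that the sum is a tight proxy. An optional
recessive model counts case individuals with summed dosage ≥ 2 and control
homozygotes.

The two-sided p-value is computed conditionally on both margins: the sum of
hypergeometric point probabilities not exceeding that of the observed
table, with a relative tie tolerance of 1e−7 (symmetric tables tie to
within floating-point rounding). The implementation is checked exhaustively
against brute-force enumeration for all tables with total ≤ 60 and against
random tables at public-control scale (agreement to better than 1e−12
relative).

## Harmonization and qualifying variants

Cases and public controls are sequenced with different capture designs, so
the comparison is restricted to well-covered territory: per base, the
fraction of samples covered at a read depth strictly greater than 10× is
computed separately for cases and controls, and a base is retained only if
that fraction is **at least 0.90 in both** cohorts (threshold inclusive;
depth threshold strict). Retained bases form a minimal half-open interval
set; coverage inputs use 0-based half-open coordinates internally while
VCF-derived variant keys stay 1-based.

Variant representation is harmonized by splitting multiallelic records into
biallelic ones and trimming shared allele suffixes then prefixes (position
advancing per trimmed leading base) while both alleles keep length > 1.
This reference-free trim makes case, control and annotation keys directly
joinable; it is idempotent and preserves the haplotype edit. A genome FASTA
is deliberately not required.

A variant *qualifies* if it lies in retained territory, has PASS filter
status in both cohorts, its effective allele frequency is ≤ the arm's
ceiling (1% for the "rare" arm, 0.1% for the "very rare" arm; comparison
inclusive), and it is predicted deleterious. Deleteriousness defaults to
the conjunction (`combine_rule = "AND"`) of CADD Phred ≥ 20 and a
high-impact consequence (splice acceptor/donor, stop-gain, frameshift,
stop-lost, start-lost); the sentence defining the rule in the source
protocol is ambiguous between AND and OR, so the rule is exposed in
`qualify_config()` while AND — the literal reading — is the default.
Unknown consequence terms warn and count as non-impact.

The *effective allele frequency* walks an ordered list of sources (the
control-matched European frequency first, then the ALFA European
frequency) and takes the first non-missing entry; a variant absent from
every source is treated as frequency 0 (novel). Missing genotypes (`./.`)
count as dosage 0, which is conservative for case counts. Control rows
absent for a case variant contribute AC = 0: gnomAD-style summaries omit
unobserved alleles, and the coverage gate has already certified the region
callable.

Only genes with ≥ 1 qualifying variant carried by ≥ 1 case are analysed
(the SNP map); a separate arm restricts to genes with case allele count
≥ 2, which covers both one homozygous case and two heterozygous carriers.
A variant annotated to several genes contributes to each of them — the
pathway table of the bundled published example requires exactly this
behaviour (the same gene contributes to many low-level Reactome sets).

## Pathway aggregation

Gene sets are read from GMT files; each set is intersected with the SNP-map
genes and empty sets are dropped, so the multiplicity denominator of the
pathway arm is the number of *surviving* sets pooled across the three
databases. Pathway counts are plain sums of member-gene counts — faithfully
to the source protocol, which sums variant counts — so an individual
carrying qualifying variants in two member genes is counted twice on the
case side; the count is capped at the cohort size for table validity and
the row flagged. Reactome low-level pathways are the tested units;
higher-level hierarchy labels are carried as annotation only. Redundancy
across databases is accepted as-is (it makes the Bonferroni correction
conservative).

## Inflation factor and multiplicity

Observed −log10 p-values are paired with uniform order-statistic
expectations −log10(i/(n+1)). The inflation factor λ(0.5–0.95) is the
through-origin least-squares slope of observed on expected, fitted only to
points whose expected value lies within the [0.5, 0.95] quantile window of
the expected distribution — equivalently, points whose expected p lies
between its 5th and 50th percentile. The window drops both the
uninformative head and the extreme tail, which in sparse collapsing designs
is dominated by ultra-rare variants. A through-origin fit is used because λ
measures slope inflation; an intercept would absorb the signal. With fewer
than 20 in-window points the estimate is unstable and λ falls back to 1
with a warning.

Corrections are multiplicative and ordered for reporting clarity (the
order is immaterial under multiplication): `p_lambda = min(1, p_raw *
max(lambda, 1))` — deflation (λ < 1) is never applied, as shrinking
p-values would be anti-conservative — then Bonferroni over the units tested
in the arm, `p_final = min(1, p_lambda * n_tests)`. A unit is called
associated when `p_final ≤ 0.05` (boundary inclusive).

## The synthetic-data generator

`simulate_null()` / `simulate_alternative()` emit a complete input bundle —
multi-sample VCF, control summary TSV, coverage tracks, annotation table,
GMT — plus a ground-truth sidecar the pipeline never reads. The defaults
emulate the study conditions: 38 cases against 56,885 summary controls
(33,370 matches the ExAC arm), site frequencies log-uniform on
(10⁻⁶, 10⁻²], Hardy–Weinberg case genotypes (dosage ~ Binomial(2, f)),
independent control allele counts (AC ~ Binomial(2·n_controls, f); the
cohorts do not overlap), 1 + Poisson(3) variant sites per gene (a realistic
handful of candidate qualifying sites), a 5% share of variants with an
empty AF map (novel), and optional contiguous coverage-dropout blocks that
exercise the interval logic rather than per-base flags. In risk genes the
per-variant case carrier probability becomes min(1, enrichment · 2f),
capped with a warning. Identical configurations regenerate byte-identical
bundles.

What the generator does **not** emulate: linkage disequilibrium, population
structure, sequencing artifacts, capture-platform batch effects, or
annotation error. Passing tests therefore validate the statistical
machinery and its calibration under idealized sampling, not robustness to
the confounders that affect real case/public-control comparisons.

## Calibration results, and a deliberate red flag

On 2,000 simulated null genes at the default conditions, the empirical
type-I error of the gene-level test at α = 0.05 is ≈ 0.04 — below the
nominal level, as expected for an exact test on sparse tables — and a
spiked gene with enrichment 20 and total site frequency 0.005 attains the
smallest raw p among 40 simulated genes in ≈ 99% of 200 replicates. These
numbers are recomputed, not quoted, by `scripts/acceptance.R` and the test
suite.

λ on the same null simulation is ≈ 1.7, *not* ≈ 1. This is a property of
the design, not a bug: only genes with at least one case carrier are
tested, so under the null the tested genes are selected on the case count
and their p-values are stochastically small — most visibly for ultra-rare
sites, where the selecting event is itself the numerator of the test. This
selection-induced inflation is exactly why the protocol multiplies p-values
by λ when λ > 1; users should expect λ substantially above 1 whenever the
case cohort is small and the qualifying spectrum reaches allele counts of
order 1 in the controls, and should not interpret it as ancestry mismatch
alone.

## Numerical and degenerate-input choices

* Fisher tie tolerance: 1e−7 relative (matches the common convention for
  two-sided exact tests); oracle agreement is still better than 1e−12
  because ties are resolved identically on both paths.
* Odds ratios with a zero cell are reported as `NA` rather than
  Haldane-corrected — they are descriptive output only.
* Empty gene or pathway result sets warn and yield header-only outputs;
  zero-sample VCFs, malformed lines (named by line number), allele-count
  invariant violations (named by row) and zero-arm configurations are hard
  errors.
* All outputs are sorted lexicographically by unit name and reruns are
  byte-identical, so diffs between analysis arms are meaningful.

## Problem sizes used in the checks

The shipped checks run at desk scale by choice: exhaustive Fisher
enumeration over all tables with total ≤ 60 plus 1,000 random
control-scale tables; 2,000 null genes for calibration; 200 replicates for
power; pipeline round-trips on bundles of 25–150 genes. The published
per-gene count table bundled under `inst/extdata/lymphoid/` exercises the
pathway aggregation on real printed numbers, including two mutually
inconsistent printed cells (the peroxisome EHHADH/PEX7 case counts in the
gnomAD ≤ 0.1% arm) that are flagged rather than silently corrected; the
corresponding pathway case total is treated as non-reproducible.

## Known limitations

* Control carrier counts are an AC-sum proxy; at frequencies near the 1%
  ceiling it slightly overstates carriers (homozygotes counted twice).
* The recessive control side uses homozygote counts only; compound
  heterozygosity in controls is invisible to summary statistics, so the
  recessive test is asymmetric and disabled by default.
* Corrected p-values from the source study cannot be reproduced exactly:
  its per-arm inflation factors were published only in supplementary
  material and its raw exomes are not deposited. The correction chain
  itself (p_raw × λ × n_tests, with caps) is unit-tested on analytic
  cases instead.
* A variant mapped to k genes contributes to all k; no transcript
  selection or annotation re-ranking is attempted.
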