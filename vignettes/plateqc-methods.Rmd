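---
title: "plateqc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plateqc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateqc)
```

## The problem

Targeted SNP genotyping projects type tens of SNPs on thousands of samples
spread over 384-well plates, on two families of platforms: endpoint
allelic-discrimination chemistry read on RT-PCR instruments (TaqMan, KASPar)
and multiplexed single-base-extension chemistry read by MALDI-TOF mass
spectrometry (iPLEX). The instruments' analysis software exports per-plate
text tables whose "genotype" column is not a genotype: it is a raw call
token — a detector label, a "Both", an allele concatenation, or an empty
cell. Turning a drawer of such files into a QC-checked genotype matrix
involves merging, token conversion, replicate reconciliation and statistical
checks, each of which silently corrupts data when done ad hoc. `plateqc`
implements that workflow as a batch library with a thin CLI.

## Input dialects and conversion

Two delimiter-separated dialects are supported, chosen to carry the same
information the platform exports carry (well, sample, assay, raw call):

* **SDS dialect** (one plate per file): `Well, Sample Name, Marker, Call`,
  where `Call` is a detector name for a homozygote, `Both` for a
  heterozygote, or `Undetermined`. Detector names are expected to follow the
  `<name>_<allele>` convention (`rs328_G`, `LPL-rs328_G`); the split is on
  the **last** underscore, because the name part is unconstrained and often
  contains underscores itself.
* **TYPER dialect** (many plates and multiplexed assays per file):
  `Plate, Well, Sample Id, Assay Id, Genotype`, where `Genotype` is an
  allele concatenation (`A`, `AG`) or empty for a no-call.

Conversion from token to genotype is mediated by a per-assay *conversion
map* that must be explicitly approved before use — the second of two
checkpoints mirroring wet-lab review practice (the first is the confirmation
of the list of non-study wells to drop). Non-conformant detector names
(`FAM-probe`) are never guessed at: they stay unmapped and force a manual
edit at approval time. One practically important assay class exercises this
path on purpose: a sex-marker assay in which one homozygote class never
occurs (males heterozygous, females homozygous) exposes only one conformant
detector, so the heterozygote token cannot be auto-inferred and requires a
one-line manual mapping.

Genotypes are canonical strings with alphabetically ordered alleles
(`"A/G"`), missing is `"0/0"`; both choices make the PED export an exact
textual transformation.

## ID classification and the call-rate denominator

A study is a manifest of sample IDs plus token sets for control wells
(default `NTC`, `PC`) and annulled samples (default `ER`). Classification is
exact-string by default (case folding and prefix matching, for labs that
number their controls `NTC1`, `NTC2`, are opt-in switches) and tested in the
order annulled → control → manifest → unknown, so a token collision is
resolved toward the more specific exclusion.

Two accounting rules keep the statistics honest:

* manifest samples present on **no** plate file still occupy a row of the
  genotype matrix and count in the call-rate denominator — otherwise a
  forgotten well silently inflates the call rate;
* every well is either retained or on the removal list; nothing is dropped
  implicitly.

## Replicates

Replicates are detected automatically as sample IDs occupying more than one
well; no naming convention is required. A group's status is `single`,
`concordant` (≥ 2 usable calls, all equal), `discordant` (≥ 2 usable calls,
not all equal) or `unresolved` (≥ 2 wells, < 2 usable calls). The reported
counts are group-based: *expected* counts groups with ≥ 2 wells, *real*
counts groups that produced ≥ 2 usable calls, and a triplicate with one
deviant call is **one** discordant replicate. A discordant group resolves to
the missing genotype: the conservative rule never fabricates a genotype from
a disagreement. Majority vote is available behind a flag (off by default)
for labs that prefer it; ties still resolve to missing.

## The QC statistics

All per-SNP statistics are computed over unique samples (one matrix row per
manifest ID), not wells. Undefined values are `NA` and export as the literal
`"NA"`, never 0 or blank — an undefined discordance rate (no real
replicates) is not a zero discordance rate.

The HWE test is the Pearson chi-square of observed genotype counts against
expectations \(n\hat p^2, 2n\hat p\hat q, n\hat q^2\) at the estimated
allele frequency, 1 df, no continuity correction (Yates is a flag; an exact
test is an explicit extension point). The chi-square was chosen as the
field-standard test of this workflow's era and matches the Pearson test used
for the population comparison. Degenerate inputs are defined, not errors: a
monomorphic SNP reports chi-square 0 with an undefined p (nothing to test),
an all-missing column reports an undefined test.

## Reference-population comparison

Observed counts are compared against per-population genotype counts from a
local TSV table (columns `snp_id, population, source, allele_a, allele_b,
n_AA, n_AB, n_BB`; `source` ∈ HAPMAP, KG). A local table replaces live
lookup services deliberately: the original web services of that generation
are dead, and caching reference counts locally is what a production tool did
anyway. Population labels are free text, so any panel — classic HapMap
populations or 1000-Genomes super-populations — is just rows. Lookups fall
back to a per-SNP alternate rs-number, covering SNPs whose identifier
changed between dbSNP releases.

Before testing, allele labels are harmonized: `direct`, `allele_swapped`
(reference counts re-ordered), `strand_flipped` (reverse complement),
`ambiguous` (palindromic A/T and C/G SNPs, where flip and swap are
indistinguishable — the comparison proceeds as direct with a warning flag),
or `incompatible` (no test). The test itself is the Pearson chi-square on
the 2×3 genotype table (genotype-level rather than allele-level, matching
what reference panels report as absolute genotype numbers; an allele-level
2×2 variant is a natural option). Columns with zero total are dropped and
the df reduced, which keeps the statistic defined for SNPs monomorphic in
one source without inventing a pooling rule; expected cells below 5 attach a
small-count flag rather than suppressing the test.

## Sex-marker concordance

A SNP on a gene present on both X and Y (amelogenin, GYG2, ZFX/ZFY)
separates the sexes by genotype. Because marker panels differ, the
genotype→sex assignment is always user-supplied, as is the phenotype file's
sex coding (a pure renaming layer: the report is invariant under relabeling
of the tokens). Samples are reported discordant only when both sexes are
known and disagree; unknown genotypic sex and missing phenotypes are counted
separately and the four categories always sum to the manifest size. Only
discordance records are ever persisted in the project store — full
phenotype lists never sit next to genotype data, by structural design rather
than policy.

## Project store and atomic imports

The store is a plain directory (JSON metadata, TSV call tables) rather than
a relational database: the artifact is a single-user batch tool, and a
directory is zero-install, diff-able and trivially backed up. An import
computes everything — both checkpoints, conversion, replicate resolution,
QC — before the first file is written, so a refusal or error leaves the
store untouched. Re-importing an existing result name is a collision error;
`overwrite` replaces, `append` merges the new calls into the stored result
and recomputes its QC, which is how a large study split across several
uploads converges to the same statistics as a single upload (verified at
20,000 samples in the test suite).

## The synthetic-data generator

`generate_truth()` draws a truth genotype matrix under Hardy-Weinberg
(p², 2pq, q²) — or, for HWE-violating fixtures, an inbreeding-style
heterozygote deficit with coefficient F — lays samples row-major onto
384-well plates with a configurable duplicate fraction, and assigns a truth
sex per sample; sex-marker SNPs derive their genotypes from sex truth
(males heterozygous) rather than from a frequency. `inject_defects()` then
plants exactly-known defects and records them in a ledger: discordant
duplicate calls, blanked no-call wells, extra wells with IDs outside the
manifest (mislabeled wells are added rather than relabeled in place, so an
unknown-ID well never doubles as a spuriously missing sample), samples
removed from all plates, and flipped sex-phenotype entries. Every stochastic
stage seeds its own RNG sub-stream, so changing one defect count does not
shift any other draw. `write_fixture()` serializes the result in either
dialect together with manifest, reference table (binomial HWE population
model around each SNP's truth frequency) and sex phenotype file.

What the generator does *not* emulate — and what passing tests therefore do
not show — includes cluster-plot artifacts and intensity-dependent no-call
structure, plate-edge and batch effects, contamination producing excess
heterozygosity, and vendor formatting quirks beyond the two documented
dialects. The fixtures validate the bookkeeping and the statistics exactly;
they do not validate instrument physics.

## Numerical and interface choices

* Well addresses accept zero-padded columns (`A01`) and canonicalize to
  unpadded form; the valid universe is exactly the 16×24 layout.
* Conversion-map lookups use positional name matching throughout, because R's
  named-vector indexing never matches an empty-string name and the TYPER
  no-call token is legitimately `""`.
* Sample-ID matching strips surrounding whitespace but is case-sensitive by
  default; silent case folding can merge distinct IDs.
* MAF ties at 0.5 report the alphabetically first allele as minor,
  deterministically.
* Exports are CSV (RFC-4180 quoting) with all statistic cells written as
  text; an XLSX writer is an extension point, and requesting it raises an
  informative error rather than a silent fallback.
* Default highlight thresholds: HWE p < 0.05, call rate < 0.95, discordance
  rate > 0 — the first is the conventional screening level, the others
  ordinary lab practice; all are user-overridable, and rules never fire on
  undefined values.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` exercise: exhaustive HWE oracle
agreement over all genotype triples with n ≤ 30; HWE type-I error on 2,000
simulated studies of n = 500 at MAF 0.3 (rejection rate expected within
[0.03, 0.07] of the nominal 0.05); defect recovery on a 200-sample study
with 3 discordant pairs, 5 no-calls, 2 unknown-ID wells and 1 absent sample;
exhaustive 2×3 contingency oracle agreement over all tables with cells ≤ 6;
sex concordance on 100 samples with 2 injected mismatches; and merge
invariance on a 20,000-sample, 55-plate study imported once versus in four
parts. These sizes were chosen to make each property exact (exhaustive where
the space is enumerable, seeded simulation where it is not) while keeping
the whole suite interactive.

## Known limitations

* Only the two documented text dialects parse; binary vendor files,
  cluster plots and raw intensities are out of scope, as are Illumina
  array formats.
* No Mendelian-inheritance or pedigree checks; no association testing or
  imputation.
* Call rate is defined over unique samples, not wells; a well-level rate
  would differ for heavily replicated designs.
* The store has no locking; concurrent writers are out of contract.
* Live reference-frequency retrieval is out of scope by design; the TSV
  table is the interchange format.
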