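# plateqc

Quality control of plate-based SNP genotyping data.

Targeted SNP genotyping on 384-well plates — endpoint allelic discrimination
(TaqMan/KASPar on RT-PCR instruments) and multiplexed single-base-extension
mass-array assays (iPLEX) — produces one result file per plate in a
vendor-specific dialect. Before those genotypes can be analyzed, someone has
to merge plate files, map raw call tokens to genotypes, find and reconcile
replicated samples, compute per-SNP quality metrics, and sanity-check allele
frequencies against reference populations. Done by hand in spreadsheets,
every one of those steps is a known source of silent data corruption.

`plateqc` is a batch R implementation of that workflow for wet-lab genotyping
groups and genetic-epidemiology analysts. It parses and merges plate exports
in the two supported dialects, validates sample IDs against a study manifest
with two explicit confirmation checkpoints (well removal, genotype
conversion), resolves replicates conservatively, computes the standard QC
panel per SNP, and exports merged genotype lists, QC reports and PLINK
PED/MAP files from a file-backed project store.

## Statistics

For a biallelic SNP with genotype counts \(n_{AA}, n_{AB}, n_{BB}\) over the
full study manifest (samples absent from every plate file count as missing),
with \(n = n_{AA}+n_{AB}+n_{BB}\):

* **call rate** \(= n / (n + n_{missing})\);
* **MAF**: \(\hat p = (2 n_{AA} + n_{AB}) / 2n\), MAF \(= \min(\hat p, 1-\hat p)\);
* **replicates**: *expected* = sample IDs plated on ≥ 2 wells, *real* = those
  with ≥ 2 usable calls, *discordant* = those whose usable calls disagree;
  discordance rate = discordant / real. A discordant replicate resolves to a
  missing genotype, never a guess;
* **HWE test**: Pearson chi-square of \((n_{AA}, n_{AB}, n_{BB})\) against
  \((n\hat p^2,\ 2n\hat p\hat q,\ n\hat q^2)\), 1 df, no continuity
  correction (Yates optional); monomorphic SNPs report an undefined p;
* **reference-population comparison**: Pearson chi-square on the 2×3
  user-vs-reference genotype contingency table after allele harmonization
  (swap / strand flip detection, palindromic A/T and C/G SNPs flagged
  ambiguous), zero-total columns dropped with matching df reduction.

## Worked example

The package ships a tiny synthetic demo: one SDS-dialect plate of an *LPL*
SNP (rs328) typed on 10 wells plus a duplicate and a water control, an
11-sample manifest, and a synthetic reference-population count table.

```r
library(plateqc)
plate    <- system.file("extdata", "demo_plate.csv", package = "plateqc")
manifest <- system.file("extdata", "demo_manifest.txt", package = "plateqc")

study  <- create_study("demo", manifest, expected_replicate_count = 1)
plates <- read_plates(plate)

propose_removals(plates, study)     # checkpoint 1: what gets dropped?
#>   sample_id plate_name well   klass
#> 1       NTC demo_plate  A10 control
missing_samples(study, plates)      # manifest sample on no plate
#> [1] "S011"

map <- approve_conversion(infer_conversion_map(plates, "rs328"))  # checkpoint 2
cs  <- apply_conversion(plates, study, map)
mat <- build_genotype_matrix(study, list(cs))
report <- build_qc_report("rs328", mat[, "rs328"], collect_replicates(cs),
                          alleles = c("C", "G"), operator = "demo")
report
#> <qc_report> rs328 (2026-09-30, operator: demo)
#>   call rate:        0.8182
#>   replicates:       1 expected, 1 real, 0 discordant (rate 0)
#>   MAF:              0.2778 (C)
#>   HWE:              chi2 0.2578, p 0.6117
```

9 of 11 manifest samples produced a genotype (one well was a no-call, S011
was never plated), hence the 0.818 call rate; the duplicate of S002 agreed
with itself, so the one detected replicate is concordant; the data are
compatible with Hardy-Weinberg equilibrium. Plausibility against a reference
population:

```r
ref <- load_reference_table(system.file("extdata", "demo_reference_table.tsv",
                                        package = "plateqc"))
compare_all("rs328", report$counts, ref)[[1]]
#> <population_comparison> CEU [HAPMAP] (ambiguous): chi2 = 3.663, df = 2,
#>   p = 0.1602 [small expected counts]
```

The `ambiguous` flag warns that rs328 is a C/G (palindromic) SNP, where a
strand flip cannot be told from an allele swap; the small-count flag warns
that expected cells fall below 5 at this toy sample size.

The same workflow runs non-interactively from a shell through
`exec/plateqc` (`init-study`, `import`, `qc`, `compare`, `sex-check`,
`export`, `list`, `search`, `delete`, `deactivate`), with `--auto-approve`
standing in for the two interactive checkpoints.

## Layout

* `R/` — parsing (`plate-io.R`), study/ID handling (`study.R`), conversion
  and replicates (`genotype.R`), QC statistics (`qc-stats.R`),
  reference-population comparison (`pop-compare.R`), sex concordance
  (`sex-check.R`), exports (`report-export.R`), synthetic fixtures
  (`fixtures.R`), project store and import orchestration (`pipeline.R`,
  `cli.R`).
* `vignettes/plateqc-methods.Rmd` — models, conventions, design decisions
  and limitations.
* `tests/testthat/` — unit, property and whole-pipeline tests.
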