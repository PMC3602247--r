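Package: plateqc
Title: Quality Control of Plate-Based SNP Genotyping Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch workflow for processing SNP genotyping results exported
    from 384-well plate platforms: parses and merges plate result files in an
    allelic-discrimination (SDS-like) dialect and a mass-spectrometry plate
    (TyperAnalyzer-like) dialect, validates sample identifiers against a study
    manifest, converts raw call tokens to normalized genotypes through
    user-approved conversion maps, detects replicates and resolves
    discordances, computes per-SNP quality control statistics (call rate,
    replicate concordance, minor allele frequency, Hardy-Weinberg equilibrium
    chi-square test), compares observed genotype counts against reference
    population tables by Pearson chi-square with allele harmonization, checks
    sex-marker concordance, and exports merged genotype lists, QC reports and
    PLINK PED/MAP files. Includes a synthetic-fixture generator so the whole
    pipeline is testable from a known truth genotype matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    zip
Config/testthat/edition: 3
RoxygenNote: 7.3.3
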