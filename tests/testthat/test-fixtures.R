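test_that("truth generation is deterministic and honors the replicate fraction", {
  spec <- list(truth_snp("rs1", c("A", "G"), maf = 0.3))
  a <- generate_truth(100, spec, replicate_fraction = 0.1, seed = 42)
  b <- generate_truth(100, spec, replicate_fraction = 0.1, seed = 42)
  expect_identical(a$truth, b$truth)
  expect_identical(a$wells, b$wells)
  expect_length(a$replicated, 10L)
  expect_equal(nrow(a$wells), 110L)
  c_ <- generate_truth(100, spec, replicate_fraction = 0.1, seed = 43)
  expect_false(identical(a$truth, c_$truth))
})

test_that("sample allele frequency concentrates around the truth MAF", {
  t1 <- generate_truth(500, list(truth_snp("rs1", c("A", "G"), maf = 0.3)), 0, seed = 42)
  cts <- genotype_counts(t1$truth[, "rs1"], alleles = c("A", "G"))
  maf <- minor_allele_freq(cts)$maf
  tol <- 3 * sqrt(0.3 * 0.7 / (2 * 500))
  expect_lt(abs(maf - 0.3), tol)
})

test_that("wells overflow onto additional plates at capacity", {
  t1 <- generate_truth(380, list(truth_snp("rs1")), replicate_fraction = 0.1, seed = 1)
  expect_equal(length(unique(t1$wells$plate_name)), 2L)  # 418 wells / 384
  expect_equal(t1$wells$well[1], "A1")
  expect_equal(t1$wells$well[385], "A1")
  expect_equal(t1$wells$well[384], "P24")
})

test_that("defect injection records exact indices and is identity at zero", {
  spec <- list(truth_snp("rs1", c("A", "G"), maf = 0.3))
  t0 <- generate_truth(200, spec, replicate_fraction = 0.1, seed = 5)
  same <- inject_defects(t0)
  expect_identical(same$well_gt, t0$well_gt)
  expect_identical(same$wells, t0$wells)

  t1 <- inject_defects(t0, k_discordant = 2, k_nocall = 4, k_unknown_ids = 3,
                       k_absent = 1)
  expect_length(t1$defects$discordant, 2L)
  expect_length(t1$defects$nocall, 4L)
  expect_length(t1$defects$unknown_ids, 3L)
  expect_length(t1$defects$absent, 1L)
  # absent sample appears in the manifest but on no plate
  expect_true(t1$defects$absent %in% t1$manifest)
  expect_false(t1$defects$absent %in% t1$wells$sample_id)
  # no-call wells are blanked
  expect_true(all(t1$well_gt[t1$defects$nocall, ] == "0/0"))
  # unknown-ID wells carry IDs outside the manifest
  expect_false(any(t1$wells$sample_id[t1$defects$unknown_ids] %in% t1$manifest))
})

test_that("written fixtures parse back to the truth record-for-record", {
  spec <- list(truth_snp("rs1", c("A", "G"), maf = 0.3),
               truth_snp("rs2", c("C", "T"), maf = 0.2))
  truth <- inject_defects(
    generate_truth(60, spec, replicate_fraction = 0.1, seed = 9),
    k_nocall = 2)

  for (dialect in c("SDS", "TYPER")) {
    fx <- write_fixture(truth, withr::local_tempdir(), dialect)
    plates <- read_plates(fx$plates)
    assays <- unique(unlist(lapply(plates, function(p) p$calls$assay_id)))
    expect_setequal(assays, truth$snp_ids)
    for (j in seq_along(truth$snp_ids)) {
      snp <- truth$snp_ids[j]
      map <- approve_conversion(infer_conversion_map(plates, snp))
      study <- create_study("fx", truth$manifest)
      cs <- apply_conversion(plates, study, map,
                             removals = propose_removals(plates, study)[0, ])
      # order wells as in the truth plan and compare genotypes verbatim
      key_truth <- paste(truth$wells$sample_id, truth$wells$well)
      key_got <- paste(cs$calls$sample_id, cs$calls$well)
      expect_setequal(key_got, key_truth)
      got_gt <- cs$calls$genotype[match(key_truth, key_got)]
      expect_equal(got_gt, unname(truth$well_gt[, j]))
    }
  }
})

test_that("the full pipeline recovers truth genotypes and defect counts", {
  spec <- list(truth_snp("rs1", c("A", "G"), maf = 0.3))
  truth <- inject_defects(
    generate_truth(120, spec, replicate_fraction = 0.15, seed = 13),
    k_discordant = 2, k_nocall = 3, k_unknown_ids = 2, k_absent = 1)
  fx <- write_fixture(truth, withr::local_tempdir(), "SDS")
  study <- create_study("fx", fx$manifest)
  plates <- read_plates(fx$plates)

  expect_setequal(missing_samples(study, plates), truth$defects$absent)
  rem <- propose_removals(plates, study)
  expect_equal(sum(rem$klass == "unknown"), 2L)

  map <- approve_conversion(infer_conversion_map(plates, "rs1"))
  cs <- apply_conversion(plates, study, map, removals = rem)
  groups <- collect_replicates(cs)
  expect_equal(sum(groups$status == "discordant"), 2L)
  expect_setequal(groups$sample_id[groups$status == "discordant"],
                  truth$defects$discordant)

  mat <- build_genotype_matrix(study, list(cs))
  # non-defective samples recover their truth genotype exactly
  defective <- unique(c(truth$defects$discordant, truth$defects$absent,
                        truth$wells$sample_id[truth$defects$nocall],
                        truth$manifest[!truth$manifest %in% truth$wells$sample_id]))
  clean <- setdiff(truth$manifest, defective)
  expect_equal(mat[clean, "rs1"], truth$truth[clean, "rs1"])
  # discordant groups resolve to missing
  expect_true(all(mat[truth$defects$discordant, "rs1"] == "0/0"))
})

test_that("heterozygote-deficit draws violate HWE detectably", {
  spec <- list(truth_snp("rs1", c("A", "G"), maf = 0.3, hwe = FALSE, f = 0.5))
  t1 <- generate_truth(800, spec, 0, seed = 3)
  cts <- genotype_counts(t1$truth[, "rs1"], alleles = c("A", "G"))
  h <- hwe_chisq(cts)
  expect_lt(h$p, 0.001)
})
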