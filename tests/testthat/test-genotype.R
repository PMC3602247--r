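test_that("genotype normalization sorts alleles, handles missing, is idempotent", {
  expect_equal(normalize_genotype(c("GA", "AA", "AG", "a", "")),
               c("A/G", "A/A", "A/G", "A/A", "0/0"))
  expect_equal(normalize_genotype(c("0/0", NA, "G/A")), c("0/0", "0/0", "A/G"))
  expect_error(normalize_genotype("AN"), class = "plateqc_invalid_allele")
  # idempotence over all unordered pairs
  pairs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  once <- normalize_genotype(pairs)
  expect_equal(normalize_genotype(once), once)
})

test_that("conversion maps are inferred per dialect", {
  sds <- read_sds_export(sds_lines(list(
    c("A1", "S1", "rs328", "rs328_C"), c("A2", "S2", "rs328", "rs328_G"),
    c("A3", "S3", "rs328", "Both"), c("A4", "S4", "rs328", "Undetermined"))), "P")
  m <- infer_conversion_map(sds, "rs328")
  expect_false(m$approved)
  expect_equal(m$mapping[c("rs328_C", "rs328_G", "Both", "Undetermined")],
               c(rs328_C = "C/C", rs328_G = "G/G", Both = "C/G",
                 Undetermined = "0/0"))

  typ <- read_typer_export(typer_lines(list(
    c("P1", "A1", "S1", "rs1", "A"), c("P1", "A2", "S2", "rs1", "AG"),
    c("P1", "A3", "S3", "rs1", "G"), c("P1", "A4", "S4", "rs1", ""))))
  mt <- infer_conversion_map(typ, "rs1")
  expect_equal(sort(unname(mt$mapping)), sort(c("A/A", "A/G", "G/G", "0/0")))

  # non-conformant SDS detectors stay unmapped and block approval
  fam <- read_sds_export(sds_lines(list(
    c("A1", "S1", "rs1", "probeFAM"), c("A2", "S2", "rs1", "probeVIC"))), "P")
  mf <- infer_conversion_map(fam, "rs1")
  expect_true(all(is.na(mf$mapping)))
  expect_error(approve_conversion(mf), class = "plateqc_incomplete_map")

  # three conformant detectors on one assay is ambiguous
  amb <- read_sds_export(sds_lines(list(
    c("A1", "S1", "rs1", "rs1_A"), c("A2", "S2", "rs1", "rs1_G"),
    c("A3", "S3", "rs1", "rs1_T"))), "P")
  expect_error(infer_conversion_map(amb, "rs1"), class = "plateqc_ambiguous_assay")
})

test_that("approval applies edits and gates conversion", {
  sds <- read_sds_export(sds_lines(list(
    c("A1", "S1", "rs1", "rs1_A"), c("A2", "S2", "rs1", "rs1_G"),
    c("A3", "S3", "rs1", "Both"))), "P")
  m <- infer_conversion_map(sds, "rs1")
  ok <- approve_conversion(m)
  expect_true(ok$approved)
  # a user edit at the checkpoint has authority over the suggestion
  edited <- approve_conversion(m, edits = c(Both = "0/0"))
  expect_equal(unname(edited$mapping["Both"]), "0/0")

  study <- create_study("st", c("S1", "S2", "S3"))
  expect_error(apply_conversion(sds, study, m), class = "plateqc_checkpoint")

  cs <- apply_conversion(sds, study, ok)
  expect_equal(nrow(cs$calls), 3L)
  expect_equal(cs$calls$genotype, c("A/A", "G/G", "A/G"))
  expect_equal(cs$calls$well, c("A1", "A2", "A3"))

  # a token not seen at inference time is a stale-map error
  changed <- read_sds_export(sds_lines(list(c("A1", "S1", "rs1", "rs1_T"))), "P")
  expect_error(apply_conversion(changed, study, ok), class = "plateqc_stale_map")
})

test_that("conversion preserves cardinality and keeps no-calls present", {
  study <- create_study("st", sprintf("S%02d", 1:20))
  rows <- lapply(1:20, function(i) {
    tok <- if (i == 5) "Undetermined" else "Both"
    c(paste0("A", ((i - 1) %% 24) + 1), sprintf("S%02d", i), "rs1", tok)
  })
  rows[[21]] <- c("B1", "NTC", "rs1", "Undetermined")
  pr <- read_sds_export(sds_lines(c(rows,
    list(c("B2", "S01", "rs1", "rs1_A"), c("B3", "S02", "rs1", "rs1_G")))), "P")
  m <- approve_conversion(infer_conversion_map(pr, "rs1"))
  cs <- apply_conversion(pr, study, m)
  # 22 retained wells (23 rows minus the NTC well)
  expect_equal(nrow(cs$calls), 22L)
  expect_true("0/0" %in% cs$calls$genotype)
  expect_false("NTC" %in% cs$calls$sample_id)
})

test_that("replicate groups partition samples and statuses follow the definitions", {
  calls <- data.frame(
    sample_id = c("S1", "S1", "S2", "S2", "S3", "S3", "S4", "S5", "S5", "S5"),
    plate_name = "P", well = paste0("A", 1:10),
    genotype = c("A/G", "A/G",      # concordant pair
                 "A/G", "G/G",      # discordant pair
                 "A/G", "0/0",      # unresolved: one usable call only
                 "A/A",             # single
                 "A/G", "A/G", "G/G"),  # triplicate with one deviant
    stringsAsFactors = FALSE)
  cs <- plateqc:::new_snp_callset("rs1", "rs1", calls)
  g <- collect_replicates(cs)
  expect_equal(stats::setNames(g$status, g$sample_id),
               c(S1 = "concordant", S2 = "discordant", S3 = "unresolved",
                 S4 = "single", S5 = "discordant"))
  # statuses partition the distinct sample IDs
  expect_equal(nrow(g), length(unique(calls$sample_id)))
  expect_equal(stats::setNames(g$resolved, g$sample_id),
               c(S1 = "A/G", S2 = "0/0", S3 = "A/G", S4 = "A/A", S5 = "0/0"))
  # majority vote is opt-in and resolves the triplicate
  g2 <- collect_replicates(cs, majority_vote = TRUE)
  expect_equal(g2$resolved[g2$sample_id == "S5"], "A/G")
  expect_equal(g2$resolved[g2$sample_id == "S2"], "0/0")  # tie stays missing
})

test_that("resolution rules are conservative", {
  expect_equal(resolve_replicates(c("A/G", "A/G")), "A/G")
  expect_equal(resolve_replicates(c("A/G", "G/G")), "0/0")
  expect_equal(resolve_replicates(c("0/0", "0/0")), "0/0")
  expect_equal(resolve_replicates(c("A/G", "0/0")), "A/G")
  expect_equal(resolve_replicates("A/A"), "A/A")
})

test_that("the genotype matrix always spans the full manifest", {
  study <- create_study("st", sprintf("S%02d", 1:10))
  calls <- data.frame(sample_id = sprintf("S%02d", 1:8), plate_name = "P",
                      well = paste0("A", 1:8),
                      genotype = rep(c("A/A", "A/G"), 4),
                      stringsAsFactors = FALSE)
  cs <- plateqc:::new_snp_callset("rs1", "rs1", calls)
  mat <- build_genotype_matrix(study, list(cs))
  expect_equal(dim(mat), c(10L, 1L))
  expect_equal(rownames(mat), study$sample_ids)
  expect_equal(sum(mat == "0/0"), 2L)   # S09, S10 absent -> missing

  # empty callset list: zero columns, full row set
  m0 <- build_genotype_matrix(study, list())
  expect_equal(dim(m0), c(10L, 0L))

  cs2 <- plateqc:::new_snp_callset("rs1", "rs1", calls)
  expect_error(build_genotype_matrix(study, list(cs, cs2)),
               class = "plateqc_name_collision")
})
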