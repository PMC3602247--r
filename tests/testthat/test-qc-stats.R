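test_that("genotype counting orders alleles and rejects multi-allelic columns", {
  col <- c(rep("A/A", 25), rep("A/G", 50), rep("G/G", 25))
  cts <- genotype_counts(col)
  expect_equal(c(cts$n_AA, cts$n_AB, cts$n_BB, cts$n_missing), c(25, 50, 25, 0))
  expect_equal(c(cts$allele1, cts$allele2), c("A", "G"))

  all_missing <- genotype_counts(rep("0/0", 10), alleles = c("A", "G"))
  expect_equal(c(all_missing$n_AA, all_missing$n_AB, all_missing$n_BB), c(0, 0, 0))
  expect_equal(all_missing$n_missing, 10L)

  expect_error(genotype_counts(c("A/A", "C/G")), class = "plateqc_multi_allelic")
})

test_that("call rate counts absent manifest samples in the denominator", {
  expect_equal(call_rate(as_genotype_counts(25, 50, 25)), 1.0)
  # 8 called of a manifest of 10: one sample absent from the files, one no-call
  expect_equal(call_rate(as_genotype_counts(3, 3, 2, n_missing = 2)), 0.8)
  expect_equal(call_rate(as_genotype_counts(0, 0, 0, n_missing = 10)), 0.0)
  expect_true(is.na(call_rate(as_genotype_counts(0, 0, 0, n_missing = 0))))
})

test_that("minor allele frequency and tie-breaking", {
  m <- minor_allele_freq(as_genotype_counts(25, 50, 25, allele1 = "A", allele2 = "G"))
  expect_equal(m$maf, 0.5)
  expect_equal(m$minor_allele, "A")     # tie -> alphabetically first
  expect_equal(minor_allele_freq(as_genotype_counts(0, 10, 90))$maf, 10 / 200)
  m2 <- minor_allele_freq(as_genotype_counts(0, 0, 50, allele1 = "C", allele2 = "T"))
  expect_equal(m2$maf, 0.0)
  expect_equal(m2$minor_allele, "C")    # monomorphic: absent allele is minor
  expect_true(is.na(minor_allele_freq(as_genotype_counts(0, 0, 0))$maf))
})

test_that("replicate summary distinguishes expected, real and discordant", {
  # three duplicated samples: one pair with a missing call, one discordant
  calls <- data.frame(
    sample_id = c("S1", "S1", "S2", "S2", "S3", "S3"),
    plate_name = "P", well = paste0("A", 1:6),
    genotype = c("A/G", "0/0", "A/G", "G/G", "A/A", "A/A"),
    stringsAsFactors = FALSE)
  g <- collect_replicates(plateqc:::new_snp_callset("rs1", "rs1", calls))
  rs <- replicate_summary(g)
  expect_equal(rs$expected, 3L)
  expect_equal(rs$real, 2L)
  expect_equal(rs$discordant, 1L)
  expect_equal(rs$discordance_rate, 0.5)

  no_reps <- collect_replicates(plateqc:::new_snp_callset("rs1", "rs1",
    data.frame(sample_id = c("S1", "S2"), plate_name = "P", well = c("A1", "A2"),
               genotype = c("A/A", "A/G"), stringsAsFactors = FALSE)))
  rs0 <- replicate_summary(no_reps)
  expect_equal(c(rs0$expected, rs0$real, rs0$discordant), c(0L, 0L, 0L))
  expect_true(is.na(rs0$discordance_rate))

  # declared/detected mismatch warns, never errors
  study <- create_study("st", c("S1", "S2", "S3"), expected_replicate_count = 5)
  expect_warning(replicate_summary(g, study), class = "plateqc_replicate_mismatch")
})

test_that("HWE chi-square matches hand-computed values and handles degeneracy", {
  h <- hwe_chisq(as_genotype_counts(25, 50, 25))
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)
  h2 <- hwe_chisq(as_genotype_counts(30, 40, 30))
  expect_equal(h2$chi2, 4.0)
  expect_equal(h2$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)

  mono <- hwe_chisq(as_genotype_counts(50, 0, 0))
  expect_equal(mono$chi2, 0)
  expect_true(is.na(mono$p))
  expect_true(is.na(hwe_chisq(as_genotype_counts(0, 0, 0))$chi2))
})

test_that("HWE agrees with the allele-count oracle over random triples", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    split <- stats::rmultinom(1, n, prob = c(runif(1), runif(1), runif(1)))
    got <- hwe_chisq(as_genotype_counts(split[1], split[2], split[3]))
    want <- oracle_hwe(split[1], split[2], split[3])
    expect_equal(got$chi2, want$chi2, tolerance = 1e-9)
    if (!is.na(want$p)) expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

test_that("call rate and MAF are invariant under sample reordering", {
  set.seed(3)
  col <- sample(c("A/A", "A/G", "G/G", "0/0"), 60, replace = TRUE)
  a <- genotype_counts(col, alleles = c("A", "G"))
  b <- genotype_counts(sample(col), alleles = c("A", "G"))
  expect_equal(call_rate(a), call_rate(b))
  expect_equal(minor_allele_freq(a), minor_allele_freq(b))
})

test_that("the assembled QC report carries all statistics and metadata", {
  set.seed(5)
  col <- stats::setNames(sample(c("A/A", "A/G", "G/G"), 50, replace = TRUE,
                                prob = c(0.49, 0.42, 0.09)),
                         sprintf("S%02d", 1:50))
  calls <- data.frame(sample_id = names(col), plate_name = "P",
                      well = paste0(rep(LETTERS[1:3], each = 24)[1:50], rep(1:24, 3)[1:50]),
                      genotype = unname(col), stringsAsFactors = FALSE)
  g <- collect_replicates(plateqc:::new_snp_callset("rs1", "rs1", calls))
  rep1 <- build_qc_report("rs1", col, g, operator = "tester", comment = "run 1")
  expect_s3_class(rep1, "qc_report")
  expect_equal(rep1$call_rate, 1.0)
  expect_equal(rep1$operator, "tester")
  df <- as.data.frame(rep1)
  expect_equal(nrow(df), 1L)
  expect_true(all(c("call_rate", "maf", "hwe_p", "discordance_rate") %in% names(df)))

  mono <- build_qc_report("rs2", rep("C/C", 10), g[0, ], alleles = c("C", "T"))
  expect_equal(mono$maf, 0)
  expect_true(is.na(mono$hwe_p))
  expect_true(is.na(mono$discordance_rate))
})
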