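test_that("reference tables validate structure, keys and counts", {
  tab <- load_reference_table(ref_table_lines(list(
    c("rs328", "CEU", "HAPMAP", "C", "G", 10, 40, 50),
    c("rs328", "YRI", "HAPMAP", "C", "G", 30, 50, 20),
    c("rs328", "EUR", "KG", "C", "G", 12, 45, 43))))
  expect_s3_class(tab, "ref_table")
  expect_equal(nrow(tab), 3L)

  expect_error(load_reference_table(ref_table_lines(list(
    c("rs328", "CEU", "HAPMAP", "C", "G", 10, 40, 50),
    c("rs328", "CEU", "HAPMAP", "C", "G", 1, 2, 3)))),
    class = "plateqc_duplicate_key")
  expect_error(load_reference_table(ref_table_lines(list(
    c("rs328", "CEU", "HAPMAP", "C", "G", 10, -1, 50)))),
    class = "plateqc_validation")
  expect_error(load_reference_table("snp_id\tpopulation\nrs1\tCEU"),
               class = "plateqc_format")
})

test_that("allele harmonization covers swap, strand flip, palindromes", {
  expect_equal(harmonize_alleles(c("A", "G"), c("A", "G"))$outcome, "direct")
  sw <- harmonize_alleles(c("A", "G"), c("G", "A"))
  expect_equal(sw$outcome, "allele_swapped")
  expect_equal(sw$ref_order, c(3L, 2L, 1L))
  # {A,G} vs {C,T}: reverse complement maps A->T, G->C
  fl <- harmonize_alleles(c("A", "G"), c("C", "T"))
  expect_equal(fl$outcome, "strand_flipped")
  expect_equal(harmonize_alleles(c("A", "T"), c("A", "T"))$outcome, "ambiguous")
  expect_equal(harmonize_alleles(c("C", "G"), c("C", "G"))$outcome, "ambiguous")
  expect_equal(harmonize_alleles(c("A", "G"), c("A", "C"))$outcome, "incompatible")

  # harmonizing the already-harmonized pair is a fixed point
  u <- c("A", "G"); r <- c("T", "C")
  h <- harmonize_alleles(u, r)
  expect_equal(h$outcome, "strand_flipped")
  expect_equal(harmonize_alleles(u, u)$outcome, "direct")
})

test_that("the population chi-square matches identity, symmetry, proportionality", {
  same <- compare_population(as_genotype_counts(25, 50, 25),
                             as_genotype_counts(25, 50, 25))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_equal(same$df, 2L)

  a <- as_genotype_counts(40, 40, 20); b <- as_genotype_counts(20, 40, 40)
  ab <- compare_population(a, b); ba <- compare_population(b, a)
  expect_equal(ab$chi2, ba$chi2)
  expect_equal(ab$p, ba$p)
  want <- oracle_chisq_2x3(c(40, 40, 20), c(20, 40, 40))
  expect_equal(ab$chi2, want$chi2, tolerance = 1e-12)

  # proportional rows: chi2 0, p 1, over randomized scalar multiples
  set.seed(9)
  for (i in 1:25) {
    base <- sample(0:8, 3, replace = TRUE)
    if (sum(base) == 0 || sum(base > 0) < 2) next
    k <- sample(1:5, 1)
    cmp <- compare_population(as_genotype_counts(base[1], base[2], base[3]),
                              as_genotype_counts(k * base[1], k * base[2], k * base[3]))
    expect_equal(cmp$chi2, 0, tolerance = 1e-12)
    expect_equal(cmp$p, 1)
  }

  # zero-total columns are dropped with df reduction
  drop1 <- compare_population(as_genotype_counts(10, 5, 0),
                              as_genotype_counts(12, 9, 0))
  expect_equal(drop1$df, 1L)
  undef <- compare_population(as_genotype_counts(10, 0, 0),
                              as_genotype_counts(12, 0, 0))
  expect_true(is.na(undef$p))
  expect_equal(undef$df, 0L)

  # small expected counts carry a warning flag
  expect_true(compare_population(as_genotype_counts(2, 1, 1),
                                 as_genotype_counts(1, 2, 1))$small_counts)
})

test_that("the population chi-square agrees with stats::chisq.test", {
  set.seed(21)
  for (i in 1:50) {
    u <- sample(1:30, 3, replace = TRUE)
    r <- sample(1:30, 3, replace = TRUE)
    cmp <- compare_population(as_genotype_counts(u[1], u[2], u[3]),
                              as_genotype_counts(r[1], r[2], r[3]))
    ref <- suppressWarnings(stats::chisq.test(rbind(u, r), correct = FALSE))
    expect_equal(cmp$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(cmp$p, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("compare_all looks up by primary then alternate id and harmonizes", {
  tab <- load_reference_table(ref_table_lines(list(
    c("rs328", "CEU", "HAPMAP", "A", "G", 10, 40, 50),
    c("rs328", "YRI", "HAPMAP", "G", "A", 30, 50, 20),   # swapped roles
    c("rs328", "EUR", "KG", "T", "C", 12, 45, 43),       # opposite strand
    c("rs999", "CEU", "HAPMAP", "A", "G", 5, 5, 5))))
  user <- as_genotype_counts(12, 41, 47, allele1 = "A", allele2 = "G")

  cmps <- compare_all("rs328", user, tab)
  expect_length(cmps, 3L)
  harm <- vapply(cmps, function(x) x$harmonization, character(1))
  expect_equal(sort(harm), sort(c("direct", "allele_swapped", "strand_flipped")))
  # the swapped population's counts were re-ordered before testing
  swapped <- cmps[[which(harm == "allele_swapped")]]
  expect_equal(c(swapped$ref_counts$n_AA, swapped$ref_counts$n_BB), c(20, 30))

  # absent SNP: empty with a notice; alternate id rescues the lookup
  none <- compare_all("rs000", user, tab)
  expect_length(none, 0L)
  expect_match(attr(none, "notice"), "not found")
  via_alt <- compare_all("rs000", user, tab, alt_id = "rs999")
  expect_length(via_alt, 1L)
  expect_equal(attr(via_alt, "lookup_id"), "rs999")

  # population filter restricts the output
  ceu_only <- compare_all("rs328", user, tab, populations = "CEU")
  expect_length(ceu_only, 1L)
  expect_equal(ceu_only[[1]]$population, "CEU")

  # incompatible pairs produce a flagged, untested row
  tab2 <- load_reference_table(ref_table_lines(list(
    c("rs328", "CEU", "HAPMAP", "A", "C", 10, 40, 50))))
  inc <- compare_all("rs328", user, tab2)
  expect_equal(inc[[1]]$harmonization, "incompatible")
  expect_true(is.na(inc[[1]]$p))
})
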