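# Per-SNP quality control statistics.
#
# All statistics are computed over unique study samples (one matrix row per
# manifest ID), with samples absent from every plate file counted in the
# call-rate denominator. Undefined statistics are NA, never 0, and export as
# the literal "NA".

#' Tally genotype counts for one SNP
#'
#' @param genotypes character vector of canonical genotypes, one per unique
#'   sample (a column of [build_genotype_matrix()]).
#' @param alleles optional length-2 character vector fixing the allele pair
#'   (from the conversion map); inferred from the data when omitted. Needed
#'   to label a monomorphic or all-missing column.
#' @return A `genotype_counts` object: `n_AA`, `n_AB`, `n_BB` (homozygote
#'   allele1, heterozygote, homozygote allele2; alleles in alphabetical
#'   order), `allele1`, `allele2`, `n_missing`.
#' @export
genotype_counts <- function(genotypes, alleles = NULL) {
  miss <- is_missing_gt(genotypes)
  obs <- genotype_alleles(genotypes[!miss])
  if (length(obs) > 2L) {
    pqc_stop("multi_allelic", "more than two alleles observed: %s",
             paste(obs, collapse = ", "))
  }
  if (is.null(alleles)) alleles <- obs
  alleles <- sort(unique(toupper(alleles)))
  if (length(setdiff(obs, alleles))) {
    pqc_stop("multi_allelic", "observed allele(s) %s outside declared pair %s",
             paste(setdiff(obs, alleles), collapse = ", "),
             paste(alleles, collapse = "/"))
  }
  if (length(alleles) == 0L) alleles <- c(NA_character_, NA_character_)
  if (length(alleles) == 1L) alleles <- c(alleles, NA_character_)
  gAA <- paste(alleles[1], alleles[1], sep = "/")
  gAB <- paste(alleles[1], alleles[2], sep = "/")
  gBB <- paste(alleles[2], alleles[2], sep = "/")
  structure(list(
    n_AA = sum(genotypes == gAA, na.rm = TRUE),
    n_AB = if (is.na(alleles[2])) 0L else sum(genotypes == gAB, na.rm = TRUE),
    n_BB = if (is.na(alleles[2])) 0L else sum(genotypes == gBB, na.rm = TRUE),
    allele1 = alleles[1], allele2 = alleles[2],
    n_missing = sum(miss)
  ), class = "genotype_counts")
}

#' Assemble a genotype_counts object from raw counts
#'
#' Convenience constructor for reference tables and tests.
#' @param n_AA,n_AB,n_BB non-negative counts.
#' @param allele1,allele2 the allele pair.
#' @param n_missing missing-sample count.
#' @export
as_genotype_counts <- function(n_AA, n_AB, n_BB, allele1 = "A", allele2 = "B",
                               n_missing = 0L) {
  if (any(c(n_AA, n_AB, n_BB, n_missing) < 0)) {
    pqc_stop("validation", "genotype counts must be non-negative")
  }
  structure(list(n_AA = as.integer(n_AA), n_AB = as.integer(n_AB),
                 n_BB = as.integer(n_BB), allele1 = allele1, allele2 = allele2,
                 n_missing = as.integer(n_missing)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> %s/%s: AA=%d AB=%d BB=%d missing=%d\n",
              x$allele1, x$allele2, x$n_AA, x$n_AB, x$n_BB, x$n_missing))
  invisible(x)
}

n_called <- function(counts) counts$n_AA + counts$n_AB + counts$n_BB

#' Call rate
#'
#' Fraction of attempted samples with a usable genotype:
#' called / (called + missing). The denominator spans the full manifest —
#' samples absent from the plate files count as missing. `NA` when the
#' denominator is 0.
#' @param counts a `genotype_counts`.
#' @export
call_rate <- function(counts) {
  n <- n_called(counts)
  denom <- n + counts$n_missing
  if (denom == 0L) return(NA_real_)
  n / denom
}

#' Minor allele frequency
#'
#' `freq(allele1) = (2 n_AA + n_AB) / (2 n)`; the MAF is the smaller of the
#' two allele frequencies. At a 0.5 tie the alphabetically first allele is
#' reported as minor.
#' @param counts a `genotype_counts`.
#' @return List with `maf` and `minor_allele` (both `NA` when no genotype was
#'   called).
#' @export
minor_allele_freq <- function(counts) {
  n <- n_called(counts)
  if (n == 0L) return(list(maf = NA_real_, minor_allele = NA_character_))
  p1 <- (2 * counts$n_AA + counts$n_AB) / (2 * n)
  if (p1 <= 0.5) {
    list(maf = p1, minor_allele = counts$allele1)
  } else {
    list(maf = 1 - p1, minor_allele = counts$allele2 %||% NA_character_)
  }
}

#' Replicate summary statistics
#'
#' `expected` is the number of replicate groups present on the plates (>= 2
#' wells); `real` the number that actually produced usable data (>= 2
#' non-missing calls); `discordant` counts groups whose usable calls
#' disagree (a triplicate with one deviant call is 1 discordant replicate);
#' `discordance_rate = discordant / real`, `NA` when `real` is 0.
#'
#' When a study declares an expected replicate count that differs from the
#' detected one, a warning is raised (never an error: auto-detection may
#' legitimately exceed the declaration).
#'
#' @param groups data frame from [collect_replicates()].
#' @param study optional `study_definition` for the declared-count cross-check.
#' @return List with `expected`, `real`, `discordant`, `discordance_rate`.
#' @export
replicate_summary <- function(groups, study = NULL) {
  expected <- sum(groups$n_wells >= 2L)
  real <- sum(groups$n_usable >= 2L)
  discordant <- sum(groups$status == "discordant")
  if (!is.null(study) && study$expected_replicate_count != expected) {
    pqc_warn("replicate_mismatch",
             "study '%s' declares %d replicates but %d were detected",
             study$name, study$expected_replicate_count, expected)
  }
  list(expected = expected, real = real, discordant = discordant,
       discordance_rate = if (real == 0L) NA_real_ else discordant / real)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit test of the observed genotype counts against the
#' Hardy-Weinberg expectations (n p^2, 2 n p q, n q^2) computed from the
#' estimated allele frequency, 1 degree of freedom, no continuity correction
#' by default. A monomorphic SNP has chi2 = 0 and an undefined (`NA`)
#' p-value: with a fixed allele there is nothing to test.
#'
#' @param counts a `genotype_counts`.
#' @param correct apply the Yates continuity correction.
#' @return List with `chi2` and `p` (`NA`s when no genotype was called).
#' @export
hwe_chisq <- function(counts, correct = FALSE) {
  n <- n_called(counts)
  if (n == 0L) return(list(chi2 = NA_real_, p = NA_real_))
  p_hat <- (2 * counts$n_AA + counts$n_AB) / (2 * n)
  q_hat <- 1 - p_hat
  if (p_hat == 0 || p_hat == 1) return(list(chi2 = 0, p = NA_real_))
  expected <- c(n * p_hat^2, 2 * n * p_hat * q_hat, n * q_hat^2)
  observed <- c(counts$n_AA, counts$n_AB, counts$n_BB)
  dev <- abs(observed - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Assemble the per-SNP QC report
#'
#' Combines call rate, replicate statistics, MAF and the HWE test with the
#' report metadata (operator, comment, creation date) into one record.
#'
#' @param snp_id SNP name.
#' @param genotypes matrix column of canonical genotypes (one per sample).
#' @param groups data frame from [collect_replicates()].
#' @param alleles optional allele pair from the conversion map.
#' @param operator,comment report metadata.
#' @param creation_date report date (defaults to today).
#' @param study optional `study_definition` for the replicate cross-check.
#' @return A `qc_report` object (also a one-row data frame via
#'   [as.data.frame.qc_report()]).
#' @export
build_qc_report <- function(snp_id, genotypes, groups, alleles = NULL,
                            operator = "", comment = "",
                            creation_date = Sys.Date(), study = NULL) {
  counts <- genotype_counts(genotypes, alleles = alleles)
  maf <- minor_allele_freq(counts)
  hwe <- hwe_chisq(counts)
  reps <- replicate_summary(groups, study = study)
  structure(list(
    snp_id = snp_id,
    creation_date = as.character(creation_date),
    operator = operator,
    comment = comment,
    call_rate = call_rate(counts),
    expected_replicates = reps$expected,
    real_replicates = reps$real,
    discordant_replicates = reps$discordant,
    discordance_rate = reps$discordance_rate,
    maf = maf$maf,
    minor_allele = maf$minor_allele,
    hwe_chi2 = hwe$chi2,
    hwe_p = hwe$p,
    counts = counts
  ), class = "qc_report")
}

QC_REPORT_FIELDS <- c("snp_id", "creation_date", "operator", "comment",
                      "call_rate", "expected_replicates", "real_replicates",
                      "discordant_replicates", "discordance_rate",
                      "maf", "minor_allele", "hwe_chi2", "hwe_p")

#' @export
as.data.frame.qc_report <- function(x, ...) {
  vals <- lapply(QC_REPORT_FIELDS, function(f) x[[f]] %||% NA)
  names(vals) <- QC_REPORT_FIELDS
  as.data.frame(vals, stringsAsFactors = FALSE)
}

#' @export
print.qc_report <- function(x, ...) {
  fmt <- function(v, digits = 4) {
    if (is.null(v) || (length(v) == 1 && is.na(v))) "NA"
    else if (is.numeric(v)) format(round(v, digits), nsmall = 0)
    else as.character(v)
  }
  cat(sprintf("<qc_report> %s (%s, operator: %s)\n", x$snp_id,
              x$creation_date, if (nzchar(x$operator)) x$operator else "-"))
  cat(sprintf("  call rate:        %s\n", fmt(x$call_rate)))
  cat(sprintf("  replicates:       %d expected, %d real, %d discordant (rate %s)\n",
              x$expected_replicates, x$real_replicates,
              x$discordant_replicates, fmt(x$discordance_rate)))
  cat(sprintf("  MAF:              %s (%s)\n", fmt(x$maf), fmt(x$minor_allele)))
  cat(sprintf("  HWE:              chi2 %s, p %s\n", fmt(x$hwe_chi2), fmt(x$hwe_p)))
  if (nzchar(x$comment)) cat(sprintf("  comment: %s\n", x$comment))
  invisible(x)
}
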