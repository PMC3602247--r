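# Comparison of observed genotype counts against reference populations.
#
# Reference genotype counts (a local table standing in for HapMap release 27
# and 1000 Genomes phase 1 lookups) are compared to the user's counts with a
# Pearson chi-square test on the 2x3 genotype contingency table, after
# harmonizing the allele labels (swap / strand flip) between the two sources.

REF_TABLE_COLS <- c("snp_id", "population", "source",
                    "allele_a", "allele_b", "n_AA", "n_AB", "n_BB")

#' Load a reference genotype-frequency table
#'
#' Tab-separated, header
#' `snp_id  population  source  allele_a  allele_b  n_AA  n_AB  n_BB`,
#' one row per (SNP, population, source); `source` is `HAPMAP` or `KG`.
#' Counts are absolute genotype numbers in the reference population.
#'
#' @param x file path or lines.
#' @return A validated `ref_table` (data frame).
#' @export
load_reference_table <- function(x) {
  lines <- clean_lines(as_lines(x))
  lines <- lines[nzchar(trimws2(lines)) & !startsWith(trimws2(lines), "#")]
  if (!length(lines)) pqc_stop("empty_input", "empty reference table")
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(REF_TABLE_COLS, names(tab))
  if (length(miss)) {
    pqc_stop("format", "reference table missing column(s): %s",
             paste(miss, collapse = ", "))
  }
  tab <- tab[REF_TABLE_COLS]
  key <- paste(tab$snp_id, tab$population, tab$source, sep = "\r")
  if (anyDuplicated(key)) {
    pqc_stop("duplicate_key", "duplicate (snp, population, source) row: %s",
             gsub("\r", " / ", key[duplicated(key)][1], fixed = TRUE))
  }
  for (col in c("n_AA", "n_AB", "n_BB")) {
    if (any(is.na(tab[[col]])) || any(tab[[col]] < 0)) {
      pqc_stop("validation", "column %s contains negative or missing counts", col)
    }
  }
  if (any(!tab$source %in% c("HAPMAP", "KG"))) {
    pqc_stop("validation", "source must be HAPMAP or KG, got: %s",
             paste(setdiff(unique(tab$source), c("HAPMAP", "KG")), collapse = ", "))
  }
  bad <- !grepl("^[ACGT]$", tab$allele_a) | !grepl("^[ACGT]$", tab$allele_b)
  if (any(bad)) pqc_stop("validation", "invalid allele in reference table row %d", which(bad)[1])
  class(tab) <- c("ref_table", "data.frame")
  tab
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(alleles) {
  setequal(alleles, c("A", "T")) || setequal(alleles, c("C", "G"))
}

#' Harmonize user and reference allele labels
#'
#' Determines how the reference counts must be read so both sources use the
#' same allele pair. Outcomes: `direct` (same ordered pair),
#' `allele_swapped` (same pair, roles reversed — counts re-ordered),
#' `strand_flipped` (pairs match after reverse complement, possibly also
#' swapped), `ambiguous` (palindromic A/T or C/G SNP, where a strand flip is
#' indistinguishable from an allele swap — comparison proceeds as `direct`
#' with a warning flag), `incompatible` (no relabeling reconciles the pairs;
#' no test is performed).
#'
#' @param user_alleles length-2 character vector (user data, alphabetical).
#' @param ref_alleles length-2 character vector (`allele_a`, `allele_b`).
#' @return List with `outcome` and `ref_order`, the permutation of the
#'   reference genotype categories (AA, AB, BB) aligning them to the user's;
#'   `ref_order` is `NULL` when incompatible.
#' @export
harmonize_alleles <- function(user_alleles, ref_alleles) {
  u <- toupper(user_alleles); r <- toupper(ref_alleles)
  stopifnot(length(u) == 2L, length(r) == 2L)
  direct_order <- c(1L, 2L, 3L)
  swap_order <- c(3L, 2L, 1L)
  if (setequal(u, r) && is_palindromic(u)) {
    ord <- if (identical(u, r)) direct_order else swap_order
    return(list(outcome = "ambiguous", ref_order = ord))
  }
  if (identical(u, r)) return(list(outcome = "direct", ref_order = direct_order))
  if (identical(u, rev(r))) return(list(outcome = "allele_swapped", ref_order = swap_order))
  rc <- unname(COMPLEMENT[r])
  if (identical(u, rc)) return(list(outcome = "strand_flipped", ref_order = direct_order))
  if (identical(u, rev(rc))) return(list(outcome = "strand_flipped", ref_order = swap_order))
  list(outcome = "incompatible", ref_order = NULL)
}

# Pearson chi-square on an r x k table from margins; zero-total columns are
# dropped by the caller.
pearson_chisq_table <- function(tab) {
  n <- sum(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - exp_tab)^2 / exp_tab)
  list(chi2 = chi2, expected = exp_tab)
}

#' Compare user genotype counts against one reference population
#'
#' Pearson chi-square on the 2x3 contingency table (rows: user, reference;
#' columns: AA / AB / BB after harmonization). Columns whose total is 0 are
#' dropped with a matching reduction of the degrees of freedom
#' (`df = k - 1` for `k` surviving columns); with fewer than 2 surviving
#' columns the test is undefined. An expected cell below 5 attaches a
#' small-count warning flag.
#'
#' @param user_counts,ref_counts `genotype_counts` objects (reference counts
#'   already re-ordered per [harmonize_alleles()]).
#' @param population,source,harmonization metadata carried into the result.
#' @return A `population_comparison` object with `chi2`, `df`, `p`,
#'   `small_counts`, `note`.
#' @export
compare_population <- function(user_counts, ref_counts,
                               population = "", source = "",
                               harmonization = "direct") {
  u <- c(user_counts$n_AA, user_counts$n_AB, user_counts$n_BB)
  r <- c(ref_counts$n_AA, ref_counts$n_AB, ref_counts$n_BB)
  res <- list(population = population, source = source,
              harmonization = harmonization,
              user_counts = user_counts, ref_counts = ref_counts,
              chi2 = NA_real_, df = 0L, p = NA_real_,
              small_counts = FALSE, note = NULL)
  class(res) <- "population_comparison"
  if (sum(u) == 0 || sum(r) == 0) {
    res$note <- "undefined: one source has no genotypes"
    return(res)
  }
  tab <- rbind(user = u, reference = r)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  k <- ncol(tab)
  if (k < 2L) {
    res$note <- "undefined: fewer than 2 surviving genotype classes"
    return(res)
  }
  ch <- pearson_chisq_table(tab)
  res$chi2 <- ch$chi2
  res$df <- k - 1L
  res$p <- stats::pchisq(ch$chi2, df = res$df, lower.tail = FALSE)
  res$small_counts <- any(ch$expected < 5)
  res
}

#' @export
print.population_comparison <- function(x, ...) {
  cat(sprintf("<population_comparison> %s [%s] (%s): ", x$population, x$source,
              x$harmonization))
  if (is.na(x$chi2)) {
    cat(sprintf("test undefined (%s)\n", x$note %||% "NA"))
  } else {
    cat(sprintf("chi2 = %.4g, df = %d, p = %.4g%s\n", x$chi2, x$df, x$p,
                if (x$small_counts) " [small expected counts]" else ""))
  }
  invisible(x)
}

#' Compare a SNP against all matching reference populations
#'
#' Looks the SNP up in the reference table — under its alternate rs-number
#' when one is set and the primary ID is absent (covering SNPs whose dbSNP ID
#' changed between releases) — harmonizes alleles per population row and runs
#' [compare_population()] for each. Incompatible allele pairs yield a row
#' with an undefined test rather than an error.
#'
#' @param snp_id primary SNP ID.
#' @param user_counts a `genotype_counts` (alleles set).
#' @param table a `ref_table`.
#' @param alt_id optional alternate lookup rs-number.
#' @param populations optional filter of population labels.
#' @return List of `population_comparison` objects; empty, with attribute
#'   `notice`, when the SNP is absent from the table.
#' @export
compare_all <- function(snp_id, user_counts, table, alt_id = NULL,
                        populations = NULL) {
  stopifnot(inherits(table, "ref_table"))
  rows <- table[table$snp_id == snp_id, , drop = FALSE]
  used_id <- snp_id
  if (!nrow(rows) && !is.null(alt_id)) {
    rows <- table[table$snp_id == alt_id, , drop = FALSE]
    used_id <- alt_id
  }
  if (!nrow(rows)) {
    out <- list()
    attr(out, "notice") <- sprintf("SNP '%s' not found in the reference table", snp_id)
    return(out)
  }
  if (!is.null(populations)) {
    rows <- rows[rows$population %in% populations, , drop = FALSE]
  }
  ualleles <- c(user_counts$allele1, user_counts$allele2)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    ref_raw <- c(r$n_AA, r$n_AB, r$n_BB)
    if (any(is.na(ualleles))) {
      # monomorphic/all-missing user data: compare on the reference's pair
      harm <- list(outcome = "direct", ref_order = 1:3)
    } else {
      harm <- harmonize_alleles(ualleles, c(r$allele_a, r$allele_b))
    }
    if (harm$outcome == "incompatible") {
      cmp <- compare_population(as_genotype_counts(0, 0, 0),
                                as_genotype_counts(0, 0, 0),
                                population = r$population, source = r$source,
                                harmonization = "incompatible")
      cmp$user_counts <- user_counts
      cmp$ref_counts <- as_genotype_counts(r$n_AA, r$n_AB, r$n_BB,
                                           r$allele_a, r$allele_b)
      cmp$note <- "incompatible allele pairs: no test performed"
      return(cmp)
    }
    ref_ord <- ref_raw[harm$ref_order]
    a1 <- if (is.na(ualleles[1])) r$allele_a else ualleles[1]
    a2 <- if (is.na(ualleles[2])) r$allele_b else ualleles[2]
    ref_counts <- as_genotype_counts(ref_ord[1], ref_ord[2], ref_ord[3], a1, a2)
    cmp <- compare_population(user_counts, ref_counts,
                              population = r$population, source = r$source,
                              harmonization = harm$outcome)
    cmp
  })
  attr(out, "lookup_id") <- used_id
  out
}
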