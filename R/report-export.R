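# Export of genotype lists, QC reports, population comparisons and PED/MAP.
#
# All tabular exports are CSV (RFC-4180 quoting via write.csv) with genotype
# and statistic cells written as text; undefined statistics export as the
# literal "NA", never blank or 0, so an undefined value is distinguishable
# from an absent row. QC exports carry highlight flags for values beyond the
# configured thresholds (rendered as an adjacent "*_flag" column). An XLSX
# writer is an extension point; requesting it raises an informative error.

check_format <- function(format) {
  format <- tolower(format)
  if (format == "xlsx") {
    pqc_stop("format", "XLSX export is an extension point; use format = \"csv\"")
  }
  if (format != "csv") pqc_stop("format", "unsupported export format '%s'", format)
  format
}

na_chr <- function(x) {
  out <- as.character(x)
  out[is.na(x)] <- "NA"
  out
}

#' Default highlight rules
#'
#' HWE p below 0.05, call rate below 0.95, any replicate discordance. All
#' thresholds are user-overridable; rules never fire on undefined values.
#' @return Data frame with columns `field`, `comparator`, `threshold`.
#' @export
default_highlight_rules <- function() {
  data.frame(field = c("hwe_p", "call_rate", "discordance_rate"),
             comparator = c("<", "<", ">"),
             threshold = c(0.05, 0.95, 0),
             stringsAsFactors = FALSE)
}

#' Evaluate highlight rules against a QC report
#'
#' @param report a `qc_report` (or one-row data frame of its fields).
#' @param rules data frame as in [default_highlight_rules()].
#' @return Character vector of flagged field names (possibly empty).
#' @export
apply_highlight_rules <- function(report, rules = default_highlight_rules()) {
  rep_df <- if (inherits(report, "qc_report")) as.data.frame(report) else report
  flagged <- character(0)
  for (i in seq_len(nrow(rules))) {
    f <- rules$field[i]
    v <- rep_df[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) next
    hit <- switch(rules$comparator[i],
                  "<" = v < rules$threshold[i],
                  ">" = v > rules$threshold[i],
                  "<=" = v <= rules$threshold[i],
                  ">=" = v >= rules$threshold[i],
                  pqc_stop("config", "unknown comparator '%s'", rules$comparator[i]))
    if (isTRUE(hit)) flagged <- c(flagged, f)
  }
  unique(flagged)
}

#' Export a single SNP's genotype list
#'
#' Two columns, `sample_id` and the SNP's genotypes, one row per manifest
#' sample (absent samples carry "0/0").
#'
#' @param snp_id column of `matrix` to export.
#' @param matrix genotype matrix from [build_genotype_matrix()].
#' @param path output file.
#' @param format "csv".
#' @export
export_genotype_list <- function(snp_id, matrix, path, format = "csv") {
  check_format(format)
  if (!snp_id %in% colnames(matrix)) {
    pqc_stop("config", "SNP '%s' not in the genotype matrix", snp_id)
  }
  df <- data.frame(sample_id = rownames(matrix),
                   genotype = unname(matrix[, snp_id]),
                   stringsAsFactors = FALSE)
  names(df)[2] <- snp_id
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

qc_table <- function(reports, rules) {
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  for (i in seq_along(reports)) {
    flags <- apply_highlight_rules(reports[[i]], rules)
    tab$flagged[i] <- paste(flags, collapse = ";")
  }
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], na_chr)
  tab$minor_allele <- na_chr(tab$minor_allele)
  tab
}

#' Export the merged genotype list and merged QC report
#'
#' Writes `<path_prefix>_genotypes.csv` (samples x selected SNPs) and
#' `<path_prefix>_qc.csv` (one row per SNP with every QC statistic plus a
#' `flagged` column naming the statistics beyond threshold), giving an
#' immediate overview of the QC values of all selected SNPs.
#'
#' @param study a `study_definition`.
#' @param snp_selection character vector of SNP ids to include.
#' @param matrix genotype matrix covering the selection.
#' @param reports named list of `qc_report`s (names = SNP ids).
#' @param path_prefix output path prefix.
#' @param format "csv".
#' @param rules highlight rules.
#' @return Named character vector of the two written paths.
#' @export
export_merged <- function(study, snp_selection, matrix, reports, path_prefix,
                          format = "csv", rules = default_highlight_rules()) {
  check_format(format)
  if (!length(snp_selection)) pqc_stop("empty_selection", "no SNPs selected for export")
  miss <- setdiff(snp_selection, colnames(matrix))
  if (length(miss)) pqc_stop("config", "SNP(s) not in matrix: %s", paste(miss, collapse = ", "))
  gdf <- data.frame(sample_id = rownames(matrix),
                    matrix[, snp_selection, drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  gpath <- paste0(path_prefix, "_genotypes.csv")
  utils::write.csv(gdf, gpath, row.names = FALSE, quote = TRUE)
  qpath <- paste0(path_prefix, "_qc.csv")
  sel_reports <- reports[snp_selection]
  if (any(vapply(sel_reports, is.null, logical(1)))) {
    pqc_stop("config", "missing QC report for selected SNP(s): %s",
             paste(snp_selection[vapply(sel_reports, is.null, logical(1))], collapse = ", "))
  }
  utils::write.csv(qc_table(sel_reports, rules), qpath, row.names = FALSE, quote = TRUE)
  invisible(c(genotypes = gpath, qc = qpath))
}

#' Re-import a merged genotype CSV
#'
#' Inverse of the genotype sheet written by [export_merged()]; used for
#' round-trip verification.
#' @param path CSV path.
#' @return Character genotype matrix (rownames = sample IDs).
#' @export
read_genotype_matrix_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Export population comparisons for selected populations
#'
#' One row per selected population with frequencies, absolute genotype
#' numbers, chi-square, p and the harmonization flag. An empty selection
#' exports all populations. Incompatible populations export with test fields
#' "NA" and the incompatible flag.
#'
#' @param comparisons list of `population_comparison` from [compare_all()].
#' @param path output CSV path.
#' @param populations optional selection of population labels.
#' @export
export_population_comparisons <- function(comparisons, path, populations = NULL) {
  if (length(populations)) {
    comparisons <- Filter(function(cmp) cmp$population %in% populations, comparisons)
  }
  rows <- lapply(comparisons, function(cmp) {
    u <- cmp$user_counts; r <- cmp$ref_counts
    un <- u$n_AA + u$n_AB + u$n_BB; rn <- r$n_AA + r$n_AB + r$n_BB
    ufreq <- if (un > 0) (2 * u$n_AA + u$n_AB) / (2 * un) else NA_real_
    rfreq <- if (rn > 0) (2 * r$n_AA + r$n_AB) / (2 * rn) else NA_real_
    data.frame(population = cmp$population, source = cmp$source,
               harmonization = cmp$harmonization,
               user_AA = u$n_AA, user_AB = u$n_AB, user_BB = u$n_BB,
               user_freq_allele1 = na_chr(ufreq),
               ref_AA = r$n_AA, ref_AB = r$n_AB, ref_BB = r$n_BB,
               ref_freq_allele1 = na_chr(rfreq),
               chi2 = na_chr(cmp$chi2), df = cmp$df, p = na_chr(cmp$p),
               small_counts = cmp$small_counts,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(population = character(), source = character(),
                      stringsAsFactors = FALSE)
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Export PLINK PED and MAP files
#'
#' PED: the standard 6-column prefix (family and individual IDs both the
#' sample ID, father/mother 0, sex 0 — or 1/2 when phenotypes are supplied —
#' phenotype -9) followed by one space-separated allele pair per SNP,
#' missing as "0 0". MAP: chromosome, SNP id, genetic distance 0, position
#' (chromosome/position default to 0 when no metadata is given).
#'
#' @param matrix genotype matrix.
#' @param path_prefix files are written to `<path_prefix>.ped` / `.map`.
#' @param snp_meta optional data frame `snp_id`, `chromosome`, `position`.
#' @param sex_phenotypes optional `sex_phenotypes` filling the PED sex column
#'   (male 1, female 2, unknown 0).
#' @return Named character vector of the written paths.
#' @export
export_ped_map <- function(matrix, path_prefix, snp_meta = NULL,
                           sex_phenotypes = NULL) {
  snps <- colnames(matrix)
  sex_col <- rep(0L, nrow(matrix))
  if (!is.null(sex_phenotypes)) {
    stopifnot(inherits(sex_phenotypes, "sex_phenotypes"))
    s <- sex_phenotypes$sex[rownames(matrix)]
    sex_col[which(s == "male")] <- 1L
    sex_col[which(s == "female")] <- 2L
  }
  allele_txt <- apply(matrix, 1, function(row) {
    paste(gsub("/", " ", row, fixed = TRUE), collapse = " ")
  })
  ped <- paste(rownames(matrix), rownames(matrix), 0L, 0L, sex_col, -9L,
               allele_txt)
  if (!length(snps)) ped <- paste(rownames(matrix), rownames(matrix), 0L, 0L, sex_col, -9L)
  ped_path <- paste0(path_prefix, ".ped")
  writeLines(ped, ped_path)
  chrom <- rep(0L, length(snps)); pos <- rep(0L, length(snps))
  if (!is.null(snp_meta)) {
    idx <- match(snps, snp_meta$snp_id)
    chrom[!is.na(idx)] <- snp_meta$chromosome[idx[!is.na(idx)]]
    pos[!is.na(idx)] <- snp_meta$position[idx[!is.na(idx)]]
  }
  map_path <- paste0(path_prefix, ".map")
  writeLines(paste(chrom, snps, 0L, pos, sep = "\t"), map_path)
  invisible(c(ped = ped_path, map = map_path))
}
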