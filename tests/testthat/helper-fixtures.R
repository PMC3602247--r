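# In-memory plate-file builders used across the test files.

sds_lines <- function(rows, header = "Well,Sample Name,Marker,Call",
                      comments = "# comment") {
  c(comments, header, vapply(rows, paste, character(1), collapse = ","))
}

typer_lines <- function(rows) {
  c(paste("Plate", "Well", "Sample Id", "Assay Id", "Genotype", sep = "\t"),
    vapply(rows, paste, character(1), collapse = "\t"))
}

# A small hand-written SDS plate: 3 study samples, one control, one unknown.
demo_sds <- function() {
  sds_lines(list(
    c("A1", "S001", "rs328", "rs328_G"),
    c("A2", "S002", "rs328", "rs328_C"),
    c("A3", "S003", "rs328", "Both"),
    c("A4", "NTC",  "rs328", "Undetermined"),
    c("A5", "S999", "rs328", "rs328_G")
  ))
}

demo_study <- function() {
  suppressWarnings(create_study("demo", c("S001", "S002", "S003", "S004")))
}

ref_table_lines <- function(rows) {
  c(paste(c("snp_id", "population", "source", "allele_a", "allele_b",
            "n_AA", "n_AB", "n_BB"), collapse = "\t"),
    vapply(rows, paste, character(1), collapse = "\t"))
}

# Independent margins-based Pearson chi-square used as the contingency oracle.
oracle_chisq_2x3 <- function(user, ref) {
  tab <- rbind(user, ref)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2 || any(rowSums(tab) == 0)) return(NULL)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(chi2 = sum((tab - e)^2 / e), df = ncol(tab) - 1L)
}

# Independent HWE oracle: recomputes expectations from allele counts.
oracle_hwe <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  if (n == 0) return(list(chi2 = NA_real_, p = NA_real_))
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  if (nA == 0 || nB == 0) return(list(chi2 = 0, p = NA_real_))
  exp_counts <- c(nA^2 / (4 * n), nA * nB / (2 * n), nB^2 / (4 * n))
  chi2 <- sum((c(n_AA, n_AB, n_BB) - exp_counts)^2 / exp_counts)
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}
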