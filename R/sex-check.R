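# Sex-marker concordance checking.
#
# A SNP on a gene present on both X and Y (amelogenin AMELX/AMELY, GYG2,
# ZFX/ZFY) distinguishes the sexes by genotype (on an amelogenin-style assay
# the X/Y base difference makes males heterozygous). The genotype-to-sex
# assignment is always user-supplied — marker panels differ — and expected
# phenotypic sex arrives in a two-column file with a free sex coding. Only
# discordances are ever persisted, so full phenotype lists never sit next to
# genotype data in the project store.

#' Load expected sex phenotypes
#'
#' @param x path or lines of a two-column TSV `sample_id<TAB>sex` ("#"
#'   comments allowed).
#' @param coding named character vector mapping every raw sex token in the
#'   file to "male" or "female", e.g. `c(m = "male", f = "female")`.
#' @return A `sex_phenotypes` object.
#' @export
load_sex_phenotypes <- function(x, coding) {
  if (is.null(names(coding)) || any(!coding %in% c("male", "female"))) {
    pqc_stop("config", "coding must be a named vector of token = \"male\"/\"female\"")
  }
  lines <- clean_lines(as_lines(x))
  lines <- lines[nzchar(trimws2(lines)) & !startsWith(trimws2(lines), "#")]
  if (!length(lines)) pqc_stop("empty_input", "empty sex phenotype file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    pqc_stop("parse", "sex phenotype file must have two tab-separated columns (line %d)",
             which(lengths(parts) < 2L)[1])
  }
  ids <- trimws2(vapply(parts, `[`, character(1), 1L))
  tok <- trimws2(vapply(parts, `[`, character(1), 2L))
  if (identical(tolower(ids[1]), "sample_id")) { ids <- ids[-1]; tok <- tok[-1] }
  if (anyDuplicated(ids)) {
    pqc_stop("duplicate_key", "duplicate sample ID in sex phenotype file: %s",
             ids[duplicated(ids)][1])
  }
  unknown_tok <- setdiff(unique(tok), names(coding))
  if (length(unknown_tok)) {
    pqc_stop("coding", "sex token(s) absent from the coding: %s",
             paste(sprintf("'%s'", unknown_tok), collapse = ", "))
  }
  structure(list(coding = coding,
                 records = stats::setNames(tok, ids),
                 sex = stats::setNames(unname(coding[tok]), ids)),
            class = "sex_phenotypes")
}

#' @export
print.sex_phenotypes <- function(x, ...) {
  cat(sprintf("<sex_phenotypes> %d samples (%d male, %d female); coding: %s\n",
              length(x$sex), sum(x$sex == "male"), sum(x$sex == "female"),
              paste(sprintf("%s=%s", names(x$coding), x$coding), collapse = ", ")))
  invisible(x)
}

#' Infer sex from a sex-marker genotype
#'
#' Pure lookup through the user-supplied assignment; missing genotypes, and
#' genotypes outside the assignment, give "unknown".
#'
#' @param genotypes character vector of canonical genotypes.
#' @param assignment named character vector genotype -> "male"/"female", e.g.
#'   `c("A/G" = "male", "A/A" = "female")` for an amelogenin-style marker.
#' @return Character vector over `c("male", "female", "unknown")`.
#' @export
infer_sex <- function(genotypes, assignment) {
  if (any(!assignment %in% c("male", "female"))) {
    pqc_stop("config", "assignment values must be \"male\" or \"female\"")
  }
  names(assignment) <- normalize_genotype(names(assignment))
  out <- unname(assignment[normalize_genotype(genotypes)])
  out[is.na(out)] <- "unknown"
  out[is_missing_gt(genotypes)] <- "unknown"
  out
}

#' Sex discordance report
#'
#' Compares genotypic sex (from the sex-marker column of the genotype
#' matrix) with the uploaded phenotypic sex, sample by sample. Only samples
#' where both sexes are known and disagree become discordance records; a
#' sample with an unknown genotypic sex is counted separately, and a
#' genotyped sample without a phenotype record is counted as
#' missing-phenotype — neither is ever reported discordant. Concordant
#' samples are counted but not listed.
#'
#' @param genotypes named character vector (matrix column; names = sample IDs).
#' @param assignment genotype -> sex mapping (see [infer_sex()]).
#' @param phenotypes a `sex_phenotypes` object.
#' @return A `sex_check` object: `discordances` data frame (`sample_id`,
#'   `genotypic_sex`, `phenotypic_sex`) and `summary` counts
#'   (`discordant`, `concordant`, `unknown`, `no_phenotype`, `n`).
#' @export
sex_discordance_report <- function(genotypes, assignment, phenotypes) {
  stopifnot(inherits(phenotypes, "sex_phenotypes"))
  ids <- names(genotypes)
  if (is.null(ids)) pqc_stop("config", "genotypes must be named by sample ID")
  gsex <- infer_sex(genotypes, assignment)
  psex <- unname(phenotypes$sex[ids])
  no_pheno <- is.na(psex)
  unknown <- !no_pheno & gsex == "unknown"
  comparable <- !no_pheno & !unknown
  disc <- comparable & gsex != psex
  conc <- comparable & gsex == psex
  structure(list(
    discordances = data.frame(sample_id = ids[disc],
                              genotypic_sex = gsex[disc],
                              phenotypic_sex = psex[disc],
                              stringsAsFactors = FALSE, row.names = NULL),
    summary = list(discordant = sum(disc), concordant = sum(conc),
                   unknown = sum(unknown), no_phenotype = sum(no_pheno),
                   n = length(ids))
  ), class = "sex_check")
}

#' @export
print.sex_check <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sex_check> %d samples: %d discordant, %d concordant, %d unknown, %d without phenotype\n",
              s$n, s$discordant, s$concordant, s$unknown, s$no_phenotype))
  if (nrow(x$discordances)) {
    print(x$discordances, row.names = FALSE)
  }
  invisible(x)
}
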