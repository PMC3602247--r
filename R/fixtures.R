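# Synthetic truth-known studies written as plate files.
#
# A truth study holds a manifest, a per-SNP truth genotype matrix drawn under
# Hardy-Weinberg (or an inbreeding-style heterozygote deficit), a plate/well
# plan with replicates, a defect ledger (injected discordances, no-calls,
# unknown IDs, absent samples, sex mismatches) and per-sample sex truth. It
# can be serialized to either plate dialect plus manifest, reference table
# and sex phenotype files, so every pipeline stage is testable without any
# external download. Each stochastic stage seeds its own RNG sub-stream, so
# changing one defect count does not shift the other draws.

#' Specify one SNP for a truth study
#'
#' @param id SNP/assay name.
#' @param alleles length-2 character vector.
#' @param maf minor allele frequency in [0, 0.5] (frequency of `alleles[1]`...
#'   the first allele is the minor one by convention here).
#' @param hwe draw genotypes under Hardy-Weinberg equilibrium; when `FALSE`,
#'   apply an inbreeding-style heterozygote deficit with coefficient `f`.
#' @param f inbreeding coefficient used when `hwe = FALSE`.
#' @param sex_marker make this an amelogenin-style sex-determination marker:
#'   genotypes are set from the sample's sex truth (male heterozygous from
#'   the X/Y base difference, female homozygous for `alleles[2]`) instead of
#'   being drawn from `maf`.
#' @export
truth_snp <- function(id, alleles = c("A", "G"), maf = 0.3, hwe = TRUE, f = 0.3,
                      sex_marker = FALSE) {
  stopifnot(length(alleles) == 2L, maf >= 0, maf <= 0.5)
  list(id = id, alleles = sort(toupper(alleles)), maf = maf, hwe = hwe, f = f,
       sex_marker = isTRUE(sex_marker))
}

draw_genotypes <- function(n, alleles, maf, hwe, f) {
  p <- maf; q <- 1 - maf
  if (hwe) {
    probs <- c(p^2, 2 * p * q, q^2)
  } else {
    probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  }
  cats <- sample.int(3L, n, replace = TRUE, prob = probs)
  gts <- c(paste(alleles[1], alleles[1], sep = "/"),
           normalize_genotype(paste0(alleles[1], alleles[2])),
           paste(alleles[2], alleles[2], sep = "/"))
  gts[cats]
}

#' Generate a truth study
#'
#' Draws a truth genotype matrix for `n_samples` manifest samples and lays
#' sample occurrences (each sample once, plus one duplicate well for a
#' `replicate_fraction` of samples) row-major onto 384-well plates.
#'
#' @param n_samples manifest size.
#' @param snps list of [truth_snp()] specifications.
#' @param replicate_fraction fraction of samples plated twice.
#' @param seed integer seed; the study is fully reproducible from it.
#' @param plate_capacity wells per plate.
#' @return A `truth_study` object.
#' @export
generate_truth <- function(n_samples, snps, replicate_fraction = 0.1,
                           seed = 1L, plate_capacity = 384L) {
  stopifnot(n_samples >= 1, replicate_fraction >= 0, replicate_fraction <= 1)
  if (!is.null(names(snps)) || !is.list(snps[[1]])) snps <- list(snps)
  manifest <- sprintf("S%05d", seq_len(n_samples))
  snp_ids <- vapply(snps, `[[`, character(1), "id")
  set.seed(sub_seed(seed, 3L))
  sex <- sample(c("male", "female"), n_samples, replace = TRUE)
  names(sex) <- manifest
  set.seed(sub_seed(seed, 1L))
  truth <- matrix(MISSING_GT, nrow = n_samples, ncol = length(snps),
                  dimnames = list(manifest, snp_ids))
  for (j in seq_along(snps)) {
    s <- snps[[j]]
    if (isTRUE(s$sex_marker)) {
      het <- normalize_genotype(paste0(s$alleles[1], s$alleles[2]))
      hom <- paste(s$alleles[2], s$alleles[2], sep = "/")
      truth[, j] <- ifelse(sex == "male", het, hom)
    } else {
      truth[, j] <- draw_genotypes(n_samples, s$alleles, s$maf, s$hwe, s$f)
    }
  }
  set.seed(sub_seed(seed, 2L))
  n_rep <- floor(replicate_fraction * n_samples)
  replicated <- sort(sample(manifest, n_rep))
  occupants <- c(manifest, replicated)   # occurrence order: all samples, then duplicates
  n_wells <- length(occupants)
  plate_idx <- (seq_len(n_wells) - 1L) %/% plate_capacity + 1L
  pos <- (seq_len(n_wells) - 1L) %% plate_capacity
  wells <- data.frame(
    plate_name = sprintf("PLATE%02d", plate_idx),
    well = paste0(WELL_ROWS[pos %/% 24L + 1L], pos %% 24L + 1L),
    sample_id = occupants,
    stringsAsFactors = FALSE
  )
  # per-well genotypes start as the sample's truth genotype for every SNP
  well_gt <- truth[wells$sample_id, , drop = FALSE]
  rownames(well_gt) <- NULL
  structure(list(
    manifest = manifest,
    snps = snps,
    snp_ids = snp_ids,
    truth = truth,
    wells = wells,
    well_gt = well_gt,
    sex = sex,
    sex_observed = sex,        # phenotype file content; mismatches injected later
    replicated = replicated,
    plate_capacity = plate_capacity,
    planned_wells = n_wells,
    seed = seed,
    defects = list(discordant = character(0), nocall = integer(0),
                   unknown_ids = integer(0), absent = character(0),
                   sex_mismatch = character(0))
  ), class = "truth_study")
}

#' @export
print.truth_study <- function(x, ...) {
  cat(sprintf("<truth_study> %d samples, %d SNP(s), %d wells on %d plate(s), seed %d\n",
              length(x$manifest), length(x$snp_ids), nrow(x$wells),
              length(unique(x$wells$plate_name)), x$seed))
  d <- x$defects
  cat(sprintf("  defects: %d discordant, %d no-call wells, %d unknown-ID wells, %d absent, %d sex mismatches\n",
              length(d$discordant), length(d$nocall), length(d$unknown_ids),
              length(d$absent), length(d$sex_mismatch)))
  invisible(x)
}

other_genotype <- function(gt, alleles) {
  all3 <- c(paste(alleles[1], alleles[1], sep = "/"),
            normalize_genotype(paste0(alleles[1], alleles[2])),
            paste(alleles[2], alleles[2], sep = "/"))
  setdiff(all3, gt)[1]
}

#' Inject defects into a truth study
#'
#' Alters the well-level data while recording exact indices in the defect
#' ledger: `k_discordant` replicate groups get a disagreeing duplicate call,
#' `k_absent` manifest samples are removed from all plates, `k_nocall` wells
#' are blanked, `k_unknown_ids` extra wells carrying IDs outside the manifest
#' (mislabeled wells) are plated, and `k_sex_mismatch` samples get a flipped
#' entry in the sex phenotype file. Defect classes draw from disjoint sample
#' sets so one defect never masks another (a no-call never blanks a
#' replicate's well, an absent sample is never also discordant, and so on).
#' All k = 0 returns the study unchanged.
#'
#' @param truth a `truth_study`.
#' @param k_discordant,k_nocall,k_unknown_ids,k_absent,k_sex_mismatch counts.
#' @param seed defect RNG seed (defaults to the study seed).
#' @return The modified `truth_study`; `$defects$nocall` and
#'   `$defects$unknown_ids` are row indices into the final `$wells` plan,
#'   `$defects$discordant`, `$defects$absent` and `$defects$sex_mismatch` are
#'   sample IDs.
#' @export
inject_defects <- function(truth, k_discordant = 0L, k_nocall = 0L,
                           k_unknown_ids = 0L, k_absent = 0L,
                           k_sex_mismatch = 0L, seed = truth$seed) {
  stopifnot(inherits(truth, "truth_study"))
  touched <- character(0)
  wells_of <- function(id) which(truth$wells$sample_id %in% id)

  if (k_discordant > 0L) {
    set.seed(sub_seed(seed, 11L))
    pool <- setdiff(truth$replicated, touched)
    if (length(pool) < k_discordant) pqc_stop("config", "not enough replicate groups for k_discordant")
    chosen <- sort(sample(pool, k_discordant))
    for (id in chosen) {
      w <- wells_of(id)
      dup <- w[length(w)]              # alter the duplicate occurrence
      for (j in seq_along(truth$snp_ids)) {
        truth$well_gt[dup, j] <- other_genotype(truth$well_gt[dup, j],
                                                truth$snps[[j]]$alleles)
      }
    }
    truth$defects$discordant <- chosen
    touched <- c(touched, chosen)
  }

  if (k_absent > 0L) {
    set.seed(sub_seed(seed, 14L))
    pool <- setdiff(truth$manifest, c(touched, truth$replicated))
    if (length(pool) < k_absent) pqc_stop("config", "not enough samples for k_absent")
    chosen <- sort(sample(pool, k_absent))
    drop <- wells_of(chosen)
    truth$wells <- truth$wells[-drop, , drop = FALSE]
    truth$well_gt <- truth$well_gt[-drop, , drop = FALSE]
    rownames(truth$wells) <- NULL
    truth$defects$absent <- chosen
    touched <- c(touched, chosen)
  }

  if (k_nocall > 0L) {
    set.seed(sub_seed(seed, 12L))
    pool <- which(!(truth$wells$sample_id %in% c(touched, truth$replicated)))
    if (length(pool) < k_nocall) pqc_stop("config", "not enough wells for k_nocall")
    chosen <- sort(sample(pool, k_nocall))
    truth$well_gt[chosen, ] <- MISSING_GT
    truth$defects$nocall <- chosen
    touched <- c(touched, truth$wells$sample_id[chosen])
  }

  if (k_unknown_ids > 0L) {
    set.seed(sub_seed(seed, 13L))
    pos <- truth$planned_wells + seq_len(k_unknown_ids) - 1L
    extra <- data.frame(
      plate_name = sprintf("PLATE%02d", pos %/% truth$plate_capacity + 1L),
      well = paste0(WELL_ROWS[(pos %% truth$plate_capacity) %/% 24L + 1L],
                    (pos %% truth$plate_capacity) %% 24L + 1L),
      sample_id = sprintf("X%04d", seq_len(k_unknown_ids)),
      stringsAsFactors = FALSE)
    extra_gt <- matrix(MISSING_GT, nrow = k_unknown_ids,
                       ncol = length(truth$snp_ids))
    for (j in seq_along(truth$snps)) {
      extra_gt[, j] <- draw_genotypes(k_unknown_ids, truth$snps[[j]]$alleles,
                                      truth$snps[[j]]$maf, TRUE, 0)
    }
    truth$wells <- rbind(truth$wells, extra)
    rownames(truth$wells) <- NULL
    truth$well_gt <- rbind(truth$well_gt, extra_gt)
    truth$planned_wells <- truth$planned_wells + k_unknown_ids
    truth$defects$unknown_ids <- nrow(truth$wells) - k_unknown_ids + seq_len(k_unknown_ids)
  }

  if (k_sex_mismatch > 0L) {
    set.seed(sub_seed(seed, 15L))
    pool <- setdiff(truth$manifest, c(touched, truth$defects$absent))
    if (length(pool) < k_sex_mismatch) pqc_stop("config", "not enough samples for k_sex_mismatch")
    chosen <- sort(sample(pool, k_sex_mismatch))
    flip <- c(male = "female", female = "male")
    truth$sex_observed[chosen] <- unname(flip[truth$sex[chosen]])
    truth$defects$sex_mismatch <- chosen
  }

  truth
}

sds_token <- function(gt, snp_id, alleles) {
  hom1 <- paste(alleles[1], alleles[1], sep = "/")
  hom2 <- paste(alleles[2], alleles[2], sep = "/")
  out <- rep("Both", length(gt))
  out[gt == hom1] <- paste0(snp_id, "_", alleles[1])
  out[gt == hom2] <- paste0(snp_id, "_", alleles[2])
  out[is_missing_gt(gt)] <- "Undetermined"
  out
}

# Reference counts drawn from a binomial HWE population model around each
# SNP's truth allele frequency (slightly perturbed per population).
make_reference_table <- function(truth, populations, pop_n, seed) {
  set.seed(sub_seed(seed, 21L))
  rows <- list()
  for (j in seq_along(truth$snps)) {
    s <- truth$snps[[j]]
    for (k in seq_along(populations)) {
      p <- min(0.95, max(0.02, s$maf + stats::rnorm(1, 0, 0.02)))
      g <- table(factor(sample.int(3L, pop_n, replace = TRUE,
                                   prob = c(p^2, 2 * p * (1 - p), (1 - p)^2)),
                        levels = 1:3))
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = s$id, population = populations[k],
        source = if (grepl("^[A-Z]{3}$", populations[k]) &&
                     populations[k] %in% c("EUR", "AFR", "AMR", "ASN", "EAS", "SAS")) "KG" else "HAPMAP",
        allele_a = s$alleles[1], allele_b = s$alleles[2],
        n_AA = as.integer(g[1]), n_AB = as.integer(g[2]), n_BB = as.integer(g[3]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a truth study as plate files plus companion inputs
#'
#' SDS dialect: one file per plate per SNP, detector names `<snp>_<allele>`,
#' heterozygotes as "Both", no-calls as "Undetermined". TYPER dialect: one
#' multi-plate multi-assay file with allele-concatenation genotypes and empty
#' no-calls. Also writes the manifest, a reference genotype-count table
#' (binomial HWE population model around each SNP's truth frequency) and a
#' sex phenotype file reflecting the (possibly mismatch-injected) observed
#' sex.
#'
#' @param truth a `truth_study`.
#' @param dir output directory (created).
#' @param dialect "SDS" or "TYPER".
#' @param populations reference populations to tabulate.
#' @param pop_n reference population size per row.
#' @param sex_coding named tokens used in the sex phenotype file.
#' @param zip also bundle the plate files into `plates.zip` (requires the
#'   `zip` package).
#' @return List of written paths: `plates`, `manifest`, `reference`, `sex`,
#'   and `zip` when requested.
#' @export
write_fixture <- function(truth, dir, dialect = c("SDS", "TYPER"),
                          populations = c("CEU", "YRI", "EUR"),
                          pop_n = 120L,
                          sex_coding = c(m = "male", f = "female"),
                          zip = FALSE) {
  dialect <- match.arg(dialect)
  plate_dir <- file.path(dir, "plates")
  dir.create(plate_dir, recursive = TRUE, showWarnings = FALSE)
  plate_files <- character(0)
  if (dialect == "SDS") {
    for (p in unique(truth$wells$plate_name)) {
      sel <- truth$wells$plate_name == p
      for (j in seq_along(truth$snp_ids)) {
        snp <- truth$snp_ids[j]
        path <- file.path(plate_dir, sprintf("%s_%s.csv", p, snp))
        tok <- sds_token(truth$well_gt[sel, j], snp, truth$snps[[j]]$alleles)
        lines <- c("# synthetic allelic-discrimination export",
                   "Well,Sample Name,Marker,Call",
                   paste(truth$wells$well[sel], truth$wells$sample_id[sel],
                         snp, tok, sep = ","))
        writeLines(lines, path)
        plate_files <- c(plate_files, path)
      }
    }
  } else {
    rows <- character(0)
    for (j in seq_along(truth$snp_ids)) {
      gt_tok <- gsub("/", "", truth$well_gt[, j], fixed = TRUE)
      gt_tok[gt_tok == "00"] <- ""
      rows <- c(rows, paste(truth$wells$plate_name, truth$wells$well,
                            truth$wells$sample_id, truth$snp_ids[j], gt_tok,
                            sep = "\t"))
    }
    path <- file.path(plate_dir, "typer_plates.tsv")
    writeLines(c(paste("Plate", "Well", "Sample Id", "Assay Id", "Genotype",
                       sep = "\t"), rows), path)
    plate_files <- path
  }
  manifest_path <- file.path(dir, "manifest.txt")
  writeLines(c("# sample manifest", truth$manifest), manifest_path)
  ref_path <- file.path(dir, "reference_table.tsv")
  ref <- make_reference_table(truth, populations, pop_n, truth$seed)
  utils::write.table(ref, ref_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sex_path <- file.path(dir, "sex_phenotypes.tsv")
  inv_coding <- stats::setNames(names(sex_coding), sex_coding)
  keep <- setdiff(truth$manifest, truth$defects$absent)
  writeLines(c("sample_id\tsex",
               paste(keep, inv_coding[truth$sex_observed[keep]], sep = "\t")),
             sex_path)
  out <- list(plates = plate_files, manifest = manifest_path,
              reference = ref_path, sex = sex_path)
  if (zip) {
    if (!requireNamespace("zip", quietly = TRUE)) {
      pqc_stop("config", "the 'zip' package is required for zip = TRUE")
    }
    zip_path <- file.path(dir, "plates.zip")
    zip::zipr(zip_path, plate_files)
    out$zip <- zip_path
  }
  out
}
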