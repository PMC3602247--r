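# Raw-call conversion, replicate handling and the study genotype matrix.
#
# Genotypes are stored as canonical strings "A/G" with alleles in ascending
# alphabetical order; the missing sentinel is "0/0" (PED-compatible "0 0" on
# export). Conversion from raw call tokens happens through a per-assay
# conversion map that must be explicitly approved (checkpoint 2) before use.

MISSING_GT <- "0/0"

#' Normalize a raw allele pair to a canonical genotype
#'
#' Accepts two-base strings ("GA"), single bases (homozygote shorthand "A"),
#' slash-separated pairs ("G/A"), and the missing forms ("", NA, "0/0", "00").
#' Alleles are sorted so "GA" and "AG" both canonicalize to "A/G"; the
#' operation is idempotent.
#'
#' @param raw character vector of raw allele pairs.
#' @return Character vector of canonical genotypes ("A/G" or "0/0").
#' @export
normalize_genotype <- function(raw) {
  raw <- as.character(raw)
  out <- character(length(raw))
  stripped <- gsub("/", "", trimws2(raw), fixed = TRUE)
  stripped[is.na(raw)] <- ""
  miss <- stripped %in% c("", "0", "00", "NA", "--")
  out[miss] <- MISSING_GT
  todo <- which(!miss)
  if (length(todo)) {
    one <- nchar(stripped[todo]) == 1L
    stripped[todo][one] <- strrep(stripped[todo][one], 2L)
    bad <- nchar(stripped[todo]) != 2L |
      !grepl("^[ACGTacgt]{2}$", stripped[todo])
    if (any(bad)) {
      pqc_stop("invalid_allele", "invalid allele pair(s): %s",
               paste(unique(raw[todo][bad]), collapse = ", "))
    }
    up <- toupper(stripped[todo])
    a1 <- substr(up, 1, 1); a2 <- substr(up, 2, 2)
    swap <- a1 > a2
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    out[todo] <- paste(a1, a2, sep = "/")
  }
  out
}

genotype_alleles <- function(gt) {
  gt <- gt[!is_missing_gt(gt)]
  sort(unique(unlist(strsplit(gt, "/", fixed = TRUE))))
}

new_conversion_map <- function(assay_id, mapping, dialect,
                               snp_id = assay_id, alt_id = NULL) {
  structure(list(assay_id = assay_id, mapping = mapping, dialect = dialect,
                 snp_id = snp_id, alt_id = alt_id, approved = FALSE),
            class = "conversion_map")
}

#' @export
print.conversion_map <- function(x, ...) {
  cat(sprintf("<conversion_map> assay '%s' (%s)%s%s\n", x$assay_id, x$dialect,
              if (x$approved) " [approved]" else " [NOT approved]",
              if (!is.null(x$alt_id)) sprintf(" alt-id %s", x$alt_id) else ""))
  for (tok in names(x$mapping)) {
    cat(sprintf("  %-20s -> %s\n",
                sprintf("'%s'", tok),
                if (is.na(x$mapping[[tok]])) "<unmapped>" else x$mapping[[tok]]))
  }
  invisible(x)
}

#' Infer a conversion map from observed call tokens (unapproved)
#'
#' Suggests the raw-token-to-genotype mapping for one assay, to be reviewed
#' and approved at the second data checkpoint.
#'
#' SDS dialect: the two detector-name tokens are parsed via
#' [parse_detector_designation()]; a conformant detector token maps to the
#' homozygote of its allele, "Both" to the heterozygote of the two alleles,
#' "Undetermined" to missing. Detectors that do not follow the
#' `<name>_<allele>` pattern stay unmapped and force manual completion.
#' TYPER dialect: tokens are read as allele concatenations ("A" homozygote,
#' "AG" heterozygote, "" missing).
#'
#' @param plates list of `plate_result` objects (or one).
#' @param assay_id assay whose tokens to map.
#' @param dialect "SDS" or "TYPER"; defaults to the plates' dialect.
#' @return An unapproved `conversion_map`.
#' @export
infer_conversion_map <- function(plates, assay_id, dialect = NULL) {
  if (inherits(plates, "plate_result")) plates <- list(plates)
  tokens <- unlist(lapply(plates, function(p) {
    p$calls$call_token[p$calls$assay_id == assay_id]
  }))
  if (is.null(dialect)) dialect <- plates[[1]]$dialect
  tokens <- unique(tokens)
  if (!length(tokens)) pqc_stop("empty_input", "no call tokens observed for assay '%s'", assay_id)
  mapping <- stats::setNames(rep(NA_character_, length(tokens)), tokens)
  if (dialect == "SDS") {
    special <- names(mapping) %in% c("Both", "Undetermined")
    det <- parse_detector_designation(names(mapping)[!special])
    conf <- det[det$conformant, , drop = FALSE]
    designations <- unique(paste(conf$assay_name, conf$allele))
    if (length(designations) > 2L) {
      pqc_stop("ambiguous_assay",
               "assay '%s' carries %d distinct detector designations (expected 2): %s",
               assay_id, length(designations),
               paste(conf$detector_name, collapse = ", "))
    }
    for (i in seq_len(nrow(conf))) {
      mapping[conf$detector_name[i]] <- normalize_genotype(strrep(conf$allele[i], 2))
    }
    alleles <- sort(unique(conf$allele))
    if (length(alleles) == 2L) {
      mapping[names(mapping) == "Both"] <- normalize_genotype(paste0(alleles[1], alleles[2]))
    }
    mapping[names(mapping) == "Undetermined"] <- MISSING_GT
  } else {
    # positional assignment: a token may legitimately be "" (TYPER no-call),
    # and name-based indexing never matches the empty string
    for (i in seq_along(mapping)) {
      mapping[[i]] <- tryCatch(normalize_genotype(names(mapping)[i]),
                               plateqc_error = function(e) NA_character_)
    }
  }
  new_conversion_map(assay_id, mapping, dialect)
}

#' Approve a conversion map (checkpoint 2)
#'
#' Applies any manual edits, verifies the mapping is total over the observed
#' tokens, and sets the approved flag. [apply_conversion()] refuses
#' unapproved maps.
#'
#' @param map a `conversion_map`.
#' @param edits named character vector of token -> genotype overrides
#'   (genotypes are normalized; use "0/0" or "" for missing).
#' @param snp_id optional SNP name for the result (defaults to the assay id).
#' @param alt_id optional alternate rs-number used for reference-population
#'   lookup when the SNP's ID changed between dbSNP releases.
#' @return The approved `conversion_map`.
#' @export
approve_conversion <- function(map, edits = NULL, snp_id = NULL, alt_id = NULL) {
  stopifnot(inherits(map, "conversion_map"))
  if (!is.null(edits)) {
    if (is.null(names(edits))) {
      pqc_stop("config", "conversion edits must be a named vector of token = genotype")
    }
    for (tok in names(edits)) {
      i <- match(tok, names(map$mapping))
      if (is.na(i)) {
        map$mapping <- c(map$mapping, stats::setNames(NA_character_, tok))
        i <- length(map$mapping)
      }
      map$mapping[[i]] <- normalize_genotype(edits[[tok]])
    }
  }
  unmapped <- names(map$mapping)[is.na(map$mapping)]
  if (length(unmapped)) {
    pqc_stop("incomplete_map",
             "assay '%s': token(s) still unmapped, manual mapping required: %s",
             map$assay_id, paste(sprintf("'%s'", unmapped), collapse = ", "))
  }
  if (!is.null(snp_id)) map$snp_id <- snp_id
  if (!is.null(alt_id)) map$alt_id <- alt_id
  map$approved <- TRUE
  map
}

new_snp_callset <- function(assay_id, snp_id, calls, alt_id = NULL) {
  rownames(calls) <- NULL
  structure(list(assay_id = assay_id, snp_id = snp_id, alt_id = alt_id,
                 calls = calls),
            class = "snp_callset")
}

#' @export
print.snp_callset <- function(x, ...) {
  cat(sprintf("<snp_callset> %s (assay '%s'): %d calls from %d samples, %d missing\n",
              x$snp_id, x$assay_id, nrow(x$calls),
              length(unique(x$calls$sample_id)),
              sum(is_missing_gt(x$calls$genotype))))
  invisible(x)
}

#' Convert raw calls to genotypes under an approved map
#'
#' Applies checkpoint-1 removals (controls, annulled samples, unknown IDs are
#' dropped), then maps every retained well's raw token through the approved
#' conversion map. Every retained well yields exactly one call; no-calls stay
#' present with the missing genotype.
#'
#' @param plates list of `plate_result` objects.
#' @param study a `study_definition`.
#' @param map an approved `conversion_map`.
#' @param removals the confirmed removal list; defaults to
#'   [propose_removals()] on the same plates.
#' @return A `snp_callset`.
#' @export
apply_conversion <- function(plates, study, map,
                             removals = propose_removals(plates, study)) {
  stopifnot(inherits(map, "conversion_map"))
  if (!isTRUE(map$approved)) {
    pqc_stop("checkpoint", "conversion map for assay '%s' has not been approved", map$assay_id)
  }
  if (inherits(plates, "plate_result")) plates <- list(plates)
  drop_key <- paste(removals$plate_name, removals$well, sep = "\r")
  rows <- lapply(plates, function(p) {
    sel <- p$calls$assay_id == map$assay_id
    calls <- p$calls[sel, , drop = FALSE]
    if (nrow(calls)) {
      keep <- !(paste(p$plate_name, calls$well, sep = "\r") %in% drop_key)
      calls <- calls[keep, , drop = FALSE]
    }
    tok <- calls$call_token
    unknown <- setdiff(unique(tok), names(map$mapping))
    if (length(unknown)) {
      pqc_stop("stale_map",
               "assay '%s': token(s) absent from the approved map (file changed after inference?): %s",
               map$assay_id, paste(sprintf("'%s'", unknown), collapse = ", "))
    }
    data.frame(sample_id = trimws2(calls$sample_id),
               plate_name = rep(p$plate_name, nrow(calls)),
               well = calls$well,
               genotype = unname(map$mapping[match(tok, names(map$mapping))]),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  if (is.null(calls)) {
    calls <- data.frame(sample_id = character(), plate_name = character(),
                        well = character(), genotype = character(),
                        stringsAsFactors = FALSE)
  }
  new_snp_callset(map$assay_id, map$snp_id %||% map$assay_id, calls,
                  alt_id = map$alt_id)
}

#' Group calls into replicate groups
#'
#' Replicates are detected automatically: every sample ID occurring on more
#' than one well forms one replicate group (no naming convention needed).
#' Status per group: `single` (one well), `concordant` (>= 2 usable calls,
#' all equal), `discordant` (>= 2 usable calls, not all equal), `unresolved`
#' (>= 2 wells but < 2 usable calls).
#'
#' @param callset a `snp_callset`.
#' @param majority_vote resolve discordant groups by majority vote instead of
#'   the default conservative missing genotype.
#' @return Data frame, one row per distinct sample ID: `sample_id`,
#'   `n_wells`, `n_usable`, `status`, `resolved` (the consensus genotype).
#' @export
collect_replicates <- function(callset, majority_vote = FALSE) {
  stopifnot(inherits(callset, "snp_callset"))
  gt <- callset$calls$genotype
  id <- callset$calls$sample_id
  ord <- order(factor(id, levels = unique(id)))
  gt <- gt[ord]; id <- id[ord]
  n_wells <- as.integer(table(factor(id, levels = unique(id))))
  usable <- !is_missing_gt(gt)
  groups <- split(gt, factor(id, levels = unique(id)))
  n_usable <- vapply(groups, function(g) sum(!is_missing_gt(g)), integer(1))
  n_distinct <- vapply(groups, function(g) {
    length(unique(g[!is_missing_gt(g)]))
  }, integer(1))
  status <- ifelse(n_wells == 1L, "single",
            ifelse(n_usable >= 2L & n_distinct == 1L, "concordant",
            ifelse(n_usable >= 2L & n_distinct > 1L, "discordant", "unresolved")))
  resolved <- vapply(seq_along(groups), function(i) {
    resolve_replicates(groups[[i]], majority_vote = majority_vote)
  }, character(1))
  data.frame(sample_id = names(groups), n_wells = n_wells,
             n_usable = n_usable, status = status, resolved = resolved,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Resolve a replicate group to one genotype
#'
#' The conservative default: a group with exactly one distinct usable
#' genotype resolves to it; a discordant group resolves to missing, so a
#' disagreement never fabricates a genotype. With `majority_vote = TRUE` a
#' strict majority among usable calls wins (ties stay missing).
#'
#' @param genotypes character vector of the group's genotypes.
#' @param majority_vote use majority rule for discordant groups.
#' @return A single canonical genotype string.
#' @export
resolve_replicates <- function(genotypes, majority_vote = FALSE) {
  usable <- genotypes[!is_missing_gt(genotypes)]
  if (!length(usable)) return(MISSING_GT)
  u <- unique(usable)
  if (length(u) == 1L) return(u)
  if (majority_vote) {
    tab <- sort(table(usable), decreasing = TRUE)
    if (length(tab) == 1L || tab[1] > tab[2]) return(names(tab)[1])
  }
  MISSING_GT
}

#' Build the study genotype matrix
#'
#' Rows are the full study manifest — including samples absent from every
#' plate file, which get the missing genotype — in manifest order; columns
#' are SNPs in import order.
#'
#' @param study a `study_definition`.
#' @param callsets list of `snp_callset` objects (replicate-resolved via
#'   [collect_replicates()] internally).
#' @param majority_vote passed to [collect_replicates()].
#' @return Character matrix sample_id x snp_id of canonical genotypes.
#' @export
build_genotype_matrix <- function(study, callsets, majority_vote = FALSE) {
  stopifnot(inherits(study, "study_definition"))
  if (inherits(callsets, "snp_callset")) callsets <- list(callsets)
  snp_ids <- unname(vapply(callsets, function(cs) cs$snp_id, character(1)))
  if (anyDuplicated(snp_ids)) {
    pqc_stop("name_collision", "duplicate SNP id(s) across callsets: %s",
             paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  }
  mat <- matrix(MISSING_GT, nrow = length(study$sample_ids), ncol = length(callsets),
                dimnames = list(study$sample_ids, snp_ids))
  for (j in seq_along(callsets)) {
    reps <- collect_replicates(callsets[[j]], majority_vote = majority_vote)
    hit <- reps$sample_id %in% study$sample_ids
    mat[reps$sample_id[hit], j] <- reps$resolved[hit]
  }
  mat
}
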