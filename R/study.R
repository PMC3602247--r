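# Study definition and sample-ID classification.
#
# A study is a named sample manifest plus the token sets that label wells not
# belonging to study individuals: controls (non-template / positive controls,
# default "NTC"/"PC") and annulled samples (DNA known to be flawed, default
# "ER"). Classification drives the first data checkpoint: every well whose ID
# is not a study sample is proposed for removal before any conversion.

#' Define a study
#'
#' @param name study name.
#' @param sample_ids path to a manifest file (one ID per line, "#" comments
#'   allowed) or a character vector of IDs. Duplicates are dropped with a
#'   warning, preserving first occurrence.
#' @param expected_replicate_count declared number of replicated samples on
#'   the plates (used to cross-check the auto-detected replicate count).
#' @param control_tokens IDs marking control wells.
#' @param annulled_tokens IDs marking annulled (flawed, to-exclude) samples.
#' @param case_insensitive match IDs case-insensitively (default exact match,
#'   since silent case-folding can merge distinct IDs).
#' @param prefix_tokens also treat IDs with a token prefix ("NTC1", "NTC2") as
#'   control/annulled wells.
#' @return A `study_definition` object.
#' @export
create_study <- function(name, sample_ids, expected_replicate_count = 0L,
                         control_tokens = c("NTC", "PC"),
                         annulled_tokens = "ER",
                         case_insensitive = FALSE,
                         prefix_tokens = FALSE) {
  ids <- clean_lines(as_lines(sample_ids))
  ids <- trimws2(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (!length(ids)) pqc_stop("empty_input", "empty sample manifest for study '%s'", name)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    pqc_warn("duplicate_manifest_ids",
             "manifest for '%s' lists %d ID(s) more than once: %s",
             name, length(dup), paste(utils::head(dup, 10), collapse = ", "))
    ids <- ids[!duplicated(ids)]
  }
  if (length(intersect(control_tokens, annulled_tokens))) {
    pqc_stop("config", "control and annulled token sets overlap: %s",
             paste(intersect(control_tokens, annulled_tokens), collapse = ", "))
  }
  clash <- intersect(ids, c(control_tokens, annulled_tokens))
  if (length(clash)) {
    pqc_stop("config", "manifest ID(s) collide with control/annulled tokens: %s",
             paste(clash, collapse = ", "))
  }
  if (expected_replicate_count < 0) pqc_stop("config", "expected_replicate_count must be >= 0")
  structure(list(
    name = name,
    sample_ids = ids,
    expected_replicate_count = as.integer(expected_replicate_count),
    control_tokens = control_tokens,
    annulled_tokens = annulled_tokens,
    case_insensitive = isTRUE(case_insensitive),
    prefix_tokens = isTRUE(prefix_tokens),
    active = TRUE
  ), class = "study_definition")
}

#' @export
print.study_definition <- function(x, ...) {
  cat(sprintf("<study_definition> '%s': %d samples, %d expected replicates%s\n",
              x$name, length(x$sample_ids), x$expected_replicate_count,
              if (x$active) "" else " [inactive]"))
  cat(sprintf("  control tokens: %s; annulled tokens: %s\n",
              paste(x$control_tokens, collapse = ", "),
              paste(x$annulled_tokens, collapse = ", ")))
  invisible(x)
}

fold_case <- function(x, study) if (study$case_insensitive) toupper(x) else x

matches_token <- function(ids, tokens, study) {
  ids <- fold_case(trimws2(ids), study)
  tokens <- fold_case(tokens, study)
  hit <- ids %in% tokens
  if (study$prefix_tokens && length(tokens)) {
    for (tok in tokens) hit <- hit | startsWith(ids, tok)
  }
  hit
}

#' Classify sample IDs against a study definition
#'
#' Membership is tested in order: annulled tokens, then control tokens, then
#' the study manifest; anything else is unknown. The four classes are
#' exhaustive and mutually exclusive.
#'
#' @param ids character vector of IDs as they appear on plates.
#' @param study a `study_definition`.
#' @return Character vector over
#'   `c("annulled", "control", "study_sample", "unknown")`.
#' @export
classify_id <- function(ids, study) {
  stopifnot(inherits(study, "study_definition"))
  out <- rep("unknown", length(ids))
  samp <- fold_case(trimws2(ids), study) %in% fold_case(study$sample_ids, study)
  out[samp] <- "study_sample"
  out[matches_token(ids, study$control_tokens, study)] <- "control"
  out[matches_token(ids, study$annulled_tokens, study)] <- "annulled"
  out
}

#' Propose wells for removal (checkpoint 1)
#'
#' Lists every (plate, well) whose sample ID is not a study sample — control
#' wells, annulled samples and unknown IDs — exactly once per well. This list
#' is the first data checkpoint of the import workflow and must be confirmed
#' before genotype conversion.
#'
#' @param plates list of `plate_result` objects.
#' @param study a `study_definition`.
#' @return Data frame with columns `sample_id`, `plate_name`, `well`, `klass`.
#' @export
propose_removals <- function(plates, study) {
  if (inherits(plates, "plate_result")) plates <- list(plates)
  rows <- lapply(plates, function(p) {
    wells <- p$calls[!duplicated(p$calls$well), c("well", "sample_id")]
    klass <- classify_id(wells$sample_id, study)
    keep <- klass != "study_sample"
    data.frame(sample_id = wells$sample_id[keep],
               plate_name = rep(p$plate_name, sum(keep)),
               well = wells$well[keep],
               klass = klass[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), plate_name = character(),
                      well = character(), klass = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Manifest samples absent from all plate files
#'
#' Samples in the study manifest with no well on any uploaded plate (e.g. a
#' well excluded from the scan). These samples must still appear in final
#' genotype lists with the missing code and count in call-rate denominators,
#' otherwise QC values are distorted.
#'
#' @param study a `study_definition`.
#' @param plates list of `plate_result` objects.
#' @return Character vector of manifest IDs, in manifest order.
#' @export
missing_samples <- function(study, plates) {
  if (inherits(plates, "plate_result")) plates <- list(plates)
  seen <- unique(unlist(lapply(plates, function(p) trimws2(p$calls$sample_id))))
  seen <- fold_case(seen, study)
  study$sample_ids[!(fold_case(study$sample_ids, study) %in% seen)]
}
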