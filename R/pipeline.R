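# Batch orchestration of the four-step import wizard and the project store.
#
# The store is a versioned project directory (JSON metadata plus
# delimiter-separated call tables) rather than a relational database: the
# artifact is a single-user batch tool, and a plain directory is
# zero-install, diff-able and easy to back up. Layout:
#
#   <root>/studies/<study>.json
#   <root>/results/<study>/<result_group>/<snp>.json   (QC report + map)
#   <root>/results/<study>/<result_group>/<snp>.calls.tsv
#   <root>/sex_checks/<study>/<snp>.json               (discordances only)
#
# Imports are atomic: everything is staged in a temporary directory and moved
# into place only after both checkpoints pass; a refusal or error leaves the
# store untouched.

#' Open (or initialize) a project store
#'
#' @param root directory; created if absent.
#' @return A `project_store` handle.
#' @export
open_store <- function(root) {
  for (d in c(root, file.path(root, "studies"), file.path(root, "results"),
              file.path(root, "sex_checks"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  structure(list(root = normalizePath(root)), class = "project_store")
}

#' @export
print.project_store <- function(x, ...) {
  studies <- list.files(file.path(x$root, "studies"))
  cat(sprintf("<project_store> %s: %d stud%s\n", x$root, length(studies),
              if (length(studies) == 1) "y" else "ies"))
  invisible(x)
}

study_path <- function(store, name) {
  file.path(store$root, "studies", paste0(gsub("[^A-Za-z0-9_.-]", "_", name), ".json"))
}

#' Save a study definition in the store
#' @param store a `project_store`.
#' @param study a `study_definition`.
#' @export
save_study <- function(store, study) {
  stopifnot(inherits(store, "project_store"), inherits(study, "study_definition"))
  jsonlite::write_json(unclass(study), study_path(store, study$name),
                       auto_unbox = TRUE, digits = NA)
  invisible(study_path(store, study$name))
}

#' Load a study definition from the store
#' @param store a `project_store`.
#' @param name study name.
#' @export
load_study <- function(store, name) {
  path <- study_path(store, name)
  if (!file.exists(path)) pqc_stop("not_found", "study '%s' not found in store", name)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$sample_ids <- as.character(x$sample_ids)
  structure(x, class = "study_definition")
}

#' Deactivate (hide) or reactivate a study
#' @param store a `project_store`.
#' @param name study name.
#' @param active new activation state.
#' @export
deactivate_study <- function(store, name, active = FALSE) {
  study <- load_study(store, name)
  study$active <- isTRUE(active)
  save_study(store, study)
  invisible(study)
}

result_dir <- function(store, study_name, result_group) {
  file.path(store$root, "results",
            gsub("[^A-Za-z0-9_.-]", "_", study_name),
            gsub("[^A-Za-z0-9_.-]", "_", result_group))
}

result_paths <- function(dir, snp_id) {
  base <- gsub("[^A-Za-z0-9_.-]", "_", snp_id)
  c(meta = file.path(dir, paste0(base, ".json")),
    calls = file.path(dir, paste0(base, ".calls.tsv")))
}

#' Save one SNP result (callset + QC report) in the store
#'
#' @param store a `project_store`.
#' @param study_name,result_group storage location; mass-array multiplex
#'   imports group their assays under one result-group folder, single-assay
#'   imports store under a group of the same name as the result.
#' @param callset a `snp_callset`.
#' @param report a `qc_report`.
#' @param overwrite replace an existing result of the same name.
#' @export
save_result <- function(store, study_name, result_group, callset, report,
                        overwrite = FALSE) {
  stopifnot(inherits(callset, "snp_callset"), inherits(report, "qc_report"))
  dir <- result_dir(store, study_name, result_group)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- result_paths(dir, callset$snp_id)
  if (file.exists(paths["meta"]) && !overwrite) {
    pqc_stop("name_collision",
             "result '%s' already exists in group '%s' (use overwrite)",
             callset$snp_id, result_group)
  }
  meta <- list(snp_id = callset$snp_id, assay_id = callset$assay_id,
               alt_id = callset$alt_id,
               report = unclass(report)[QC_REPORT_FIELDS],
               counts = unclass(report$counts))
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  utils::write.table(callset$calls, paths["calls"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Load one SNP result from the store
#' @inheritParams save_result
#' @param snp_id result name.
#' @return List with `callset` and `report`.
#' @export
load_result <- function(store, study_name, result_group, snp_id) {
  paths <- result_paths(result_dir(store, study_name, result_group), snp_id)
  if (!file.exists(paths["meta"])) {
    pqc_stop("not_found", "result '%s' not found in group '%s'", snp_id, result_group)
  }
  meta <- jsonlite::read_json(paths["meta"], simplifyVector = TRUE)
  calls <- utils::read.delim(paths["calls"], stringsAsFactors = FALSE,
                             colClasses = "character")
  rep_fields <- meta$report
  rep_fields[vapply(rep_fields, is.null, logical(1))] <- NA
  report <- structure(rep_fields, class = "qc_report")
  report$counts <- do.call(as_genotype_counts, meta$counts[c(
    "n_AA", "n_AB", "n_BB", "allele1", "allele2", "n_missing")])
  list(callset = new_snp_callset(meta$assay_id, meta$snp_id, calls,
                                 alt_id = meta$alt_id),
       report = report)
}

#' List stored results of a study
#' @param store a `project_store`.
#' @param study_name study name.
#' @return Data frame with `result_group` and `snp_id`.
#' @export
list_results <- function(store, study_name) {
  base <- file.path(store$root, "results", gsub("[^A-Za-z0-9_.-]", "_", study_name))
  metas <- list.files(base, pattern = "\\.json$", recursive = TRUE)
  if (!length(metas)) {
    return(data.frame(result_group = character(), snp_id = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(result_group = dirname(metas),
             snp_id = sub("\\.json$", "", basename(metas)),
             stringsAsFactors = FALSE)
}

#' Search stored results by SNP id or result-group substring
#'
#' Case-insensitive substring match, so "rs20712" finds "rs2071204".
#' @inheritParams list_results
#' @param query substring.
#' @export
search_results <- function(store, study_name, query) {
  res <- list_results(store, study_name)
  hit <- grepl(query, res$snp_id, ignore.case = TRUE, fixed = FALSE) |
    grepl(query, res$result_group, ignore.case = TRUE, fixed = FALSE)
  res[hit, , drop = FALSE]
}

#' Delete a stored result
#' @inheritParams load_result
#' @export
delete_result <- function(store, study_name, result_group, snp_id) {
  paths <- result_paths(result_dir(store, study_name, result_group), snp_id)
  if (!file.exists(paths["meta"])) {
    pqc_stop("not_found", "result '%s' not found in group '%s'", snp_id, result_group)
  }
  unlink(paths)
  invisible(TRUE)
}

confirm_checkpoint <- function(prompt, auto_approve, interactive_ok) {
  if (auto_approve) return(TRUE)
  if (interactive_ok && interactive()) {
    ans <- readline(paste0(prompt, " [y/N] "))
    return(tolower(trimws2(ans)) %in% c("y", "yes"))
  }
  FALSE
}

#' Run the four-step import workflow
#'
#' Steps: (1) parse the uploaded plate file(s)/archive and merge them;
#' (2) checkpoint 1 — the removal proposal (controls, annulled samples,
#' unknown IDs) must be confirmed; (3) infer one conversion map per assay and
#' pass checkpoint 2 — each map must be approved (optionally after manual
#' edits); (4) convert, resolve replicates, compute QC and persist. A refusal
#' at either checkpoint, or any error, aborts with nothing persisted.
#'
#' @param store a `project_store`.
#' @param study_name name of a stored study (see [save_study()]).
#' @param input plate file, zip archive, directory, or vector of files.
#' @param result_group name under which multiplexed results are grouped.
#' @param operator,comment report metadata.
#' @param auto_approve accept both checkpoints non-interactively.
#' @param conversion_edits named list: assay id -> named token/genotype
#'   overrides applied before approval.
#' @param alt_rs_ids named character vector assay id -> alternate rs-number
#'   for reference lookups.
#' @param overwrite replace existing results of the same name.
#' @param append merge the new calls into an existing stored result of the
#'   same group/SNP and recompute its QC (partial imports of a large study).
#' @return Invisibly, a named list of `list(callset, report)` per SNP.
#' @export
run_import <- function(store, study_name, input, result_group = "default",
                       operator = "", comment = "",
                       auto_approve = FALSE, conversion_edits = list(),
                       alt_rs_ids = character(0), overwrite = FALSE,
                       append = FALSE) {
  study <- load_study(store, study_name)
  plates <- read_plates(input)

  removals <- propose_removals(plates, study)
  if (!confirm_checkpoint(
    sprintf("Checkpoint 1: remove %d non-study well(s)?", nrow(removals)),
    auto_approve, interactive_ok = TRUE)) {
    pqc_stop("checkpoint", "import aborted at checkpoint 1 (removal list not confirmed)")
  }

  assays <- unique(unlist(lapply(plates, function(p) p$calls$assay_id)))
  maps <- lapply(assays, function(a) {
    m <- infer_conversion_map(plates, a)
    approve_conversion(m, edits = conversion_edits[[a]],
                       alt_id = if (a %in% names(alt_rs_ids)) alt_rs_ids[[a]] else NULL)
  })
  if (!confirm_checkpoint(
    sprintf("Checkpoint 2: approve %d conversion map(s)?", length(maps)),
    auto_approve, interactive_ok = TRUE)) {
    pqc_stop("checkpoint", "import aborted at checkpoint 2 (conversions not approved)")
  }

  # stage results, then move into the store only when every SNP succeeded
  results <- list()
  for (m in maps) {
    cs <- apply_conversion(plates, study, m, removals = removals)
    if (append) {
      existing <- tryCatch(load_result(store, study_name, result_group, m$snp_id),
                           plateqc_not_found = function(e) NULL)
      if (!is.null(existing)) {
        cs$calls <- rbind(existing$callset$calls, cs$calls)
        rownames(cs$calls) <- NULL
      }
    }
    groups <- collect_replicates(cs)
    absent <- study$sample_ids[!study$sample_ids %in% groups$sample_id]
    gts <- stats::setNames(rep(MISSING_GT, length(study$sample_ids)), study$sample_ids)
    gts[groups$sample_id[groups$sample_id %in% names(gts)]] <-
      groups$resolved[groups$sample_id %in% names(gts)]
    alleles <- genotype_alleles(m$mapping)
    report <- build_qc_report(m$snp_id, gts, groups, alleles = alleles,
                              operator = operator, comment = comment)
    results[[m$snp_id]] <- list(callset = cs, report = report)
  }
  dir <- result_dir(store, study_name, result_group)
  for (snp in names(results)) {
    paths <- result_paths(dir, snp)
    if (file.exists(paths["meta"]) && !overwrite && !append) {
      pqc_stop("name_collision",
               "result '%s' already exists in group '%s' (use overwrite or append)",
               snp, result_group)
    }
  }
  for (snp in names(results)) {
    save_result(store, study_name, result_group, results[[snp]]$callset,
                results[[snp]]$report, overwrite = overwrite || append)
  }
  invisible(results)
}

#' Persist a sex-discordance report (discordances only)
#'
#' Stores only the `sex_check` discordance records and summary counts —
#' never the uploaded phenotype file — so sensitive phenotype data is not
#' kept next to genotypes.
#'
#' @param store a `project_store`.
#' @param study_name study name.
#' @param snp_id sex-marker SNP.
#' @param check a `sex_check` object.
#' @export
save_sex_check <- function(store, study_name, snp_id, check) {
  stopifnot(inherits(check, "sex_check"))
  dir <- file.path(store$root, "sex_checks", gsub("[^A-Za-z0-9_.-]", "_", study_name))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", snp_id), ".json"))
  jsonlite::write_json(list(snp_id = snp_id,
                            discordances = check$discordances,
                            summary = check$summary),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
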