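# Reading, sniffing and merging plate export files.
#
# Two delimiter-separated dialects are supported, mirroring the exports of
# endpoint allelic-discrimination software (the "SDS" dialect, one file per
# plate, columns Well / Sample Name / Marker / Call) and multiplexed
# mass-array plate software (the "TYPER" dialect, one file holding many
# plates and assays, columns Plate / Well / Sample Id / Assay Id / Genotype).

WELL_ROWS <- LETTERS[1:16]
WELL_COLS <- 1:24

#' Parse and canonicalize 384-well addresses
#'
#' A well address is a row letter A-P followed by a column number 1-24.
#' Zero-padded columns ("A01") are accepted and canonicalized to the unpadded
#' form ("A1").
#'
#' @param x character vector of well addresses.
#' @return Character vector of canonical addresses; invalid entries are `NA`.
#' @examples
#' parse_well(c("A1", "a01", "P24", "Q1", "A25"))
#' @export
parse_well <- function(x) {
  x <- toupper(trimws2(as.character(x)))
  m <- regmatches(x, regexec("^([A-P])0*([1-9][0-9]?)$", x))
  vapply(m, function(p) {
    if (length(p) != 3L) return(NA_character_)
    col <- as.integer(p[3])
    if (col < 1L || col > 24L) return(NA_character_)
    paste0(p[2], col)
  }, character(1))
}

new_plate_result <- function(plate_name, dialect, calls) {
  stopifnot(dialect %in% c("SDS", "TYPER"))
  rownames(calls) <- NULL
  structure(
    list(plate_name = plate_name, dialect = dialect, calls = calls),
    class = "plate_result"
  )
}

#' @export
print.plate_result <- function(x, ...) {
  cat(sprintf("<plate_result> %s [%s dialect]: %d calls, %d wells, %d assays\n",
              x$plate_name, x$dialect, nrow(x$calls),
              length(unique(x$calls$well)), length(unique(x$calls$assay_id))))
  invisible(x)
}

# Split a header/data line on the sniffed delimiter.
split_fields <- function(lines, sep) {
  strsplit(lines, sep, fixed = TRUE)
}

sniff_sep <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

first_data_line <- function(lines, skip_comments = TRUE) {
  keep <- nzchar(trimws2(lines))
  if (skip_comments) keep <- keep & !startsWith(trimws2(lines), "#")
  idx <- which(keep)
  if (!length(idx)) NULL else idx[1]
}

#' Sniff the dialect of a plate export
#'
#' Decides between the two supported dialects from the header row: a column
#' named "Marker" marks the SDS dialect, "Assay Id" the TYPER dialect.
#'
#' @param x file path, single string with newlines, or character vector of lines.
#' @return `"SDS"` or `"TYPER"`.
#' @export
sniff_format <- function(x) {
  lines <- clean_lines(as_lines(x))
  i <- first_data_line(lines)
  if (is.null(i)) pqc_stop("empty_input", "empty stream: no header line found")
  header <- trimws2(split_fields(lines[i], sniff_sep(lines[i]))[[1]])
  if ("Marker" %in% header) return("SDS")
  if ("Assay Id" %in% header) return("TYPER")
  pqc_stop("format",
           "unrecognized plate file header [%s]: expected a column 'Marker' (SDS dialect) or 'Assay Id' (TYPER dialect)",
           paste(header, collapse = ", "))
}

# Parse a delimiter-separated table given required column names.
# Returns a data.frame of character columns plus the source line numbers.
read_dialect_table <- function(lines, required, skip_comments) {
  lines <- clean_lines(lines)
  keep <- nzchar(trimws2(lines))
  if (skip_comments) keep <- keep & !startsWith(trimws2(lines), "#")
  idx <- which(keep)
  if (!length(idx)) pqc_stop("empty_input", "empty stream: no header line found")
  sep <- sniff_sep(lines[idx[1]])
  fields <- split_fields(lines[idx], sep)
  header <- trimws2(fields[[1]])
  miss <- setdiff(required, header)
  if (length(miss)) {
    pqc_stop("format", "missing required column(s): %s", paste(miss, collapse = ", "))
  }
  data_idx <- idx[-1]
  fields <- fields[-1]
  n <- length(fields)
  out <- vector("list", length(required))
  names(out) <- required
  pos <- match(required, header)
  for (j in seq_along(required)) {
    out[[j]] <- vapply(fields, function(f) {
      if (pos[j] <= length(f)) trimws2(f[pos[j]]) else ""
    }, character(1))
  }
  out <- as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- required
  out$.line <- data_idx
  out
}

#' Read a plate export in the SDS dialect
#'
#' One file corresponds to one plate. Call tokens are captured verbatim: a
#' detector name for a homozygote, "Both" for a heterozygote, "Undetermined"
#' for a no-call. Lines starting with "#" are comments.
#'
#' @param x file path or lines (see [sniff_format()]).
#' @param plate_name plate label; defaults to the file name without extension.
#' @return A `plate_result` object.
#' @export
read_sds_export <- function(x, plate_name = NULL) {
  if (is.null(plate_name)) {
    plate_name <- if (length(x) == 1L && file.exists(x)) {
      tools::file_path_sans_ext(basename(x))
    } else "plate"
  }
  tab <- read_dialect_table(as_lines(x),
                            c("Well", "Sample Name", "Marker", "Call"),
                            skip_comments = TRUE)
  well <- parse_well(tab$Well)
  if (anyNA(well)) {
    bad <- which(is.na(well))[1]
    pqc_stop("parse", "malformed well address '%s' at line %d",
             tab$Well[bad], tab$.line[bad])
  }
  key <- paste(well, tab$Marker, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    pqc_stop("duplicate_well", "duplicate (well, marker) row: %s",
             sub("\r", " / ", dup, fixed = TRUE))
  }
  calls <- data.frame(well = well,
                      sample_id = tab[["Sample Name"]],
                      assay_id = tab$Marker,
                      call_token = tab$Call,
                      stringsAsFactors = FALSE)
  new_plate_result(plate_name, "SDS", calls)
}

#' Read a plate export in the TYPER dialect
#'
#' A single file may carry several plates and several multiplexed assays; rows
#' are grouped by the Plate column into one `plate_result` per plate. The
#' Genotype column is captured verbatim ("AG", "A", or empty for no call).
#'
#' @param x file path or lines.
#' @return A list of `plate_result` objects, in order of first appearance.
#' @export
read_typer_export <- function(x) {
  tab <- read_dialect_table(as_lines(x),
                            c("Plate", "Well", "Sample Id", "Assay Id", "Genotype"),
                            skip_comments = TRUE)
  if (any(!nzchar(tab$Plate))) {
    bad <- which(!nzchar(tab$Plate))[1]
    pqc_stop("parse", "missing Plate value at line %d", tab$.line[bad])
  }
  well <- parse_well(tab$Well)
  if (anyNA(well)) {
    bad <- which(is.na(well))[1]
    pqc_stop("parse", "malformed well address '%s' at line %d",
             tab$Well[bad], tab$.line[bad])
  }
  key <- paste(tab$Plate, well, tab[["Assay Id"]], sep = "\r")
  if (anyDuplicated(key)) {
    dup <- strsplit(key[duplicated(key)][1], "\r", fixed = TRUE)[[1]]
    pqc_stop("duplicate_well", "duplicate (plate, well, assay) row: %s / %s / %s",
             dup[1], dup[2], dup[3])
  }
  plates <- unique(tab$Plate)
  lapply(plates, function(p) {
    sel <- tab$Plate == p
    new_plate_result(p, "TYPER", data.frame(
      well = well[sel],
      sample_id = tab[["Sample Id"]][sel],
      assay_id = tab[["Assay Id"]][sel],
      call_token = tab$Genotype[sel],
      stringsAsFactors = FALSE))
  })
}

#' Read plate exports from a zip archive, directory, or file set
#'
#' All members must parse under one sniffed dialect; mixing SDS and TYPER
#' members in one archive is an error. SDS plate names default to the member
#' file name; TYPER plate names come from the Plate column.
#'
#' @param path a .zip archive, a directory, or a character vector of files.
#' @return List of `plate_result` objects (concatenated, order-preserved).
#' @export
read_archive <- function(path) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
  } else if (length(path) == 1L && grepl("\\.zip$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) pqc_stop("io", "archive not found: %s", path)
    exdir <- tempfile("plateqc_zip_")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    members <- utils::unzip(path, list = TRUE)$Name
    if (!length(members)) pqc_stop("empty_input", "empty archive: %s", path)
    utils::unzip(path, exdir = exdir)
    files <- file.path(exdir, members)
  } else {
    files <- path
  }
  files <- files[!dir.exists(files)]
  if (!length(files)) pqc_stop("empty_input", "no plate files found")
  dialects <- vapply(files, function(f) {
    tryCatch(sniff_format(f), error = function(e) {
      pqc_stop("member", "unreadable member '%s': %s", basename(f), conditionMessage(e))
    })
  }, character(1))
  if (length(unique(dialects)) > 1L) {
    pqc_stop("mixed_format", "archive mixes dialects: %s",
             paste(sprintf("%s (%s)", basename(files), dialects), collapse = ", "))
  }
  out <- list()
  for (f in files) {
    res <- tryCatch({
      if (dialects[[1]] == "SDS") list(read_sds_export(f)) else read_typer_export(f)
    }, plateqc_error = function(e) {
      pqc_stop("member", "error in member '%s': %s", basename(f), conditionMessage(e))
    })
    out <- c(out, res)
  }
  out
}

#' Read plate files of any supported shape
#'
#' Convenience front end used by the pipeline: dispatches to [read_archive()]
#' for zips/directories/file sets and to the single-file readers otherwise.
#' Always returns a list of `plate_result`.
#' @param path input path(s).
#' @export
read_plates <- function(path) {
  if (length(path) > 1L || dir.exists(path[1]) ||
      grepl("\\.zip$", path[1], ignore.case = TRUE)) {
    return(read_archive(path))
  }
  if (sniff_format(path) == "SDS") list(read_sds_export(path)) else read_typer_export(path)
}

#' Parse a detector designation
#'
#' Allelic-discrimination detector names are expected to follow the pattern
#' `<arbitrary detector name>_<allele>` (e.g. "rs328_G", "LPL-rs328_G"): the
#' name is split on the LAST underscore and the trailing token must be a
#' single base A/C/G/T (case-insensitive). Non-conformant names yield an
#' undetermined designation (never an error) and require a manual conversion
#' mapping downstream.
#'
#' @param detector_name character vector of detector names.
#' @return Data frame with columns `detector_name`, `assay_name`, `allele`,
#'   `conformant`; `assay_name`/`allele` are `NA` for non-conformant names.
#' @examples
#' parse_detector_designation(c("rs328_G", "LPL-rs328_G", "FAM-probe"))
#' @export
parse_detector_designation <- function(detector_name) {
  detector_name <- as.character(detector_name)
  m <- regmatches(detector_name,
                  regexec("^(.*)_([ACGTacgt])$", detector_name))
  assay <- vapply(m, function(p) if (length(p) == 3L && nzchar(p[2])) p[2] else NA_character_,
                  character(1))
  allele <- vapply(m, function(p) if (length(p) == 3L && nzchar(p[2])) toupper(p[3]) else NA_character_,
                   character(1))
  data.frame(detector_name = detector_name,
             assay_name = assay,
             allele = allele,
             conformant = !is.na(allele),
             stringsAsFactors = FALSE)
}
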