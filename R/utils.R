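# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a condition class of the form
#' "plateqc_<kind>" so callers (and tests) can distinguish failure modes.
#' @noRd
pqc_stop <- function(kind, msg, ...) {
  stop(structure(
    class = c(paste0("plateqc_", kind), "plateqc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

pqc_warn <- function(kind, msg, ...) {
  warning(structure(
    class = c(paste0("plateqc_", kind), "plateqc_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Read lines from a path or pass through a character vector
#'
#' Every reader in the package accepts either a file path or the file's lines
#' as a character vector, so tests and fixtures can stay in memory.
#' @noRd
as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }
}

# Strip UTF-8 BOM and trailing CR (files written on Windows instruments).
clean_lines <- function(lines) {
  lines <- sub("\r$", "", lines)
  if (length(lines)) lines[1] <- sub("^﻿", "", lines[1])
  lines
}

trimws2 <- function(x) trimws(x, which = "both")

is_missing_gt <- function(g) is.na(g) | g == "0/0" | g == ""

#' Derive an independent RNG sub-stream seed
#'
#' Each stochastic stage of the fixture generator seeds its own sub-stream so
#' changing one stage's parameters does not shift the draws of another.
#' @noRd
sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1009L + stream * 7919L
}
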