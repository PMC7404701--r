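# Peptide-activity database: a local, validated stand-in for the
# BIOPEP-UWM bioactive-peptide table.
#
# TSV dialect: tab-separated, UTF-8, header row with columns
#   peptide  activity_code  activity_name  ic50_value  ic50_unit  reference
# (the last four optional). One row per (peptide, activity) association.

.db_columns <- c("peptide", "activity_code", "activity_name",
                 "ic50_value", "ic50_unit", "reference")

#' Construct a peptide-activity database
#'
#' @param records Data frame with columns `peptide` and `activity_code`
#'   (required) plus optional `activity_name`, `ic50_value`, `ic50_unit`,
#'   `reference`. Peptides must pass strict canonicalization;
#'   (peptide, activity_code) pairs must be unique.
#' @return An object of class `peptide_activity_db` holding the validated
#'   `records` and an `index` mapping activity code to its peptide set.
#' @export
activity_db <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(c("peptide", "activity_code"), names(records))
  if (length(missing_cols)) {
    stop("activity table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in .db_columns) {
    if (!col %in% names(records)) {
      records[[col]] <- rep(if (col == "ic50_value") NA_real_
                            else NA_character_, nrow(records))
    }
  }
  records <- records[, .db_columns, drop = FALSE]
  records$peptide <- as.character(records$peptide)
  records$activity_code <- as.character(records$activity_code)
  records$ic50_value <- as.numeric(records$ic50_value)
  if (nrow(records)) {
    for (i in seq_len(nrow(records))) {
      pep <- records$peptide[i]
      ok <- tryCatch(identical(canonicalize_sequence(pep), pep),
                     error = function(e) FALSE)
      if (!ok) stop(sprintf("row %d: invalid peptide '%s'", i, pep))
      if (is.na(records$activity_code[i]) || !nzchar(records$activity_code[i])) {
        stop(sprintf("row %d: empty activity code", i))
      }
    }
    key <- paste(records$peptide, records$activity_code, sep = "\r")
    if (anyDuplicated(key)) {
      dups <- unique(key[duplicated(key)])
      warning(sprintf("collapsed %d duplicate (peptide, activity) row(s)",
                      sum(duplicated(key))))
      records <- records[!duplicated(key), , drop = FALSE]
    }
    ord <- order(records$activity_code, records$peptide, method = "radix")
    records <- records[ord, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(
    list(records = records,
         index = split(records$peptide, records$activity_code)),
    class = "peptide_activity_db"
  )
}

#' @export
print.peptide_activity_db <- function(x, ...) {
  cat(sprintf("<peptide_activity_db> %d record(s), %d peptide(s), %d activity code(s)\n",
              nrow(x$records), length(unique(x$records$peptide)),
              length(x$index)))
  invisible(x)
}

#' Load a peptide-activity table from TSV
#'
#' Validates every row (strict 20-letter peptides, non-empty activity codes)
#' and collapses duplicated (peptide, activity) rows with a warning.
#'
#' @param path TSV file with the documented header.
#' @return A [activity_db()] object.
#' @export
load_activity_table <- function(path) {
  if (!file.exists(path)) stop("activity table not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = c("NA", ""), check.names = FALSE)
  missing_cols <- setdiff(c("peptide", "activity_code"), names(raw))
  if (length(missing_cols)) {
    stop("activity table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  tryCatch(activity_db(raw), error = function(e) {
    stop(sprintf("%s (line numbers follow the header row)", conditionMessage(e)),
         call. = FALSE)
  })
}

#' Export a peptide-activity database to TSV
#'
#' Emits the same dialect that [load_activity_table()] reads, so that
#' load and export round-trip the record set exactly.
#'
#' @param db A [activity_db()] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_activity_table <- function(db, path) {
  stopifnot(inherits(db, "peptide_activity_db"))
  utils::write.table(db$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundled ACE / DPP-IV inhibitor database
#'
#' The nine short collagen-derived peptides reported as ACE inhibitors
#' (code `ah`) and/or DPP-IV inhibitors (code `dpp`), with literature IC50
#' metadata where available. Shipped as a reproducible stand-in for a full
#' bioactive-peptide database snapshot, which cannot be redistributed; any
#' snapshot in the documented TSV format can be used instead.
#'
#' @return A [activity_db()] object with 9 peptides.
#' @examples
#' db <- builtin_fixture()
#' peptides_for_activity(db, "ah")
#' @export
builtin_fixture <- function() {
  path <- system.file("extdata", "ace_dppiv_fixture.tsv",
                      package = "biopepsim", mustWork = TRUE)
  load_activity_table(path)
}

#' Peptides carrying a given activity code
#'
#' @param db A [activity_db()] object.
#' @param activity_code Activity code (case-sensitive). Unknown codes return
#'   an empty set, not an error.
#' @return Sorted character vector of peptide sequences.
#' @export
peptides_for_activity <- function(db, activity_code) {
  stopifnot(inherits(db, "peptide_activity_db"),
            is.character(activity_code), length(activity_code) == 1L)
  sort(unique(db$index[[activity_code]] %||% character(0)))
}

#' Activity codes present in a database
#'
#' @param db A [activity_db()] object.
#' @return Sorted character vector of activity codes.
#' @export
activity_codes <- function(db) {
  stopifnot(inherits(db, "peptide_activity_db"))
  sort(names(db$index))
}
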