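# Report writers.
#
# Formatted (TSV) tables follow the reporting conventions of the release
# parameters: A, A_E and W printed with 3 decimals, DH_t with 2; values
# that round to 0.000 are blanked, and rows whose A_E and W both blank are
# dropped (an activity can retain a visible W while its A_E rounds away).
# Undefined W (A == 0) is a blank cell in TSV and an explicit null in JSON.
# Machine-readable (JSON) output keeps full precision.

.fmt3 <- function(x) ifelse(is.na(x) | round(x, 3) == 0, "", sprintf("%.3f", x))

#' Occurrence report table
#'
#' Table of protein x activity with `a`, `A` (3 decimals) and the bin;
#' activities whose A rounds to 0.000 are omitted.
#'
#' @param occurrence The `occurrence` element of a [run_pipeline()] result.
#' @return Data frame of formatted character columns.
#' @export
format_occurrence_table <- function(occurrence) {
  if (!nrow(occurrence)) {
    return(data.frame(protein_id = character(0),
                      activity_code = character(0), a = integer(0),
                      A = character(0), bin = character(0)))
  }
  keep <- round(occurrence$A, 3) > 0
  df <- occurrence[keep, , drop = FALSE]
  out <- data.frame(protein_id = df$protein_id,
                    activity_code = df$activity_code,
                    a = df$a_count, A = .fmt3(df$A), bin = df$bin,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Release report table
#'
#' Table of protein x enzyme set x activity with `d`, `A_E`, `W`
#' (3 decimals; cells rounding to 0.000 blanked) and DH_t (2 decimals)
#' repeated per protein x enzyme set.
#'
#' @param release,dh The `release` and `dh` elements of a [run_pipeline()]
#'   result.
#' @return Data frame of formatted character columns.
#' @export
format_release_table <- function(release, dh) {
  if (!nrow(release)) {
    return(data.frame(protein_id = character(0), enzymes = character(0),
                      activity_code = character(0), d = integer(0),
                      A_E = character(0), W = character(0),
                      DH_t = character(0)))
  }
  ae <- .fmt3(release$A_E)
  w <- .fmt3(release$W)
  keep <- nzchar(ae) | nzchar(w)
  key <- paste(release$protein_id, release$enzymes)
  dh_key <- paste(dh$protein_id, dh$enzymes)
  out <- data.frame(protein_id = release$protein_id,
                    enzymes = release$enzymes,
                    activity_code = release$activity_code,
                    d = release$d_count, A_E = ae, W = w,
                    DH_t = sprintf("%.2f", dh$dh_t[match(key, dh_key)]),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pipeline reports
#'
#' Writes the occurrence, DH_t, release, released-peptide and (if present)
#' chemistry tables plus the run manifest into a directory. With
#' `format = "tsv"` the formatted tables use the rounding/omission
#' conventions above; with `format = "json"` full-precision values are
#' written (undefined W as null). Output is deterministic: identical
#' inputs give byte-identical files.
#'
#' @param results A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"json"`.
#' @return Invisible character vector of written paths.
#' @export
write_report <- function(results, dir, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(results, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, name) {
    if (format == "tsv") {
      path <- file.path(dir, paste0(name, ".tsv"))
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
    } else {
      path <- file.path(dir, paste0(name, ".json"))
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
    }
    paths <<- c(paths, path)
  }
  if (format == "tsv") {
    wr(format_occurrence_table(results$occurrence), "occurrence")
    wr(format_release_table(results$release, results$dh), "release")
    dh <- results$dh
    dh$dh_t <- sprintf("%.2f", dh$dh_t)
    wr(dh, "dh_t")
    wr(results$released_peptides, "released_peptides")
    if (!is.null(results$chem)) {
      chem <- results$chem
      chem$mw <- sprintf("%.2f", chem$mw)
      chem$logp <- sprintf("%.2f", chem$logp)
      wr(chem, "chem")
    }
  } else {
    wr(results$occurrence, "occurrence")
    wr(results$release, "release")
    wr(results$dh, "dh_t")
    wr(results$released_peptides, "released_peptides")
    if (!is.null(results$chem)) wr(results$chem, "chem")
  }
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(results$manifest, man_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, man_path)
  invisible(paths)
}
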