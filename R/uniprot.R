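# Optional UniProt retrieval. Network-dependent convenience; every core
# computation in the package works from local or synthetic FASTA.

uniprot_base <- "https://rest.uniprot.org/uniprotkb"

#' Fetch UniProt entries as FASTA
#'
#' Downloads one or more entries from the UniProt REST service and returns
#' them as protein records (optionally also writing a standard FASTA file).
#' Requires network access; errors promptly when the service is unreachable.
#'
#' @param accessions Character vector of UniProt accession numbers.
#' @param path Optional output FASTA path.
#' @param timeout Per-request timeout in seconds.
#' @return List of [protein_record()] objects, ids set to the accessions.
#' @export
fetch_uniprot <- function(accessions, path = NULL, timeout = 30) {
  stopifnot(is.character(accessions), length(accessions) >= 1L)
  recs <- lapply(accessions, function(acc) {
    url <- sprintf("%s/%s.fasta", uniprot_base, acc)
    txt <- .http_get(url, timeout)
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    writeLines(txt, tf)
    rec <- read_fasta(tf)[[1]]
    rec$id <- acc
    rec
  })
  if (!is.null(path)) write_fasta(recs, path)
  recs
}

#' Fetch a UniProt mature chain (signal peptide excluded)
#'
#' Retrieves the entry's sequence and its annotated signal-peptide feature,
#' and returns the record trimmed to the residues after the signal peptide.
#' Entries without a signal-peptide annotation are returned whole, with a
#' warning. No prediction is performed: the range comes from the UniProt
#' feature table.
#'
#' @inheritParams fetch_uniprot
#' @param accession A single UniProt accession.
#' @return A [protein_record()] trimmed to the mature range.
#' @export
fetch_uniprot_mature <- function(accession, timeout = 30) {
  stopifnot(is.character(accession), length(accession) == 1L)
  rec <- fetch_uniprot(accession, timeout = timeout)[[1]]
  url <- sprintf("%s/%s.json?fields=ft_signal", uniprot_base, accession)
  meta <- jsonlite::fromJSON(.http_get(url, timeout), simplifyVector = FALSE)
  sig_end <- NA_integer_
  for (f in meta$features %||% list()) {
    if (identical(f$type, "Signal")) {
      sig_end <- suppressWarnings(as.integer(f$location$end$value))
    }
  }
  if (is.na(sig_end)) {
    warning("no signal-peptide annotation for ", accession,
            "; returning the full chain")
    return(rec)
  }
  apply_mature_range(rec, sig_end + 1L, rec$n_residues)
}

# Minimal HTTP GET via base R; keeps the package free of network-client
# dependencies for a feature that is off the critical path.
.http_get <- function(url, timeout) {
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  con <- url(url, open = "rb")
  on.exit(close(con), add = TRUE)
  rawToChar(readBin(con, what = "raw", n = 50e6))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
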