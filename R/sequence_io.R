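# Protein sequence input, validation and trimming.

#' Standard amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes accepted throughout the package.
#' Hydroxyproline and other modified residues are not representable; protein
#' chains are plain 20-letter strings.
#'
#' @return Character vector of 20 one-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a protein record
#'
#' A validated, identified amino-acid chain. The residue count `n_residues`
#' (N) is the denominator of the occurrence and release parameters A and A_E.
#'
#' @param id Accession or label.
#' @param sequence Amino-acid string; canonicalized with `policy`.
#' @param organism Optional free-text organism name.
#' @param policy Canonicalization policy, see [canonicalize_sequence()].
#' @return An object of class `protein_record` with fields `id`, `organism`,
#'   `sequence`, `n_residues`.
#' @examples
#' protein_record("toy", "GKGFRL")
#' @export
protein_record <- function(id, sequence, organism = NA_character_,
                           policy = c("strict", "drop_unknown")) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- canonicalize_sequence(sequence, policy)
  structure(
    list(id = id, organism = organism, sequence = sequence,
         n_residues = nchar(sequence)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, x$n_residues))
  seq <- x$sequence
  if (nchar(seq) > 60) seq <- paste0(substr(seq, 1, 57), "...")
  cat(" ", seq, "\n")
  invisible(x)
}

#' Canonicalize a raw amino-acid string
#'
#' Uppercases and strips whitespace and gap characters (`-`, `.`, `*`). Under
#' the `strict` policy any remaining character outside the 20-letter alphabet
#' (including B, J, O, U, X, Z) is an error; under `drop_unknown` such
#' characters are removed with a warning listing their positions.
#'
#' @param raw Character scalar.
#' @param policy `"strict"` or `"drop_unknown"`.
#' @return Canonical uppercase sequence string.
#' @examples
#' canonicalize_sequence("gkg frl")          # "GKGFRL"
#' canonicalize_sequence("GKXFRL", "drop_unknown")
#' @export
canonicalize_sequence <- function(raw, policy = c("strict", "drop_unknown")) {
  policy <- match.arg(policy)
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  s <- toupper(gsub("[-.*[:space:]]", "", raw))
  if (!nzchar(s)) stop("sequence is empty after removing whitespace/gaps")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad)) {
    if (policy == "strict") {
      stop(sprintf(
        "non-standard residue(s) %s at position(s) %s (strict policy)",
        paste(unique(chars[bad]), collapse = ","),
        paste(bad, collapse = ",")
      ))
    }
    warning(sprintf(
      "dropped non-standard residue(s) %s at position(s) %s",
      paste(unique(chars[bad]), collapse = ","),
      paste(bad, collapse = ",")
    ))
    chars <- chars[-bad]
    if (!length(chars)) stop("sequence is empty after dropping non-standard residues")
    s <- paste(chars, collapse = "")
  }
  s
}

#' Read protein sequences from a FASTA file
#'
#' One `protein_record` per FASTA entry, in file order. The header token
#' before the first whitespace becomes the record id; the remainder of the
#' header, if any, is kept as `organism`-style free text.
#'
#' @param path FASTA file path (wrapped or unwrapped lines).
#' @param policy Canonicalization policy passed to [canonicalize_sequence()].
#' @return List of [protein_record()] objects.
#' @export
read_fasta <- function(path, policy = c("strict", "drop_unknown")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- sub("^[^[:space:]]+[[:space:]]*", "", headers)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    raw <- as.character(set[[i]])
    if (!nzchar(gsub("[-.*[:space:]]", "", raw))) {
      stop(sprintf("record '%s' has an empty sequence", headers[i]))
    }
    out[[i]] <- protein_record(
      id = ids[i], sequence = raw,
      organism = if (nzchar(desc[i])) desc[i] else NA_character_,
      policy = policy
    )
  }
  out
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: ids and sequences round-trip exactly.
#'
#' @param records A `protein_record` or list of them.
#' @param path Output file path.
#' @param width Line-wrap width (0 for unwrapped).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path,
                              width = if (width > 0) width else 80000L)
  invisible(path)
}

#' Restrict a protein record to a mature-chain range
#'
#' Trims the record to `start..end` (1-based, inclusive; UniProt feature
#' convention). No signal-peptide prediction is performed: the range must be
#' supplied externally (user config or UniProt annotation). The id is
#' annotated with the range unless it spans the whole chain.
#'
#' @param record A [protein_record()].
#' @param start,end 1-based inclusive bounds, `1 <= start <= end <= N`.
#' @return A `protein_record` for the sub-chain.
#' @examples
#' apply_mature_range(protein_record("toy", "GKGFRL"), 2, 6)
#' @export
apply_mature_range <- function(record, start, end) {
  stopifnot(inherits(record, "protein_record"))
  start <- as.integer(start); end <- as.integer(end)
  n <- record$n_residues
  if (is.na(start) || is.na(end) || start < 1L || end > n || start > end) {
    stop(sprintf("invalid mature range %s..%s for '%s' (N = %d)",
                 start, end, record$id, n))
  }
  if (start == 1L && end == n) return(record)
  protein_record(
    id = sprintf("%s|%d-%d", record$id, start, end),
    sequence = substr(record$sequence, start, end),
    organism = record$organism
  )
}
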