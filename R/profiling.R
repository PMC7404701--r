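# Quantitative occurrence and release parameters.
#
# For a protein of N residues and an activity code x with database peptides
# P(x):
#   a   = total number of (possibly overlapping) occurrences of peptides in
#         P(x) as substrings of the chain, with multiplicity per position;
#   A   = a / N          frequency of occurrence (protein potential);
#   d   = number of digest fragments whose full sequence equals a peptide
#         in P(x), with multiplicity across fragment positions;
#   A_E = d / N          frequency of release by the selected enzyme(s);
#   W   = A_E / A        relative release (defined only where A > 0).
# A peptide listed under k activity codes contributes to all k profiles.
# Release matching requires the whole fragment to equal a database peptide,
# not substring containment: a fragment is "released" only when the enzymes
# liberate exactly that peptide.

#' Count (possibly overlapping) occurrences of a peptide in a sequence
#'
#' Number of start positions at which `peptide` occurs as a contiguous
#' substring of `protein_sequence`; overlapping matches all count.
#'
#' @param protein_sequence Canonical amino-acid string.
#' @param peptide Canonical peptide, length >= 1.
#' @return Non-negative integer.
#' @examples
#' count_occurrences("AAA", "AA")   # 2
#' @export
count_occurrences <- function(protein_sequence, peptide) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L,
            is.character(peptide), length(peptide) == 1L)
  if (!nzchar(peptide)) stop("peptide must have length >= 1")
  Biostrings::countPattern(peptide, protein_sequence)
}

#' Occurrence profile of a protein against an activity database
#'
#' For every activity code in the database, the occurrence count `a_count`,
#' the frequency of occurrence `A = a_count / N`, and its bin
#' (see [classify_A()]). Activities that never occur are omitted unless
#' `include_zero = TRUE`.
#'
#' @param protein A [protein_record()].
#' @param db A [activity_db()] object.
#' @param include_zero Keep activities with `a_count == 0`?
#' @return Data frame with columns `protein_id`, `activity_code`, `a_count`,
#'   `A`, `bin`, sorted by descending `A` then code.
#' @export
profile_occurrence <- function(protein, db, include_zero = FALSE) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(db, "peptide_activity_db"))
  codes <- sort(names(db$index))
  if (!length(codes)) {
    return(data.frame(protein_id = character(0),
                      activity_code = character(0), a_count = integer(0),
                      A = numeric(0), bin = character(0)))
  }
  peps <- unique(db$records$peptide)
  counts <- vapply(peps, function(p) count_occurrences(protein$sequence, p),
                   integer(1))
  a_count <- vapply(codes, function(code) {
    sum(counts[unique(db$index[[code]])])
  }, numeric(1))
  out <- data.frame(
    protein_id = protein$id,
    activity_code = codes,
    a_count = as.integer(a_count),
    A = a_count / protein$n_residues,
    stringsAsFactors = FALSE
  )
  out$bin <- classify_A(out$A)
  if (!include_zero) out <- out[out$a_count > 0L, , drop = FALSE]
  out <- out[order(-out$A, out$activity_code, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin a frequency-of-occurrence value
#'
#' `major` for `A >= 0.500`, `moderate` for `0.100 <= A < 0.500`, `minor`
#' for `0 < A < 0.100`, and `none` for `A == 0`. Vectorized.
#'
#' @param A Non-negative numeric vector.
#' @return Character vector of bins.
#' @examples
#' classify_A(c(0.834, 0.238, 0.073, 0))
#' @export
classify_A <- function(A) {
  stopifnot(is.numeric(A))
  if (any(is.na(A)) || any(A < 0)) stop("A must be non-negative and non-missing")
  ifelse(A >= 0.500, "major",
         ifelse(A >= 0.100, "moderate",
                ifelse(A > 0, "minor", "none")))
}

#' Release profile of a digest against an activity database
#'
#' For each activity code, the number of released fragments whose full
#' sequence equals a database peptide with that code (`d_count`, counted
#' with multiplicity across fragment positions), the frequency of release
#' `A_E = d_count / N`, and the relative release `W = A_E / A` (NA where
#' `A == 0`).
#'
#' @param protein The digested [protein_record()].
#' @param digest The matching [digest()] result.
#' @param db A [activity_db()] object.
#' @param occurrence Optional precomputed
#'   `profile_occurrence(protein, db, include_zero = TRUE)`; recomputed when
#'   NULL.
#' @param include_zero Keep activities with `a_count == 0` and
#'   `d_count == 0`?
#' @return Data frame with columns `protein_id`, `enzymes`, `activity_code`,
#'   `d_count`, `A_E`, `W`, `a_count`, `A`, sorted by descending `A_E` then
#'   code.
#' @export
profile_release <- function(protein, digest, db, occurrence = NULL,
                            include_zero = FALSE) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(digest, "digest_result"),
            inherits(db, "peptide_activity_db"))
  if (!identical(digest$protein_id, protein$id)) {
    stop(sprintf("digest of '%s' does not belong to protein '%s'",
                 digest$protein_id, protein$id))
  }
  if (is.null(occurrence)) {
    occurrence <- profile_occurrence(protein, db, include_zero = TRUE)
  }
  codes <- sort(names(db$index))
  frag_tab <- table(digest$fragments$sequence)
  d_count <- vapply(codes, function(code) {
    peps <- unique(db$index[[code]])
    sum(frag_tab[peps], na.rm = TRUE)
  }, numeric(1))
  occ <- occurrence[match(codes, occurrence$activity_code), , drop = FALSE]
  A <- occ$A
  A_E <- d_count / protein$n_residues
  out <- data.frame(
    protein_id = protein$id,
    enzymes = paste(digest$enzymes, collapse = "+"),
    activity_code = codes,
    d_count = as.integer(d_count),
    A_E = A_E,
    W = ifelse(A > 0, A_E / A, NA_real_),
    a_count = occ$a_count,
    A = A,
    stringsAsFactors = FALSE
  )
  if (!include_zero) {
    out <- out[out$a_count > 0L | out$d_count > 0L, , drop = FALSE]
  }
  out <- out[order(-out$A_E, out$activity_code, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
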