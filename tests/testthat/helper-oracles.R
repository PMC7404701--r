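# Independent brute-force oracles used to validate the engine, written
# against the definitions (not the implementation): a position-by-position
# substring scan and a per-bond window test.

oracle_count <- function(sequence, peptide) {
  n <- nchar(sequence); k <- nchar(peptide)
  if (k > n) return(0L)
  sum(vapply(seq_len(n - k + 1L), function(i) {
    substr(sequence, i, i + k - 1L) == peptide
  }, logical(1)))
}

# Window offsets: residue index (1-based) of position `pos` around 0-based
# bond b is b + 1 + offset.
oracle_offsets <- c("P4" = -3, "P3" = -2, "P2" = -1, "P1" = 0,
                    "P1'" = 1, "P2'" = 2, "P3'" = 3, "P4'" = 4)

oracle_rule_fires <- function(chars, b, rule) {
  n <- length(chars)
  for (pos in names(rule$window)) {
    con <- rule$window[[pos]]
    idx <- b + 1 + oracle_offsets[[pos]]
    present <- idx >= 1 && idx <= n && chars[idx] %in% con$residues
    if (con$type == "allow" && !present) return(FALSE)
    if (con$type == "deny" && present) return(FALSE)
  }
  TRUE
}

oracle_cut_sites <- function(sequence, enzymes) {
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2) return(integer(0))
  Filter(function(b) {
    any(vapply(enzymes, function(enz) {
      any(vapply(enz$rules, function(r) oracle_rule_fires(chars, b, r),
                 logical(1)))
    }, logical(1)))
  }, 0:(n - 2))
}

random_sequence <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

toy_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(id) {
    c(paste0(">", id), entries[[id]])
  })), path)
  path
}
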