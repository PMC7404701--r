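# End-to-end orchestration: proteins x enzyme sets -> occurrence profiles,
# digests with DH_t, release profiles, released-peptide annotation and an
# optional chemistry pass over the unique released bioactive peptides.

#' Run the full profiling pipeline
#'
#' For every protein: the occurrence profile (a, A, bin per activity). For
#' every protein x enzyme set: the digest, DH_t and the release profile
#' (d, A_E, W per activity). Released peptides that match the database are
#' annotated with their activities and IC50 metadata; the unique released
#' bioactive peptides are optionally passed through the chemistry stage
#' (SMILES + Rule of 5). A failing protein is reported and skipped; the
#' `ok` field of the returned summary is FALSE if anything failed.
#'
#' @param proteins FASTA path, a `protein_record`, or list of records.
#' @param enzyme_sets List of character vectors of enzyme names; singletons
#'   and combinations (e.g. `list("pepsin", c("pepsin", "trypsin"))`).
#' @param db A [activity_db()], a TSV path, or `"fixture"` for the bundled
#'   ACE/DPP-IV database.
#' @param ruleset A ruleset list, a YAML path, or `"biopep_2020"` for the
#'   bundled ruleset.
#' @param mature_ranges Optional named list `id -> c(start, end)` applied
#'   before analysis (1-based inclusive).
#' @param chem Run the chemistry pass over released bioactive peptides?
#'   Peptides longer than 10 residues are skipped with a note.
#' @param ranker_scores Optional data frame (`peptide`, `score`) of
#'   externally computed bioactivity-likelihood scores, joined into the
#'   released-peptide table with a `likely_bioactive` flag (score > 0.5).
#'   Scores are never computed by this package.
#' @param out_dir If non-NULL, reports are written there via
#'   [write_report()].
#' @param format `"tsv"` or `"json"` for written reports.
#' @return An object of class `pipeline_result`: `occurrence`, `dh`
#'   (protein x enzyme-set DH_t), `release`, `released_peptides`, `chem`,
#'   `manifest`, `failures`, `ok`.
#' @export
run_pipeline <- function(proteins, enzyme_sets, db = "fixture",
                         ruleset = "biopep_2020", mature_ranges = NULL,
                         chem = TRUE, ranker_scores = NULL, out_dir = NULL,
                         format = c("tsv", "json")) {
  format <- match.arg(format)
  ruleset <- .resolve_ruleset(ruleset)
  db <- .resolve_db(db)
  # validate every enzyme name before any computation
  enzyme_sets <- lapply(enzyme_sets, as.character)
  for (set in enzyme_sets) resolve_enzymes(set, ruleset)
  proteins <- .resolve_proteins(proteins)
  if (!is.null(mature_ranges)) {
    proteins <- lapply(proteins, function(p) {
      rng <- mature_ranges[[p$id]]
      if (is.null(rng)) p else apply_mature_range(p, rng[1], rng[2])
    })
  }
  if (!is.null(ranker_scores)) {
    stopifnot(is.data.frame(ranker_scores),
              all(c("peptide", "score") %in% names(ranker_scores)))
  }

  occ_all <- list(); rel_all <- list(); dh_all <- list(); pep_all <- list()
  failures <- character(0)
  db_peptides <- unique(db$records$peptide)
  for (p in proteins) {
    res <- tryCatch({
      occ_full <- profile_occurrence(p, db, include_zero = TRUE)
      rel_p <- list(); dh_p <- list(); pep_p <- list()
      for (set in enzyme_sets) {
        enz <- resolve_enzymes(set, ruleset)
        dg <- digest(p, enz)
        rel_p[[length(rel_p) + 1L]] <-
          profile_release(p, dg, db, occurrence = occ_full)
        dh_p[[length(dh_p) + 1L]] <- data.frame(
          protein_id = p$id, enzymes = paste(set, collapse = "+"),
          n_residues = p$n_residues, n_cuts = length(dg$cut_sites),
          dh_t = dg$dh_t, stringsAsFactors = FALSE)
        frag_tab <- table(dg$fragments$sequence)
        matched <- intersect(names(frag_tab), db_peptides)
        if (length(matched)) {
          rec <- db$records[db$records$peptide %in% matched, , drop = FALSE]
          pep_p[[length(pep_p) + 1L]] <- data.frame(
            peptide = rec$peptide, activity_code = rec$activity_code,
            protein_id = p$id, enzymes = paste(set, collapse = "+"),
            n_released = as.integer(frag_tab[rec$peptide]),
            ic50_value = rec$ic50_value, ic50_unit = rec$ic50_unit,
            reference = rec$reference, stringsAsFactors = FALSE)
        }
      }
      list(occ = occ_full[occ_full$a_count > 0L, , drop = FALSE],
           rel = do.call(rbind, rel_p), dh = do.call(rbind, dh_p),
           pep = if (length(pep_p)) do.call(rbind, pep_p))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("protein '%s' failed: %s", p$id,
                      conditionMessage(res)))
      failures <- c(failures, p$id)
      next
    }
    occ_all[[p$id]] <- res$occ
    rel_all[[p$id]] <- res$rel
    dh_all[[p$id]] <- res$dh
    pep_all[[p$id]] <- res$pep
  }
  occurrence <- .rbind_or_empty(occ_all, c("protein_id", "activity_code",
                                           "a_count", "A", "bin"))
  release <- .rbind_or_empty(rel_all, c("protein_id", "enzymes",
                                        "activity_code", "d_count", "A_E",
                                        "W", "a_count", "A"))
  dh <- .rbind_or_empty(dh_all, c("protein_id", "enzymes", "n_residues",
                                  "n_cuts", "dh_t"))

  released <- .rbind_or_empty(pep_all, c("peptide", "activity_code",
                                         "protein_id", "enzymes",
                                         "n_released", "ic50_value",
                                         "ic50_unit", "reference"))
  if (nrow(released)) {
    released <- released[order(released$peptide, released$activity_code,
                               released$protein_id, released$enzymes,
                               method = "radix"), , drop = FALSE]
    rownames(released) <- NULL
  }
  if (!is.null(ranker_scores) && nrow(released)) {
    idx <- match(released$peptide, ranker_scores$peptide)
    released$ranker_score <- ranker_scores$score[idx]
    released$likely_bioactive <- !is.na(released$ranker_score) &
      released$ranker_score > 0.5
  }
  chem_tab <- NULL
  if (chem && nrow(released)) {
    peps <- unique(released$peptide)
    short <- peps[nchar(peps) <= 10L]
    if (length(short)) chem_tab <- chem_table(sort(short))
  }

  manifest <- list(
    package = "biopepsim",
    version = as.character(utils::packageVersion("biopepsim")),
    ruleset = attr(ruleset, "name") %||% "custom",
    enzymes = vapply(enzyme_sets, paste, "", collapse = "+"),
    n_proteins = length(proteins),
    db_fingerprint = .db_fingerprint(db),
    config_hash = .obj_fingerprint(list(
      ids = vapply(proteins, `[[`, "", "id"),
      enzyme_sets = enzyme_sets, mature_ranges = mature_ranges,
      chem = chem, format = format)),
    failures = failures
  )
  out <- structure(
    list(occurrence = occurrence, dh = dh, release = release,
         released_peptides = released, chem = chem_tab,
         manifest = manifest, failures = failures,
         ok = length(failures) == 0L),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_report(out, out_dir, format)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d protein(s) x %d enzyme set(s); %d released bioactive peptide row(s)%s\n",
    x$manifest$n_proteins, length(x$manifest$enzymes),
    nrow(x$released_peptides),
    if (x$ok) "" else sprintf("; %d FAILURE(s)", length(x$failures))))
  invisible(x)
}

.resolve_ruleset <- function(ruleset) {
  if (is.character(ruleset) && length(ruleset) == 1L) {
    if (identical(ruleset, "biopep_2020")) return(default_ruleset())
    return(parse_ruleset(ruleset))
  }
  stopifnot(is.list(ruleset))
  ruleset
}

.resolve_db <- function(db) {
  if (is.character(db) && length(db) == 1L) {
    if (identical(db, "fixture")) return(builtin_fixture())
    return(load_activity_table(db))
  }
  stopifnot(inherits(db, "peptide_activity_db"))
  db
}

.resolve_proteins <- function(proteins) {
  if (is.character(proteins) && length(proteins) == 1L) {
    return(read_fasta(proteins))
  }
  if (inherits(proteins, "protein_record")) return(list(proteins))
  stopifnot(is.list(proteins), length(proteins) >= 1L)
  for (p in proteins) stopifnot(inherits(p, "protein_record"))
  proteins
}

.rbind_or_empty <- function(lst, cols) {
  lst <- Filter(function(x) !is.null(x) && nrow(x), lst)
  if (!length(lst)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  out <- do.call(rbind, unname(lst))
  rownames(out) <- NULL
  out
}

.db_fingerprint <- function(db) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  export_activity_table(db, tf)
  unname(tools::md5sum(tf))
}

.obj_fingerprint <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}
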