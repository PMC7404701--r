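# Collagen-like synthetic proteins with planted motifs.
#
# The generator emulates the repetitive G-X-Y structure of the collagen
# triple helix: every third residue is Gly and the X/Y positions are drawn
# from a proline-rich composition. Bioactive motifs are planted at known,
# triplet-aligned positions so that the occurrence and release parameters
# are analytically known, and the expected values are computed by an
# independent brute-force pass (naive substring scan, naive per-bond rule
# test) -- deliberately NOT by the engine modules, so that
# oracle-equivalence tests are meaningful.

#' Specify a synthetic collagen-like protein
#'
#' @param n_triplets Number of G-X-Y triplets (chain length `3 * n_triplets`).
#' @param composition Named non-negative weights for the X and Y positions.
#'   The default approximates collagen: proline-dominant with minor
#'   A, R, K, E, D, S, Q, L, F, so that pepsin/trypsin site densities stay
#'   in the low-DH_t regime typical of collagen chains.
#' @param motifs List of `list(peptide =, activity_code =, copies =)`
#'   entries to plant.
#' @param flank_mode `"cuttable"` (flank each copy so the ruleset's enzymes
#'   cut exactly at its boundaries) or `"inert"` (flanks avoid the enzymes'
#'   cleavage context).
#' @param enzyme_sets List of character vectors of enzyme names; the
#'   enzyme sets for which ground-truth release parameters are computed.
#' @param ruleset Named list of [enzyme_spec()] (default: bundled ruleset).
#' @param seed Integer seed; mandatory, no global random state is consulted.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_triplets = 340L,
                           composition = c(P = 0.50, A = 0.12, E = 0.08,
                                           S = 0.06, Q = 0.05, R = 0.05,
                                           D = 0.04, L = 0.04, K = 0.03,
                                           F = 0.03),
                           motifs = list(),
                           flank_mode = c("cuttable", "inert"),
                           enzyme_sets = list("pepsin", "trypsin"),
                           ruleset = default_ruleset(),
                           seed) {
  flank_mode <- match.arg(flank_mode)
  if (missing(seed)) stop("a seed is mandatory for synthetic specs")
  n_triplets <- as.integer(n_triplets)
  if (is.na(n_triplets) || n_triplets < 1L) stop("n_triplets must be >= 1")
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition weights must be named by residue")
  }
  bad <- setdiff(names(composition), aa_alphabet())
  if (length(bad)) stop("composition has non-standard residue(s): ",
                        paste(bad, collapse = ","))
  if (any(composition < 0) || sum(composition) <= 0) {
    stop("composition weights must be non-negative with a positive sum")
  }
  for (m in motifs) {
    if (!all(c("peptide", "activity_code", "copies") %in% names(m))) {
      stop("each motif needs fields peptide, activity_code, copies")
    }
    canonicalize_sequence(m$peptide)
    if (m$copies < 1L) stop("motif copies must be >= 1")
  }
  enzyme_sets <- lapply(enzyme_sets, as.character)
  for (set in enzyme_sets) resolve_enzymes(set, ruleset)
  structure(
    list(n_triplets = n_triplets, composition = composition, motifs = motifs,
         flank_mode = flank_mode, enzyme_sets = enzyme_sets,
         ruleset = ruleset, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a collagen-like base sequence
#'
#' `n_triplets` G-X-Y triplets with X and Y drawn from the spec's
#' composition under a local seeded generator; deterministic for a fixed
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [protein_record()] with id `synthetic_<seed>`.
#' @examples
#' generate_collagen_like(synthetic_spec(n_triplets = 3,
#'                                       composition = c(P = 1), seed = 7))
#' @export
generate_collagen_like <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  xy <- .with_seed(spec$seed, {
    sample(names(spec$composition), size = 2L * spec$n_triplets,
           replace = TRUE, prob = spec$composition)
  })
  chars <- character(3L * spec$n_triplets)
  chars[seq(1L, length(chars), by = 3L)] <- "G"
  chars[seq(2L, length(chars), by = 3L)] <- xy[seq_len(spec$n_triplets)]
  chars[seq(3L, length(chars), by = 3L)] <- xy[-seq_len(spec$n_triplets)]
  protein_record(sprintf("synthetic_%d", spec$seed),
                 paste(chars, collapse = ""))
}

# Run code under a temporary RNG state derived from `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- independent brute-force oracle -----------------------------------

# Naive overlapping substring count (position-by-position scan).
.naive_count <- function(sequence, peptide) {
  n <- nchar(sequence); k <- nchar(peptide)
  if (k < 1L || k > n) return(0L)
  hits <- 0L
  for (i in seq_len(n - k + 1L)) {
    if (substr(sequence, i, i + k - 1L) == peptide) hits <- hits + 1L
  }
  hits
}

# Naive per-bond rule test: loops over bonds, rules and window positions.
.naive_cut_sites <- function(sequence, enzymes) {
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sites <- integer(0)
  offsets <- c("P4" = -3L, "P3" = -2L, "P2" = -1L, "P1" = 0L,
               "P1'" = 1L, "P2'" = 2L, "P3'" = 3L, "P4'" = 4L)
  if (n < 2L) return(sites)
  for (b in 0:(n - 2L)) {
    fired <- FALSE
    for (enz in enzymes) {
      for (rule in enz$rules) {
        ok <- TRUE
        for (pos in names(rule$window)) {
          con <- rule$window[[pos]]
          idx <- b + 1L + offsets[[pos]]
          present <- idx >= 1L && idx <= n && chars[idx] %in% con$residues
          if (con$type == "allow" && !present) { ok <- FALSE; break }
          if (con$type == "deny" && present) { ok <- FALSE; break }
        }
        if (ok) { fired <- TRUE; break }
      }
      if (fired) break
    }
    if (fired) sites <- c(sites, b)
  }
  sites
}

# Naive fragment list from naive cut sites.
.naive_fragments <- function(sequence, enzymes) {
  sites <- .naive_cut_sites(sequence, enzymes)
  n <- nchar(sequence)
  starts <- c(0L, sites + 1L)
  ends <- c(sites + 1L, n)
  substring(sequence, starts + 1L, ends)
}

#' Plant motifs into a collagen-like base sequence
#'
#' Each motif copy replaces a segment starting at a seeded-random
#' triplet-aligned (Gly) position, copies never overlapping. Under
#' `flank_mode = "cuttable"` the residue preceding each copy is drawn from a
#' P1 `allow` set of the spec's enzymes so that digestion cuts at the copy's
#' boundaries where the motif sequence permits it; under `"inert"` the
#' flanking residues (and the copy's immediate context) are chosen to avoid
#' all the enzymes' cleavage contexts. Placement is validated: the final
#' sequence must contain each motif exactly `copies` times (no accidental
#' occurrences); placement is retried under derived seeds and errors out
#' after `max_retries` failures.
#'
#' The returned ground truth (planted positions, expected A, A_E, W, DH_t
#' per enzyme set) is computed by the brute-force oracle, independently of
#' the digestion and profiling engines.
#'
#' @param base A [protein_record()] from [generate_collagen_like()].
#' @param spec The same [synthetic_spec()].
#' @param max_retries Placement retries before giving up.
#' @return An object of class `ground_truth` with fields `protein`,
#'   `planted_positions` (0-based starts per motif), `db`, `enzyme_sets`,
#'   `expected_A`, `expected_AE`, `expected_W`, `expected_DHt`.
#' @export
plant_motifs <- function(base, spec, max_retries = 25L) {
  stopifnot(inherits(base, "protein_record"), inherits(spec, "synthetic_spec"))
  n <- base$n_residues
  total_len <- sum(vapply(spec$motifs, function(m) {
    nchar(m$peptide) * m$copies
  }, numeric(1)))
  if (total_len > n) stop("planted motifs do not fit into the base sequence")
  enzymes_flat <- resolve_enzymes(unique(unlist(spec$enzyme_sets)),
                                  spec$ruleset)
  for (attempt in seq_len(max_retries)) {
    res <- .with_seed(spec$seed + 7919L * attempt, {
      .try_place(base$sequence, spec, enzymes_flat)
    })
    if (!is.null(res)) {
      protein <- protein_record(base$id, res$sequence,
                                organism = base$organism)
      return(.ground_truth(protein, res$positions, spec))
    }
  }
  stop("could not place motifs without collisions/accidental occurrences ",
       "after ", max_retries, " retries")
}

# One placement attempt; NULL on failure.
.try_place <- function(sequence, spec, enzymes_flat) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  taken <- rep(FALSE, n)
  positions <- list()
  p1_allowed <- unique(unlist(lapply(enzymes_flat, function(e) {
    unlist(lapply(e$rules, function(r) {
      con <- r$window[["P1"]]
      if (!is.null(con) && con$type == "allow") con$residues
    }))
  })))
  # residues that are safe flanks for "inert" mode: outside every allow-set
  # that could complete a cleavage context around the copy
  context_res <- unique(unlist(lapply(enzymes_flat, function(e) {
    unlist(lapply(e$rules, function(r) {
      unlist(lapply(r$window, function(con) {
        if (con$type == "allow") con$residues
      }))
    }))
  })))
  inert_pool <- setdiff(c("G", "P", "Q", "S", "T", "N", "H"), context_res)
  if (!length(inert_pool)) inert_pool <- "P"
  for (m in spec$motifs) {
    len <- nchar(m$peptide)
    mot <- strsplit(m$peptide, "", fixed = TRUE)[[1]]
    for (k in seq_len(m$copies)) {
      # triplet-aligned candidate starts (Gly positions), keeping one
      # residue of clearance for the flank
      cand <- seq(4L, n - len + 1L, by = 3L)
      cand <- cand[vapply(cand, function(s) {
        !any(taken[max(1L, s - 1L):min(n, s + len)])
      }, logical(1))]
      if (!length(cand)) return(NULL)
      s <- cand[sample.int(length(cand), 1L)]
      chars[s:(s + len - 1L)] <- mot
      if (spec$flank_mode == "cuttable") {
        if (length(p1_allowed)) {
          chars[s - 1L] <- p1_allowed[sample.int(length(p1_allowed), 1L)]
        }
      } else {
        chars[s - 1L] <- inert_pool[sample.int(length(inert_pool), 1L)]
        if (s + len <= n) {
          chars[s + len] <- inert_pool[sample.int(length(inert_pool), 1L)]
        }
      }
      taken[max(1L, s - 1L):min(n, s + len)] <- TRUE
      positions[[length(positions) + 1L]] <-
        list(peptide = m$peptide, start = s - 1L)   # 0-based
    }
  }
  if (!length(spec$motifs)) {
    return(list(sequence = paste(chars, collapse = ""), positions = positions))
  }
  # scrub accidental occurrences: the base sequence may contain chance
  # copies of a motif; mutate one free residue inside each chance match
  # (preferring X/Y positions so the G frame survives) and re-validate
  per_pep <- tapply(vapply(spec$motifs, `[[`, numeric(1), "copies"),
                    vapply(spec$motifs, `[[`, "", "peptide"), sum)
  scrub_pool <- setdiff(c("P", "Q", "S", "T", "N", "H"),
                        unique(unlist(strsplit(names(per_pep), ""))))
  if (!length(scrub_pool)) scrub_pool <- "P"
  planted_idx <- rep(FALSE, n)
  for (pp in positions) {
    planted_idx[(pp$start + 1L):(pp$start + nchar(pp$peptide))] <- TRUE
  }
  for (pass in 1:10) {
    out <- paste(chars, collapse = "")
    clean <- TRUE
    for (pep in names(per_pep)) {
      k <- nchar(pep)
      hits <- which(vapply(seq_len(n - k + 1L), function(i) {
        substr(out, i, i + k - 1L) == pep
      }, logical(1)))
      planted_starts <- 1L + vapply(
        Filter(function(pp) pp$peptide == pep, positions),
        `[[`, integer(1), "start")
      for (h in setdiff(hits, planted_starts)) {
        span <- h:(h + k - 1L)
        free <- span[!taken[span] & !planted_idx[span]]
        if (!length(free)) return(NULL)   # overlaps a planted copy: retry
        pick <- free[(free - 1L) %% 3L != 0L]   # prefer non-Gly-frame slots
        if (!length(pick)) pick <- free
        idx <- pick[sample.int(length(pick), 1L)]
        repl <- setdiff(scrub_pool, chars[idx])
        chars[idx] <- repl[sample.int(length(repl), 1L)]
        clean <- FALSE
      }
    }
    if (clean) break
  }
  out <- paste(chars, collapse = "")
  for (pep in names(per_pep)) {
    if (.naive_count(out, pep) != per_pep[[pep]]) return(NULL)
  }
  list(sequence = out, positions = positions)
}

# Brute-force expected parameters for a planted protein.
.ground_truth <- function(protein, positions, spec) {
  db <- make_synthetic_db(spec)
  n <- protein$n_residues
  codes <- unique(vapply(spec$motifs, `[[`, "", "activity_code"))
  expected_A <- vapply(codes, function(code) {
    peps <- unique(vapply(
      Filter(function(m) m$activity_code == code, spec$motifs), `[[`, "",
      "peptide"))
    sum(vapply(peps, function(p) .naive_count(protein$sequence, p),
               integer(1))) / n
  }, numeric(1))
  set_label <- vapply(spec$enzyme_sets, paste, "", collapse = "+")
  expected_AE <- expected_W <- list()
  expected_DHt <- numeric(0)
  for (i in seq_along(spec$enzyme_sets)) {
    enz <- resolve_enzymes(spec$enzyme_sets[[i]], spec$ruleset)
    frags <- .naive_fragments(protein$sequence, enz)
    sites <- .naive_cut_sites(protein$sequence, enz)
    expected_DHt[[set_label[i]]] <-
      if (n >= 2L) 100 * length(sites) / (n - 1L) else 0
    ae <- vapply(codes, function(code) {
      peps <- unique(vapply(
        Filter(function(m) m$activity_code == code, spec$motifs), `[[`, "",
        "peptide"))
      sum(frags %in% peps) / n
    }, numeric(1))
    expected_AE[[set_label[i]]] <- ae
    expected_W[[set_label[i]]] <-
      ifelse(expected_A > 0, ae / expected_A, NA_real_)
  }
  planted <- split(
    vapply(positions, `[[`, integer(1), "start"),
    vapply(positions, `[[`, "", "peptide")
  )
  structure(
    list(protein = protein, planted_positions = lapply(planted, sort),
         db = db, enzyme_sets = spec$enzyme_sets,
         expected_A = expected_A, expected_AE = expected_AE,
         expected_W = expected_W, expected_DHt = expected_DHt),
    class = "ground_truth"
  )
}

#' Activity database of the planted motifs
#'
#' @param spec A [synthetic_spec()].
#' @return A [activity_db()] with exactly the planted (peptide, activity)
#'   associations.
#' @export
make_synthetic_db <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!length(spec$motifs)) {
    return(activity_db(data.frame(peptide = character(0),
                                  activity_code = character(0))))
  }
  activity_db(data.frame(
    peptide = vapply(spec$motifs, `[[`, "", "peptide"),
    activity_code = vapply(spec$motifs, `[[`, "", "activity_code"),
    stringsAsFactors = FALSE
  ))
}

#' Write a synthetic fixture to disk
#'
#' Emits the planted protein as FASTA, the activity table as TSV and the
#' ground truth as JSON, so fixtures are regenerable and inspectable.
#'
#' @param truth A [plant_motifs()] result.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the three paths.
#' @export
write_synthetic_fixture <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(truth$protein$id, ".fasta"))
  tsv <- file.path(dir, paste0(truth$protein$id, "_activities.tsv"))
  js <- file.path(dir, paste0(truth$protein$id, "_truth.json"))
  write_fasta(truth$protein, fa)
  export_activity_table(truth$db, tsv)
  jsonlite::write_json(
    list(protein_id = truth$protein$id,
         planted_positions = truth$planted_positions,
         expected_A = as.list(truth$expected_A),
         expected_AE = truth$expected_AE,
         expected_DHt = as.list(truth$expected_DHt)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fa, tsv, js))
}
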