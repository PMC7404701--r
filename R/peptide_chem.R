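# Peptide cheminformatics: SMILES construction and Lipinski descriptors.
#
# SMILES strings for short peptides (length 1-10) are assembled by
# condensing per-residue templates through amide bonds, N- to C-terminus,
# with L-configuration alpha carbons. The ionized form carries the dominant
# species at neutral pH: N-terminal ammonium (+1), C-terminal carboxylate
# (-1), Asp/Glu side-chain carboxylates (-1), Lys ammonium and Arg
# guanidinium (+1); His and Cys are left neutral.
#
# Lipinski conventions: HBD = number of N-H and O-H hydrogens and
# HBA = number of N + O atoms, both on the neutral form; MW from average
# residue masses plus one water; logP from OpenBabel's atom-contribution
# model (Wildman-Crippen) on the neutral form.

.water_mass <- 18.0153

# sc: side-chain branch SMILES attached at the alpha carbon (neutral and
# ionized); mass: average residue mass (Da); no: side-chain N+O atoms;
# hd: side-chain N-H/O-H hydrogens (neutral form).
.residue_chem <- list(
  A = list(sc = "C",                sc_ion = NULL, mass =  71.0788, no = 0L, hd = 0L),
  C = list(sc = "CS",               sc_ion = NULL, mass = 103.1388, no = 0L, hd = 0L),
  D = list(sc = "CC(=O)O",          sc_ion = "CC(=O)[O-]", mass = 115.0886, no = 2L, hd = 1L),
  E = list(sc = "CCC(=O)O",         sc_ion = "CCC(=O)[O-]", mass = 129.1155, no = 2L, hd = 1L),
  F = list(sc = "Cc1ccccc1",        sc_ion = NULL, mass = 147.1766, no = 0L, hd = 0L),
  G = list(sc = "",                 sc_ion = NULL, mass =  57.0519, no = 0L, hd = 0L),
  H = list(sc = "Cc1c[nH]cn1",      sc_ion = NULL, mass = 137.1411, no = 2L, hd = 1L),
  I = list(sc = "[C@@H](C)CC",      sc_ion = NULL, mass = 113.1594, no = 0L, hd = 0L),
  K = list(sc = "CCCCN",            sc_ion = "CCCC[NH3+]", mass = 128.1741, no = 1L, hd = 2L),
  L = list(sc = "CC(C)C",           sc_ion = NULL, mass = 113.1594, no = 0L, hd = 0L),
  M = list(sc = "CCSC",             sc_ion = NULL, mass = 131.1926, no = 0L, hd = 0L),
  N = list(sc = "CC(=O)N",          sc_ion = NULL, mass = 114.1038, no = 2L, hd = 2L),
  P = list(sc = NA,                 sc_ion = NULL, mass =  97.1167, no = 0L, hd = 0L),
  Q = list(sc = "CCC(=O)N",         sc_ion = NULL, mass = 128.1307, no = 2L, hd = 2L),
  R = list(sc = "CCCNC(=N)N",       sc_ion = "CCCNC(=[NH2+])N", mass = 156.1875, no = 3L, hd = 4L),
  S = list(sc = "CO",               sc_ion = NULL, mass =  87.0782, no = 1L, hd = 1L),
  T = list(sc = "[C@H](O)C",        sc_ion = NULL, mass = 101.1051, no = 1L, hd = 1L),
  V = list(sc = "C(C)C",            sc_ion = NULL, mass =  99.1326, no = 0L, hd = 0L),
  W = list(sc = "Cc1c[nH]c2ccccc12", sc_ion = NULL, mass = 186.2132, no = 1L, hd = 1L),
  Y = list(sc = "Cc1ccc(O)cc1",     sc_ion = NULL, mass = 163.1760, no = 1L, hd = 1L)
)

.check_peptide <- function(peptide, max_len = 10L) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (!length(chars) || length(chars) > max_len) {
    stop(sprintf("peptide length must be 1..%d residues, got %d",
                 max_len, length(chars)))
  }
  bad <- setdiff(chars, aa_alphabet())
  if (length(bad)) {
    stop("unsupported residue(s): ", paste(unique(bad), collapse = ","))
  }
  chars
}

#' Build a SMILES string for a short peptide
#'
#' Condenses per-residue templates (L-configuration) into the linear
#' peptide. With `ionized = TRUE` the dominant neutral-pH species is
#' produced: `[NH3+]` N-terminus (`[NH2+]` for proline), `[O-]` C-terminus
#' and Asp/Glu/Lys/Arg side-chain charges; histidine stays neutral. The
#' neutral and ionized forms share the same heavy-atom graph.
#'
#' @param peptide Canonical peptide, 1-10 residues.
#' @param ionized Produce the neutral-pH ionized form?
#' @return A SMILES string.
#' @examples
#' peptide_to_smiles("G")                   # "NCC(=O)O"
#' peptide_to_smiles("GG", ionized = TRUE)  # "[NH3+]CC(=O)NCC(=O)[O-]"
#' @export
peptide_to_smiles <- function(peptide, ionized = FALSE) {
  chars <- .check_peptide(peptide)
  n <- length(chars)
  parts <- character(n)
  for (i in seq_len(n)) {
    r <- chars[i]
    info <- .residue_chem[[r]]
    if (r == "P") {
      ntok <- if (i == 1L && ionized) "[NH2+]1" else "N1"
      core <- paste0(ntok, "CCC[C@H]1")
    } else {
      ntok <- if (i == 1L && ionized) "[NH3+]" else "N"
      sc <- if (ionized && !is.null(info$sc_ion)) info$sc_ion else info$sc
      core <- if (r == "G") paste0(ntok, "C")
              else paste0(ntok, "[C@@H](", sc, ")")
    }
    tail <- if (i < n) "C(=O)" else if (ionized) "C(=O)[O-]" else "C(=O)O"
    parts[i] <- paste0(core, tail)
  }
  paste(parts, collapse = "")
}

#' Canonicalize a SMILES string
#'
#' Round-trips a SMILES through OpenBabel's canonical writer; two strings
#' denote the same structure iff their canonical forms are identical.
#'
#' @param smiles SMILES string(s).
#' @return Canonical SMILES string(s).
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- ChemmineOB::convertFormat("SMILES", "CAN", s)
    sub("[[:space:]].*$", "", out)
  }, "", USE.NAMES = FALSE)
}

#' Net formal charge encoded in a SMILES string
#'
#' Sums the charges of all bracket atoms. For peptides built by
#' [peptide_to_smiles()] this equals the bookkeeping sum of the ionization
#' rules (0 for the neutral form).
#'
#' @param smiles SMILES string(s).
#' @return Integer vector of net formal charges.
#' @export
smiles_formal_charge <- function(smiles) {
  vapply(smiles, function(s) {
    atoms <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    total <- 0L
    for (a in atoms) {
      m <- regmatches(a, regexec("([+-])([0-9]*)\\]$", a))[[1]]
      if (length(m)) {
        mag <- if (nzchar(m[3])) as.integer(m[3]) else 1L
        total <- total + if (m[2] == "+") mag else -mag
      }
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

#' Lipinski-relevant descriptors of a short peptide
#'
#' Molecular weight from average residue masses plus one water; H-bond
#' donors (N-H and O-H hydrogens) and acceptors (N + O atoms) counted on
#' the neutral form; logP from OpenBabel's atom-contribution model on the
#' neutral SMILES.
#'
#' @param peptide Canonical peptide, 1-10 residues.
#' @return An object of class `molecule_descriptors` with fields `peptide`,
#'   `smiles_neutral`, `smiles_ionized`, `mw`, `hbd`, `hba`, `logp`,
#'   `logp_method`.
#' @examples
#' compute_descriptors("GF")$mw   # 222.24
#' @export
compute_descriptors <- function(peptide) {
  chars <- .check_peptide(peptide)
  n <- length(chars)
  info <- .residue_chem[chars]
  mw <- sum(vapply(info, `[[`, numeric(1), "mass")) + .water_mass
  # backbone donors: N-terminal amine (1 H for proline, else 2), one H per
  # internal amide N unless that residue is proline, C-terminal OH
  hbd <- (if (chars[1] == "P") 1L else 2L) +
    sum(chars[-1] != "P") + 1L +
    sum(vapply(info, `[[`, integer(1), "hd"))
  # backbone acceptors: one N and one carbonyl O per residue + C-term OH
  hba <- 2L * n + 1L + sum(vapply(info, `[[`, integer(1), "no"))
  smi_neutral <- peptide_to_smiles(peptide, ionized = FALSE)
  smi_ionized <- peptide_to_smiles(peptide, ionized = TRUE)
  mol <- ChemmineOB::forEachMol("SMILES", smi_neutral, identity)[[1]]
  logp <- ChemmineOB::prop_OB(mol)$logP
  structure(
    list(peptide = peptide, smiles_neutral = smi_neutral,
         smiles_ionized = smi_ionized, mw = mw, hbd = hbd, hba = hba,
         logp = logp,
         logp_method = "OpenBabel atom-contribution (Wildman-Crippen)"),
    class = "molecule_descriptors"
  )
}

#' @export
print.molecule_descriptors <- function(x, ...) {
  cat(sprintf("<molecule_descriptors> %s: MW %.2f, HBD %d, HBA %d, logP %.2f\n",
              x$peptide, x$mw, x$hbd, x$hba, x$logp))
  invisible(x)
}

#' Lipinski Rule-of-5 evaluation
#'
#' The four criteria (MW <= 500 Da, logP <= 5, HBD <= 5, HBA <= 10) as
#' individual flags, their strict conjunction (`pass_all`), the number of
#' violated criteria, and the conventional Rule-of-5 verdict
#' `fulfills_ro5` (at most one violation), which is how drug-likeness
#' screens report "fulfills the Rule of 5".
#'
#' @param desc A [compute_descriptors()] result.
#' @return An object of class `lipinski_report` with fields `peptide`,
#'   `pass_mw`, `pass_logp`, `pass_hbd`, `pass_hba`, `pass_all`,
#'   `n_violations`, `fulfills_ro5`.
#' @export
rule_of_five <- function(desc) {
  stopifnot(inherits(desc, "molecule_descriptors"))
  flags <- c(pass_mw = desc$mw <= 500,
             pass_logp = desc$logp <= 5,
             pass_hbd = desc$hbd <= 5,
             pass_hba = desc$hba <= 10)
  structure(
    c(list(peptide = desc$peptide), as.list(flags),
      list(pass_all = all(flags),
           n_violations = sum(!flags),
           fulfills_ro5 = sum(!flags) <= 1L)),
    class = "lipinski_report"
  )
}

#' @export
print.lipinski_report <- function(x, ...) {
  cat(sprintf("<lipinski_report> %s: %s (%d violation(s))\n",
              x$peptide, if (x$fulfills_ro5) "+" else "-", x$n_violations))
  invisible(x)
}

#' Descriptor table for a set of peptides
#'
#' One row per peptide: SMILES (both forms), MW, logP, HBD, HBA, the
#' Rule-of-5 verdict (`"+"`/`"-"`) and the violation count.
#'
#' @param peptides Character vector of canonical peptides (1-10 residues).
#' @return Data frame, one row per peptide, in input order.
#' @export
chem_table <- function(peptides) {
  stopifnot(is.character(peptides))
  rows <- lapply(peptides, function(p) {
    d <- compute_descriptors(p)
    r <- rule_of_five(d)
    data.frame(peptide = p, smiles_neutral = d$smiles_neutral,
               smiles_ionized = d$smiles_ionized, mw = d$mw, logp = d$logp,
               hbd = d$hbd, hba = d$hba,
               rule_of_5 = if (r$fulfills_ro5) "+" else "-",
               n_violations = r$n_violations,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write peptides to a .smi file
#'
#' One `SMILES<space>identifier` line per peptide.
#'
#' @param peptides Character vector of canonical peptides.
#' @param path Output path.
#' @param ionized Write the neutral-pH ionized forms?
#' @return `path`, invisibly.
#' @export
write_smiles <- function(peptides, path, ionized = TRUE) {
  lines <- vapply(peptides, function(p) {
    paste(peptide_to_smiles(p, ionized = ionized), p)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
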