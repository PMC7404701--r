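---
title: "In silico proteolysis and bioactive peptide release profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico proteolysis and bioactive peptide release profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopepsim)
```

## The model

Food proteins — collagens prominently among them — encrypt short bioactive
peptides (ACE inhibitors, DPP-IV inhibitors, antioxidative fragments, ...)
that enzymatic hydrolysis can liberate. `biopepsim` implements the
quantitative framework used to screen proteins for this potential:

* **A**, the *frequency of occurrence*: the number of occurrences of
  database peptides carrying a given activity inside the intact chain,
  divided by the chain length $N$. Occurrences are counted at every start
  position, overlaps included, and a peptide listed under $k$ activity
  codes contributes to all $k$ profiles.
* **A~E~**, the *frequency of release*: the number of digest fragments
  whose **whole** sequence equals a database peptide with the activity,
  divided by $N$. Substring containment does not count — a fragment is
  released only when digestion liberates exactly that peptide.
* **W = A~E~ / A**, the *relative release*: the share of the encrypted
  potential that the chosen enzymes actually liberate. Undefined (reported
  blank) when $A = 0$.
* **DH~t~**, the *theoretical degree of hydrolysis*: the percentage of
  peptide bonds cleaved, $100\,|C|/(N-1)$ for cut-site set $C$.

A values are binned: **major** ($A \ge 0.500$), **moderate**
($0.100 \le A < 0.500$), **minor** ($0 < A < 0.100$). A chain whose major-A
activity is, say, ACE inhibition is a promising raw material for an
antihypertensive hydrolysate.

## Digestion model and its assumptions

Cleavage is **complete and simultaneous**: a peptide bond is cut if and
only if a specificity rule fires on the *intact* sequence, and every
susceptible bond is cut. There is no kinetics, no partial digestion, no
enzyme concentration, pH or temperature, and no re-digestion of fragments.
Two consequences follow and are enforced as invariants:

* multi-enzyme cut sets are exactly the union of single-enzyme cut sets,
  so DH~t~ is sub-additive, with equality when the site sets are disjoint;
* fragments always partition the chain (concatenation reproduces it).

A rule constrains residues in a P4–P4′ window around the bond
(Schechter–Berger nomenclature: P1 is N-terminal to the scissile bond,
P1′ C-terminal). Each position carries an `allow` or `deny` residue set;
a rule must constrain P1; an enzyme fires when *any* of its rules fires.
Window positions that fall off the sequence ends fail `allow` constraints
and satisfy `deny` constraints — a bond near a terminus simply lacks the
required context residue. Wider contexts than P4–P4′ are out of scope:
no specificity description we model needs them.

## The bundled ruleset and its provenance

`default_ruleset()` ships six enzymes under the label `biopep_2020`:

| enzyme | rule |
|---|---|
| pepsin (EC 3.4.23.1) | P1 ∈ {F, L} |
| trypsin (EC 3.4.21.4) | P1 ∈ {K, R}, P1′ ∉ {P} |
| chymotrypsin (EC 3.4.21.1) | P1 ∈ {F, Y, W, L, M}, P1′ ∉ {P} |
| stem bromelain (EC 3.4.22.32) | P1 ∈ {K, A, Y, G} |
| ficin (EC 3.4.22.3) | P2 ∈ hydrophobic, P1 ∉ {P}, P1′ ∉ {P} |
| papain (EC 3.4.22.2) | P1 ∈ {K, R}, P1′ ∉ {V}; or P2 ∈ hydrophobic, P1 ∉ {P}, P1′ ∉ {V} |

Pepsin and trypsin are the canonical textbook rules. The three plant
cysteine proteases are transcriptions of qualitative specificity summaries
(supplier catalogues and MEROPS-style descriptions): bromelain's
preferential cleavage after Lys/Ala/Tyr/Gly, and the papain-family
hydrophobic-P2 preference for papain and ficin. These qualitative sources
do not pin down a unique rule table, and different database snapshots
encode them differently; the ruleset is therefore **data, not code** — a
YAML file in a documented schema (`parse_ruleset()`) that users can
replace wholesale. The package's engine correctness does not rest on any
particular ruleset: it is established against an independent brute-force
oracle and synthetic ground truth (below). Reproducing the published
reference DH~t~ values for real collagen chains additionally requires the
exact UniProt mature sequences, which the test suite fetches live; that
check is network-dependent by nature.

A deliberate limitation shared with the approach we model: sequences are
plain 20-letter chains. Hydroxyproline — abundant in collagen — is not
representable, and rules cannot distinguish Pro from Hyp.

## The synthetic generator

`generate_collagen_like()` emulates the structural signature of the
collagen triple helix: `n_triplets` G-X-Y triplets whose X/Y positions are
drawn from a proline-dominant composition (default: P 0.50, A 0.12,
E 0.08, S 0.06, Q 0.05, R 0.05, D 0.04, L 0.04, K 0.03, F 0.03). The
default approximates collagen's Gly/Pro/Ala dominance while giving
pepsin and trypsin site densities in the low-DH~t~ regime characteristic
of collagen chains; the default length of 340 triplets (1020 residues)
matches the order of magnitude of a collagen α-chain helical region.
Seeds are mandatory and all randomness is local — no global RNG state is
consulted or leaked.

`plant_motifs()` overwrites triplet-aligned segments with bioactive motifs
at seeded positions. With `flank_mode = "cuttable"` the residue preceding
each copy is drawn from a P1 allow-set of the spec's enzymes, so that (for
motifs whose last residue is itself a P1 residue of the enzyme, such as
`RL` under pepsin) every copy is released and $W = 1$ analytically. With
`flank_mode = "inert"` flanks avoid the enzymes' cleavage context
entirely. Chance copies of a motif in the random background would spoil
the arithmetic, so the generator *scrubs* them — one X/Y-position residue
inside each accidental match is replaced by a residue foreign to every
motif — and then validates that each motif occurs exactly its planted
number of times, retrying placement under derived seeds and failing
loudly rather than returning an inconsistent fixture.

Every ground-truth value (`expected_A`, `expected_AE`, `expected_W`,
`expected_DHt`) is computed by a naive brute-force pass — a
position-by-position substring scan and a per-bond window test — that
shares no code with the vectorized engine. Tests then demand *exact*
equality (identical floating-point values, not tolerances), which is
attainable because both sides perform the same final division by $N$.

What passing these tests shows — and what it does not: the synthetic
chains reproduce the compositional statistics and repeat structure of
collagen, but not hydroxyproline chemistry, triple-helix accessibility,
or the curated diversity of a real bioactive-peptide database. Results on
real proteins inherit the usual caveats of complete-digestion models:
in vitro hydrolysates routinely contain fewer (or other) peptides than
the simulation predicts.

## Peptide chemistry

`peptide_to_smiles()` condenses per-residue templates (L-configuration,
verified against reference isomeric SMILES) through amide bonds. The
ionized form carries the dominant species at neutral pH: N-terminal
ammonium (+1; `[NH2+]` for proline), C-terminal carboxylate (−1),
Asp/Glu carboxylates (−1), Lys ammonium and Arg guanidinium (+1).
Histidine (pK~a~ ≈ 6) and cysteine are left neutral — the standard
dominant-species assumption. The neutral and ionized strings share one
heavy-atom graph.

Descriptors follow medicinal-chemistry convention: MW from *average*
residue masses plus one water; H-bond donors counted as N–H/O–H
*hydrogens* and acceptors as N+O *atoms*, both on the neutral form; logP
from OpenBabel's atom-contribution (Wildman–Crippen) model via
`ChemmineOB`. The scope is short fragments (1–10 residues), which covers
every released peptide this kind of screen promotes to chemistry.

`rule_of_five()` reports the four Lipinski flags, their strict
conjunction, and the conventional verdict `fulfills_ro5` (at most one
violated criterion). The distinction matters: under hydrogen counting,
arginine's guanidine alone contributes four donors, so small Arg- or
Gln-containing peptides exceed five donor hydrogens while passing MW,
logP and the acceptor bound with wide margins. Drug-likeness screens
that print a single "Rule of 5" verdict flag a compound only when two or
more criteria fail — that reading is what the bundled ACE/DPP-IV peptides
are tested against (all nine fulfill it; the Arg/Gln-containing ones carry
exactly one violation each).

## Numerical and reporting conventions

* Full precision is kept internally and in JSON output; formatted tables
  print A, A~E~, W with 3 decimals and DH~t~ with 2.
* Values rounding to 0.000 are blanked in formatted tables; a row is
  dropped only when both A~E~ and W vanish. This mirrors reports in which
  an activity shows a W value while its A~E~ rounds away.
* Undefined W ($A = 0$) is blank in TSV, `null` in JSON.
* Report rows sort by descending parameter, then activity code — output
  is deterministic, and repeated runs are byte-identical.
* Ties and degenerate inputs: a single-residue chain has one fragment and
  DH~t~ = 0; an empty activity database yields empty profiles, not errors;
  unknown activity codes query to the empty set.

## Problem sizes used in the checks

The bundled verification runs use 1000 random sequences (length ≤ 50)
for engine-vs-oracle equivalence, all 400 dipeptides for the ionization
invariants, 100 seeded ground-truth fixtures (40–80 triplets) for exact
parameter recovery, and a 20-protein synthetic cohort at the default 340
triplets for the DH~t~ summaries. These sizes give full coverage of the
rule alphabet and the motif arithmetic while keeping a complete run in
well under a minute on one core.

## A worked example

```{r example}
rs <- default_ruleset()
db <- builtin_fixture()
toy <- protein_record("toy", "GKGFRL")

profile_occurrence(toy, db)

dg <- digest(toy, rs["pepsin"])
dg$fragments
theoretical_degree_of_hydrolysis(dg)

profile_release(toy, dg, db)

rule_of_five(compute_descriptors("RL"))
```

## Known limitations

* Complete-digestion arithmetic only: no missed cleavages, no kinetics.
* The bundled plant-protease rules are qualitative transcriptions; swap in
  your own ruleset to model a specific database snapshot.
* No hydroxyproline or other post-translational modifications.
* The bundled activity database is the nine-peptide ACE/DPP-IV set with
  literature IC50 metadata — a reproducible stand-in, not a replacement
  for a full curated snapshot (the TSV schema accepts any).
* PeptideRanker-style bioactivity likelihoods are accepted as external
  annotation input and joined into reports, never computed.
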