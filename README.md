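# biopepsim

In silico proteolysis and bioactive peptide release profiling in R.

Food proteins encrypt short bioactive peptides — ACE (angiotensin
I-converting enzyme) inhibitors, DPP-IV (dipeptidyl peptidase IV)
inhibitors, antioxidative fragments and more — that enzymatic hydrolysis
can liberate. Collagen-rich raw materials are a prime example. `biopepsim`
is for researchers who want to screen protein sequences for this
potential before going to the bench: it simulates complete enzymatic
hydrolysis with rule-based cleavage specificities, matches intact chains
and released fragments against a peptide-activity database, and computes
the standard quantitative parameters of the field:

- **A** — frequency of occurrence of peptides with a given activity:
  `A = a / N` for `a` (overlapping) occurrences in a chain of `N`
  residues, binned as *major* (A ≥ 0.500), *moderate* (0.100 ≤ A < 0.500)
  or *minor* (0 < A < 0.100);
- **A_E** — frequency of release by the selected enzyme(s):
  `A_E = d / N` for `d` digest fragments exactly equal to an active
  peptide;
- **W = A_E / A** — the relative release (share of the encrypted
  potential actually liberated);
- **DH_t** — theoretical degree of hydrolysis: `100 · |cuts| / (N − 1)` %
  of peptide bonds cleaved.

Cleavage rules constrain a P4–P4′ window around each bond (e.g. trypsin:
P1 ∈ {K, R}, P1′ ∉ {P}); digestion is complete and simultaneous on the
intact chain, so multi-enzyme cut sets are unions and DH_t is
sub-additive. The package also ships a collagen-like synthetic sequence
generator (G-X-Y triplets, Pro-rich composition) with planted motifs and
an independent brute-force oracle, peptide→SMILES construction with
neutral-pH ionization, and Lipinski Rule-of-5 evaluation.

## Worked example

```r
library(biopepsim)

rs  <- default_ruleset()      # six enzymes, "biopep_2020" specificities
db  <- builtin_fixture()      # nine ACE/DPP-IV inhibitor peptides
toy <- protein_record("toy", "GKGFRL")

profile_occurrence(toy, db)
#>   protein_id activity_code a_count         A      bin
#> 1        toy            ah       2 0.3333333 moderate
#> 2        toy           dpp       2 0.3333333 moderate

dg <- digest(toy, rs["pepsin"])
dg$fragments$sequence
#> [1] "GKGF" "RL"
theoretical_degree_of_hydrolysis(dg)
#> [1] 20

profile_release(toy, dg, db)
#>   protein_id enzymes activity_code d_count       A_E   W a_count         A
#> 1        toy  pepsin            ah       1 0.1666667 0.5       2 0.3333333
#> 2        toy  pepsin           dpp       1 0.1666667 0.5       2 0.3333333
```

Reading: the toy chain contains two ACE-inhibitor occurrences (GF and
RL), so `A(ah) = 2/6 = 0.333`. Pepsin (P1 ∈ {F, L}) cuts one bond (DH_t =
1/5 = 20%) and liberates exactly `RL`, so `A_E = 1/6 = 0.167` and half the
encrypted ACE-inhibitory potential is released (`W = 0.5`).

Released peptides can be pushed through the chemistry stage:

```r
rule_of_five(compute_descriptors("RL"))
#> <lipinski_report> RL: + (1 violation(s))
```

`RL` fulfills the Rule of 5 in the conventional sense (at most one
violated criterion: arginine's guanidine exceeds the five-donor bound
while MW, logP and the acceptor count pass with wide margins).

The full pipeline over a FASTA file, including report files and a run
manifest:

```r
res <- run_pipeline("proteins.fasta",
                    enzyme_sets = list("pepsin", "trypsin",
                                       c("pepsin", "trypsin")),
                    db = "fixture", out_dir = "reports", format = "tsv")
```

A thin command-line wrapper with `run`, `digest`, `profile`, `release`,
`chem` and `synth` subcommands lives at `inst/cli/biopepsim.R`.

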