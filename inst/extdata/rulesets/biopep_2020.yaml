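# Default enzyme-specificity ruleset.
#
# Positional constraints use Schechter-Berger nomenclature: P1 is the
# residue N-terminal to the scissile bond, P1' the residue C-terminal to it.
# Residue sets are letter strings; every rule must constrain P1.
#
# Provenance: transcriptions of published qualitative specificity summaries.
#   pepsin (pH 1.3)  - preferential cleavage after Phe and Leu
#   trypsin          - after Lys/Arg, not before Pro
#   chymotrypsin A   - after aromatic residues (Phe/Tyr/Trp) and, at lower
#                      rate, Leu/Met; not before Pro
#   stem bromelain   - broad cysteine protease; preferential cleavage after
#                      Lys, Ala, Tyr, Gly
#   ficin            - papain-family; bulky hydrophobic P2 preference with
#                      broad P1 acceptance (Pro resists at P1 and P1')
#   papain           - after Arg/Lys (not before Val), plus the classical
#                      hydrophobic-P2 rule
# The file is data, not code: replace it to model another specificity
# snapshot, and keep the schema (see parse_ruleset()).
name: biopep_2020
enzymes:
  stem_bromelain:
    ec: 3.4.22.32
    rules:
      - P1: {allow: KAYG}
  ficin:
    ec: 3.4.22.3
    rules:
      - P2: {allow: FLVIWYA}
        P1: {deny: P}
        "P1'": {deny: P}
  papain:
    ec: 3.4.22.2
    rules:
      - P1: {allow: RK}
        "P1'": {deny: V}
      - P2: {allow: FVLIWYA}
        P1: {deny: P}
        "P1'": {deny: V}
  pepsin:
    ec: 3.4.23.1
    rules:
      - P1: {allow: FL}
  trypsin:
    ec: 3.4.21.4
    rules:
      - P1: {allow: KR}
        "P1'": {deny: P}
  chymotrypsin:
    ec: 3.4.21.1
    rules:
      - P1: {allow: FYWLM}
        "P1'": {deny: P}
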