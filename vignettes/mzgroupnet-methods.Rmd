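---
title: "Transformation networks from time-series LC-MS data: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transformation networks from time-series LC-MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzgroupnet)
```

## The model

`mzgroupnet` treats an untargeted metabolome time series as a directed
graph over *m/z* features. A feature is one detected ion with an observed
mass-to-charge ratio, the set of time points at which it was observed, and
a ranked list of candidate sum formulas within a mass-accuracy window. A
**transformation rule** is a named signed elemental delta
(methylation = +1C+2H, dehydration = −2H−1O, ...). An edge A → B under rule
Δ exists iff some candidate pair satisfies `f_B − f_A = Δ` by exact integer
composition arithmetic, and A does not first appear after B.

The assumptions this encodes:

1. **Compositional matching beats mass matching.** Matching is not "mass
   difference within a tolerance" but exact integer equality of elemental
   deltas between candidate formulas. Two wrong candidates rarely differ by
   exactly a biochemical delta, while the correct pair always does; a
   shared transformation therefore simultaneously detects the reaction and
   votes for the right formulas on both sides. This is the central design
   decision; a mass-tolerance variant would confound isobaric deltas
   (e.g. +CH2 vs +N at nominal 14).
2. **Chronology constrains direction.** A product cannot precede its
   substrate in the series, so edges with `first(A) > first(B)` are
   discarded. Equal first appearance is allowed: sampling is far coarser
   than enzyme kinetics, and forbidding ties would delete every reaction
   whose substrate and product both appear between two samplings.
3. **Rules are directed.** A reaction and its reverse are separate entries
   (hexosylation / dehexosylation); the rules file, not the matcher,
   decides which directions exist.

### Exact masses

Theoretical ion m/z is `(Σ n_e M_e − z m_e)/|z|` with monoisotopic atomic
masses to ≥ 9 decimals (C = 12 exactly, H = 1.0078250319,
O = 15.9949146196, ...) and the electron mass `m_e` = 0.00054857990907 Da.
Anthocyanins ionize as intact flavylium cations, so their reference masses
are electron-corrected `[M]+` values, **not** `[M+H]+`; this is the only
charge interpretation that reproduces the published reference table (35 of
36 rows to ≤ 1e-5 Da; the 36th row is internally inconsistent by 0.01017 Da
and is treated as a typo — the discrepancy is asserted, not hidden, in the
test suite).

### Pathway semantics

The network is reduced to **maximal simple directed paths**: every simple
path is a contiguous sub-path of a reported pathway and no reported pathway
is contained in another. "Contiguous sub-path" (not scattered subsequence)
is the redundancy criterion because a pathway is a chain of consecutive
reactions; a 7-member chain is then reported as one object rather than 21
fragments. When both a rule and its reverse are loaded the graph can be
cyclic; the simple-path restriction plus a length cap (default 20 nodes)
bounds enumeration, and an explosion guard (default 10 000 raw paths)
truncates with a warning — never silently.

## Tunable parameters

| parameter | default | units | why this value |
|---|---|---|---|
| `tolerance_ppm` | 1 | ppm | instrument-class mass accuracy of Orbitrap-type analyzers; the regime the candidate lists emulate |
| element bounds | C 100, H 200, O 50, N 10 | counts | standard search-space bounds for plant secondary metabolites up to ~1.6 kDa |
| `max_candidates` | 10 | — | the instrument-export cap on formulas per feature |
| `merge_ppm` | 2 | ppm | cross-time-point feature matching; 2× the assignment window so noisy reobservations of one feature still merge |
| `max_path_length` | 20 | nodes | above any plausible linear modification cascade; bounds cyclic enumeration |
| `novel_min_count` | 2 | pairs | a difference seen once is noise; twice across distinct feature pairs is a pattern worth reporting |
| `novel_max_delta_mass` | 300 | Da | covers single-group transfers (largest default rule, glutathionylation, is ~305 Da; sugar/acyl units ≪ 300) |

Candidate generation performs *no* chemical-plausibility filtering by
default (an optional RDBE ≥ 0 flag exists, off by default): the candidate
lists deliberately contain absurd compositions, because downstream
transformation matching — not filtering — is the disambiguation mechanism,
and pre-filtering would make the network look artificially clean in tests.

## The synthetic fixture: what it emulates, what it does not

`generate_fixture()` emulates the processed input of a 3-week oxidative
stress experiment on a plant rosette: seven sampling days (0, 2, 4, 8, 12,
16, 20), a planted anthocyanin elongation chain (cyanidin core *m/z* 287 →
hexoside 449 → coumaroyl 595 → pentosyl 727 → hexosyl 889 → malonyl 975 →
coumaroyl 1121) appearing on the schedule "core always present, first
glycoside after two days, the rest after four", 50 decoy features uniform
in 200–1600 Da, Gaussian m/z noise of 0.3 ppm, and up to 9 false candidates
per feature drawn from the exhaustive 1-ppm enumeration.

Design notes, fixed a priori:

* The three chain members without published reference masses (287, 449,
  595) are derived by subtracting the rule deltas from the anchored
  C35H35O17 at *m/z* 727.
* A step-4 day grid cannot represent the "after 2 days" appearance, so the
  grid is 0, 2, 4, 8, 12, 16, 20 — the 3-week span with a day-2 sample
  added.
* "Decoys unconnected to the chain" is enforced in m/z space: a decoy's
  observed m/z must lie ≥ 0.02 Da from every (chain m/z ± rule delta mass).
  This is necessary, not cosmetic: the false candidates are generated
  exhaustively, so a decoy sitting in such a window would *necessarily*
  acquire the rule-shifted composition among its candidates and attach to
  the chain. Decoy–decoy rule matches are left possible on purpose — they
  are the realistic background clutter.
* The true formula is always placed on its feature's candidate list (at its
  actual ppm error, ranked by |ppm| among the false candidates). Without
  this, a >3σ noise draw could silently break the chain for some seeds.

What the generator does **not** emulate: chromatographic peak shape,
retention-time information, isotope envelopes, adducts (Na+/K+),
in-source fragments, intensity dynamics, or missing observations. A green
end-to-end test therefore establishes that the algorithm recovers a known
chain under candidate ambiguity, realistic mass noise and unrelated
clutter — it does not establish robustness to adduct/isotopologue
redundancy, which a real dataset would add and which is out of scope here.

## The default rules file

The shipped file has 56 reaction steps. The reactions the method's
published applications rely on carry their literature deltas
(mono-oxygenation +O, hydrogenation +2H, hydration +H2O, methoxylation
+CH2O, methylation +CH2, oxidoreduction −2H, oxidation +O−2H, malonylation
+C3H2O3, hexosylation +C6H10O5, dihydroxylation +H2O2, coumaroylation
+C9H6O2, pentosylation +C5H8O4); the remainder are standard phase-I/II
biotransformations and acyl/glycosyl/prenyl transfers padded to 56 entries
with mutually distinct deltas. "Mono-oxygenation" (+O, hydroxylation) and
"oxidation" (+O−2H, net alcohol→acid-type change) are deliberately
distinct entries. The file is data, not code: users are expected to copy
and edit it, and `load_rules()` validates nonzero deltas and unique names
with row-numbered errors.

## Numerical choices and degenerate inputs

* **Hydrogen solving.** Candidate enumeration grids all non-H elements and
  solves H from the mass remainder; neighbouring H counts are probed so
  windows wider than one H mass (coarse tolerances) still see every
  lattice point. Completeness is enforced by an independent quadruple-loop
  oracle in the tests.
* **Tie-breaks.** Candidates with equal |ppm| order by formula string;
  rule-frequency ties order by rules-file position; pathway output orders
  by length descending then node sequence. All outputs are byte-stable
  across reruns (asserted on the Pajek export and the whole result
  directory).
* **Collapsing.** Multiple candidate pairs supporting the same
  (source, target, rule) collapse to one edge — the network is over
  features, not formulas — with every supporting pair retained in the
  `support` column, and the best-ranked pair supplying the display
  formulas.
* **Degenerate inputs.** Empty rule set: error before matching. Feature
  without candidates: skipped with a named warning. Empty candidate search
  space: empty result, not an error. Carbon-free formula in van Krevelen:
  skipped with a warning (ratios undefined). Empty network: valid Pajek
  file with zero vertices.
* **Per-formula support counts** (how often each candidate participates in
  edges) drive only the *display* formula choice (`choose_formulas()`,
  falling back to rank 1); they never feed back into matching.

## Known limitations

* No adduct or isotopologue de-duplication: one compound ionizing several
  ways becomes several nodes.
* Unlisted-difference mining reports both a delta and its negation when
  both directions occur; interpreting which is the "reaction" is the
  user's call.
* The maximal-path reduction is exponential in the worst case (dense
  bidirectional subgraphs); the cap and guard make this loud rather than
  slow, but very dense rule sets on large feature sets may need a lower
  `max_path_length`.
* Formula disambiguation is only as good as the rules: a wrong candidate
  pair differing by a listed delta still creates an edge (such decoy edges
  exist in the fixture runs and are tolerated by design; they are rare and
  short).
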