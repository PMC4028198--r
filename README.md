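# mzgroupnet

Mass-difference transformation networks and pathway inference for
time-series LC-MS metabolomics.

## The problem

Untargeted high-resolution LC-MS yields thousands of *m/z* features per
sample, most of them unidentified. Even at sub-ppm mass accuracy a single
measured mass maps to many elemental compositions, so formula assignment by
mass alone produces false positives. `mzgroupnet` exploits a different
signal: **chemistry between features**. If two features carry candidate
formulas that differ by exactly the elemental delta of a known reaction
(methylation = +1C+2H, hexosylation = +6C+10H+5O, ...), that shared
transformation both links the features into a putative reaction step and
disambiguates their formulas. Applied over a metabolome time series, the
matched steps assemble into a directed network from which non-redundant
pathways — including routes to previously undescribed compounds — are read
off directly.

It is written for metabolomics researchers who have per-time-point feature
tables (observed *m/z* plus ranked candidate sum formulas, e.g. exported
from an instrument's elemental-composition tool) and want automated,
reproducible transformation/pathway mining without manual pairwise
comparison.

## Method in brief

* **Exact cation masses.** For a composition with counts `n_e` and charge
  `z`, the theoretical mass-to-charge ratio is
  `m/z = (Σ_e n_e · M_e − z · m_e) / |z|` with monoisotopic atomic masses
  `M_e` and the electron mass `m_e`. Intrinsically charged ions (flavylium
  cations of anthocyanins, detected as `[M]+`) are handled as intact
  cations, not `[M+H]+` adducts.
* **Candidate generation.** Exhaustive enumeration of all compositions on a
  bounded element lattice (default C ≤ 100, H ≤ 200, O ≤ 50, N ≤ 10) whose
  theoretical *m/z* lies within a ppm window (default 1 ppm) of the observed
  value; no plausibility filtering by default — resolving ambiguity is the
  network's job.
* **Transformation matching.** For features A, B with candidate formulas
  `f_A`, `f_B` and rule delta `Δ`, a directed edge A → B is emitted iff
  `f_B − f_A = Δ` element-wise (exact integer arithmetic, no mass
  tolerance). A time filter discards edges that run against observed
  chronology (`first(A) ≤ first(B)` required).
* **Pathways.** Pathways are maximal simple directed paths: every simple
  path in the network is a contiguous sub-path of a reported pathway and no
  reported pathway is contained in another.
* **Rule ranking and novel-modification mining.** Edge counts per rule; and
  recurrent candidate-pair differences that match *no* rule are reported as
  suggestions for modifications missing from the rules file.
* **Van Krevelen mapping.** Each feature's chosen formula is plotted at
  (O/C, H/C); quadruples related by +CH2 and +O shifts ("rhombus" motifs)
  are detected by exact composition arithmetic.

The 56-rule default transformation list ships at
`system.file("extdata", "transformation_rules.csv", package = "mzgroupnet")`
and is meant to be copied and edited.

## Worked example

The built-in generator emulates a 3-week stress time series with a planted
7-member anthocyanin chain (cyanidin core, nominal *m/z* 287, progressively
glycosylated and acylated up to *m/z* 1121) plus 50 unrelated decoy
features, every feature carrying up to 10 candidate formulas within 1 ppm:

```r
library(mzgroupnet)
fx    <- generate_fixture(fixture_spec(seed = 1))
paths <- write_fixture(fx, "fixture")
res   <- run_pipeline(run_config(inputs = paths, out_dir = "results"))
#> [mzgroupnet] 56 transformation rules loaded
#> [mzgroupnet] 57 features read from 7 time point(s)
#> [mzgroupnet] 10 transformation edge(s) detected
#> [mzgroupnet] 2 non-redundant pathway(s)
#> [mzgroupnet] 50 unlisted recurrent difference(s)
#> [mzgroupnet] results written to results

p <- res$pathways
p[p$n_nodes == 7, c("nodes", "rules")]
#>                                 nodes
#> 1 M287;M449;M595;M727;M889;M975;M1121
#>                                                                                rules
#> 1 hexosylation;coumaroylation;pentosylation;hexosylation;malonylation;coumaroylation

head(res$rule_frequencies, 5)
#>             rule count
#> 1   hexosylation     2
#> 2 coumaroylation     2
#> 3   malonylation     1
#> 4  pentosylation     1
#> 5 dehexosylation     1
```

The 7-node pathway is the planted chain, recovered in order with the exact
reaction sequence despite the decoys and the candidate-formula ambiguity:
cyanidin (287) is hexosylated (449), coumaroylated (595), pentosylated
(727), hexosylated again (889), malonylated (975) and coumaroylated into
the terminal acylated anthocyanin at *m/z* 1121. The second pathway is the
same chain read backward through the degradation (de-acylation) rules among
members that first appear at the same time point. `results/` holds the five
standard artifacts: transformations table, rule-frequency ranking,
unlisted-difference suggestions, a JSON results bundle (plus pathways CSV),
and a Pajek `.net` file; `van_krevelen.csv` carries the O/C–H/C scatter
data.

The same pipeline is available from the shell:

```sh
mzgroupnet synth --out fixture --seed 1
mzgroupnet run --inputs fixture/t0_day0.csv,...,fixture/t6_day20.csv \
               --rules rules.csv --out results
mzgroupnet rules --validate rules.csv
```

(the `mzgroupnet` script is installed under `exec/` in the package
library).

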