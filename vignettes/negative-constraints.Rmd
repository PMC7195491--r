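---
title: "Identifying negative constraints in paralog interaction families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying negative constraints in paralog interaction families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negcon)
```

## The model

Paralog families such as the *Drosophila* DIP and Dpr adhesion receptors
partition into interaction-specificity subgroups: sets of paralogs that
bind members of one cognate subgroup on the opposite family side and
reject all others. With seven subgroups per side there are 49 subgroup
combinations, of which only 7 are cognate; the remaining 42 must each be
destabilized by *negative constraints* — interfacial residues whose
identity in one subgroup is incompatible with the non-cognate partner's
interface, while remaining tolerated (or favorable) in the cognate
complex.

`negcon` identifies candidate negative constraints per
(non-cognate pair, interface side, family-wide position) by intersecting
two independent sources of evidence.

### The energy filter

The input is a table of binding free-energy changes (ΔΔG, kcal/mol) from a
mutational scan performed externally on template complexes of each cognate
subfamily (e.g. FoldX BuildModel/AnalyseComplex on crystal structures or
homology models; `foldx_table_notes()` documents the mapping, and the scan
engine itself is deliberately outside the package). Each record is the
replicate mean over the scan's runs (ten in the reference protocol):
`aggregate_runs()` applies this averaging convention.

For a candidate position the filter requires that mutating the template's
wild-type residue into the residue of *every* member of the non-cognate
subgroup is destabilizing, ΔΔG ≥ 0.05 kcal/mol, on *every* template
complex of the cognate subfamily. Two deliberate asymmetries follow from
the universal quantifier:

* **Fail-closed coverage.** If any required (template × member) record is
  missing, the position cannot be certified and fails. This mirrors the
  strict all-templates rule: one template disagreeing, or simply missing,
  vetoes the call.
* **Not-applicable positions.** A member that shares the template's
  wild-type residue generates no mutation and no requirement. If *all*
  combinations are identity-shared, the position is reported with status
  `not_applicable`, never as passed.

The threshold is the replicate-mean ΔΔG, not per-run values (the mean
defines the binding ΔΔG; runs are diagnostics), and the comparison is
inclusive (≥ 0.05) because 0.05 kcal/mol is exactly the standard deviation
observed when mutating interfacial residues into themselves — the noise
floor of the scan.

### The evolutionary filter

Negative constraints should be conserved across the orthologs of a
subfamily, on the assumption that orthologs within a subfamily retain
their interaction specificity. The filter compares the two subfamilies'
alignment columns at a position and accepts when at least one of three
conditions holds:

1. **Conserved and different in identity.** Both columns have base-21
   Shannon entropy $S = -\sum_i f_i \log_{21} f_i < 0.23$, where the
   $f_i$ are exact symbol frequencies over the 21-letter alphabet (20
   amino acids plus gap), and the columns' modal-residue sets are
   disjoint. The base 21 normalizes $S$ to $[0,1]$.
2. **Biophysical property difference > 90%.** Residues are binned as
   hydrophobic (I,V,L,M,F,W,A,C,G,P), polar (S,T,Q,N,H,Y), positively
   charged (K,R), or negatively charged (E,D); each cross-class residue
   pair contributes its occurrence weight
   $f_{aa_i} \cdot f_{aa_j} \cdot 100\%$.
3. **Size-class difference > 90%.** Residues are binned by volume, tiny
   (G,A,S) < small (C,D,P,N,T) < medium (E,V,Q,H) < large (M,I,L,K,R) <
   bulky (F,Y,W). Two directional sums are formed — subfamily-*i* residue
   strictly larger, and strictly smaller, than the subfamily-*j* residue —
   and the score is their maximum, so only a *consistent* size shift can
   pass; mixed directions split the mass (e.g. a 50/50 tiny/bulky column
   against a medium column scores 50, not 100).

A call requires the energy filter *and* the evolutionary filter; the
pipeline applies them in that order and the final accepted set is by
construction a subset of each filter's accepted set.

### From K_D to ΔΔG

Experimental validation compares predictions against surface plasmon
resonance dissociation constants via
$\Delta\Delta G = RT \ln(K_{D,\mathrm{mut}}/K_{D,\mathrm{wt}})$ with
$R = 1.9872 \times 10^{-3}$ kcal mol⁻¹ K⁻¹ and $T$ defaulting to
298.15 K (the 25 °C assay temperature). Units cancel in the ratio; the
reference measurements are in μM.

```{r kd}
kd_to_ddg(7.9, 131)   # a double mutant weakening binding ~17-fold
kd_to_ddg(10, 500)    # a 50-fold weakening, ~2.3 kcal/mol
```

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `ddg_threshold` | 0.05 | kcal/mol | energy-filter destabilization floor; equals the self-mutation spread |
| `entropy_cutoff` | 0.23 | base-21 entropy | conservation bound; a clean 50/50 two-residue column scores $\log_{21} 2 \approx 0.2277$, just inside |
| `property_cutoff` | 90 | percent | condition 2; strict `>` |
| `size_cutoff` | 90 | percent | condition 3; strict `>` |
| `temperature` | 298.15 | K | K_D conversion |

All comparisons are made at full double precision; nothing is rounded
before a cutoff comparison. Strictness follows the operating point as
stated: conservation is `S < 0.23`, percent acceptance is `> 90`, the
energy floor is `>= 0.05`.

## Design choices where the protocol is underspecified

Several details of the protocol admit more than one reasonable reading;
the package fixes them as follows.

* **"Different in identity" for non-degenerate columns.** Condition 1 is
  evaluated on modal-residue sets: all residues attaining the column's
  maximum frequency, gaps excluded from modality. The condition requires
  the two sets to be disjoint. This reduces to consensus comparison when
  modes are unique and is conservative under ties (a shared tied mode
  blocks acceptance).
* **Gap handling in the percent differences.** The sums run over amino
  acid pairs only: gap frequency contributes to no pair and, by default,
  is *not* renormalized away, so gap-rich columns cannot reach the 90%
  cutoffs. That is fail-safe for constraint calling. Renormalization over
  the 20 amino acids is available behind
  `evo_filter_params(renormalize = TRUE)` for sensitivity analysis.
* **Pairwise identity with gaps.** `mean_pairwise_identity()` excludes
  gap–gap columns from both numerator and denominator and counts
  gap-vs-residue as mismatch — deterministic and conservative for
  conservation claims.
* **Interfacial assignment.** "Non-zero change in accessible surface
  area" is encoded as strictly positive ΔASA; negative values are
  rejected at parse time.
* **Indexing.** Alignment columns, family positions and residue numbers
  are all 1-based, the R convention; after
  `extract_interfacial_columns()` family position *p* is simply column
  *p*. File formats carry 1-based `alignment_column` values.
* **Cutoff monotonicity.** Tightening any cutoff (raising the ΔΔG floor
  or the percent cutoffs, lowering the entropy bound) never converts a
  rejected position into an accepted one; note that the entropy bound
  tightens *downward*, since a smaller bound admits fewer columns as
  conserved.
* **Per-template strictness.** Each template complex id is a separate
  requirement; alternative crystal conformations supplied as distinct
  templates must therefore each be destabilized.

## The synthetic-data generator

Real constraint tables require structures, a mutational-scan engine and
curated ortholog alignments, none of which are desk-reproducible. The
generator (`scenario_config()`, `generate_scenario()`) instead plants
ground truth with the statistical structure the filters assume, so the
pipeline can be validated by recovery.

Each family position is assigned a class:

* `conserved_core` — one residue shared by all subgroups, mimicking the
  conserved hydrophobic core and invariant polar anchors of a real
  interface;
* `identity_divergent` — each subgroup a distinct conserved residue,
  drawn from a single size class as far as the subgroup count allows
  (beyond five subgroups the preference list spills into the adjacent
  class);
* `property_divergent` — subgroup consensus residues alternate across
  property classes;
* `size_divergent` — consensus residues alternate across size ranks
  1/3/5, so most subgroup pairs sit ≥ 2 ranks apart;
* `neutral` — every sequence draws a uniform random residue.

The default plan cycles these classes along the 33 positions (7/7/7/6/6).
Member sequences derive from the subgroup consensus, and ortholog rows
from their member, by per-residue substitution noise ε (default 0.02,
chosen to keep within-subgroup ortholog identity in the high-90s percent
range, comfortably inside the ~84% within-subfamily ortholog identity
regime of real insect alignments while retaining realistic column noise).
Each subgroup's alignment holds `members_per_subgroup` ×
`orthologs_per_member` rows (3 × 4 = 12 by default; 4 ortholog rows per
member keeps column frequency estimates coarse enough to stress the
entropy cutoff without inflating runtime).

ΔΔG records are generated for every non-cognate pair, side, position,
template and differing source member: ten runs i.i.d. Normal(μ, 0.05)
averaged into the record mean. μ is 1.0 kcal/mol at planted constraints —
within the destabilizing range observed for confirmed constraints and 19
standard errors of the 10-run mean above the 0.05 threshold — and 0
elsewhere, except that a non-planted (pair, side, position) draws a
stabilizing mean of −0.5 kcal/mol with probability 0.1, emulating the
stabilizing mutations real scans report (interfaces are not fully
optimized for binding). Ground truth plants constraints *jointly*: a
planted position is simultaneously sequence-divergent and energetically
destabilizing, because calls require both filters; `plant_energy = FALSE`
decouples them, giving the null control in which the divergent alignments
remain but all energetic effects are null — a false call then requires
both filters to fail together.

All stochastic draws derive from the single config seed (the ddG
substream is offset so alignments and energies are independently
reproducible), and identical seeds give byte-identical scenario files.

### What the generator does and does not emulate

It reproduces the *statistical contract* of the filters: conservation and
divergence patterns at controlled strength, scan noise at the measured
self-mutation spread, complete or deliberately incomplete coverage, and
the registry/pair combinatorics (the default seven-by-seven layout yields
the family's 49/42 split). It does not simulate structures, physical
energetics, phylogenetic correlation between orthologs, alignment errors,
or indels; columns are independent, whereas real interfacial columns
co-vary. Passing recovery therefore shows the protocol's logic and
implementation are sound at its operating point — not that the operating
point is optimal for any particular real family.

## Validation results computed by this package

With the reference conditions (7×7 subgroups, 33 positions, 3 members per
subgroup, 3 templates per cognate pair, μ = 1.0, run sd = 0.05,
ε = 0.02), the pipeline recovers planted constraints with mean precision
and recall ≥ 0.95 over 20 seeds (precision is typically exactly 1; the
lost recall comes from planted positions where substitution noise pushes
a column's entropy past 0.23). The determinized variant (ε = 0,
sd = 0) is recovered exactly, and the null control accepts on the order
of zero calls across all 42 pairs. These quantities are recomputed, not
quoted, by `scripts/acceptance.R` and the test suite; problem sizes were
chosen so a full validation completes in minutes on one core.

```{r pipeline, eval = FALSE}
run <- run_pipeline(tempfile("negcon"), scenario = scenario_config(seed = 11))
run$recovery[c("precision", "recall")]
```

## Known limitations

* The protocol inherits the scan engine's biases: a systematic error in
  the ΔΔG table propagates directly into calls. The package validates the
  *filters*, not the engine.
* Columns are treated independently; compensating double substitutions
  across positions (which preserve binding while flipping single-position
  verdicts) are invisible to both filters.
* The evolutionary filter needs enough ortholog rows per subfamily for
  frequencies to be meaningful; with very few rows the entropy estimate
  is coarse and condition 1 becomes brittle.
* Consensus combination of external specificity-position predictors
  (`consensus_combiner()`) consumes their outputs; the predictors
  themselves are not reimplemented.
* Physical-origin annotation of a constraint (steric clash, cavity,
  Coulombic repulsion, unsatisfied buried charge) requires structural
  inspection and is out of scope; the report leaves it to the analyst.
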