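---
title: "Designing thermostable multiple-point mutants with protstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing thermostable multiple-point mutants with protstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protstab)
library(dplyr)
```

## The design problem

Raising a protein's melting temperature by more than a few degrees almost
always requires several substitutions. Two families of computational
evidence are available for choosing them. *Energetic* evidence comes from
force-field calculators that predict the change in folding free energy
upon mutation (ΔΔG, kcal·mol⁻¹; negative = stabilizing in the convention
used throughout this package). *Evolutionary* evidence comes from a
multiple sequence alignment (MSA) of homologs: where the query deviates
from a strong family consensus, reverting to the consensus residue is a
plausible stabilizing change. Each kind of evidence alone has a high
false-positive rate, and even truly stabilizing single mutations can
interact antagonistically when combined. `protstab` implements the full
decision pipeline around these two arms — candidate generation,
filtering, pairwise additivity testing and greedy assembly — while the
expensive physics (the ΔΔG calculations themselves) and the phylogenetic
rate inference remain external and are consumed as tables.

## Evolution arm

`read_alignment()` ingests aligned FASTA or Clustal files; all positions
are reported in 1-based coordinates over the gap-free query sequence and
mutations in `wtPOSsub` notation (e.g. `C128F`). Two back-to-consensus
rules generate candidates from per-column residue frequencies:

* **Simple consensus** (`simple_consensus()`): the column's most frequent
  residue c is proposed when c differs from the query's wild type and
  f(c) ≥ `cutoff` (default 0.5 — "at least half of the analysed
  sequences", applied inclusively).
* **Frequency ratio** (`frequency_ratio()`): c is proposed when
  f(c) ≥ `min_consensus_freq` (default 0.4) and the wild-type-to-consensus
  ratio f(wt)/f(c) ≤ `ratio_cutoff` (default 0.2). This targets positions
  where the query residue is rare against a strong consensus.

Design choices that the underlying procedure leaves open, decided here
once and kept fixed:

* **Gap policy.** The denominator of a column frequency is not dictated
  by the rules above. The default (`exclude_gaps`) counts frequencies
  over non-gap residues; `count_gaps` divides by the number of sequences
  instead, which makes heavily gapped columns unable to reach any cutoff.
  Both are exposed because either convention is defensible; the default
  matches how consensus approaches are usually described.
* **Ties.** When two residues tie for most frequent, the non-wild-type
  residue wins (a 50/50 column can still propose a candidate under the
  inclusive cutoff), then alphabetical order. Deterministic and tested.
* **"Target residue".** In the frequency-ratio rule the numerator is the
  query's wild-type residue frequency — the mutation's origin.
* **Masking.** Poorly aligned regions are excluded by user-supplied
  position ranges (`mask_ranges()`); the package deliberately does not
  score alignment quality itself.
* **Candidate invariant.** The proposed residue is always the column's
  modal residue, so `consensus_freq ≥ wt_freq` holds for every candidate.

`reduce_redundancy()` offers a simple greedy identity filter (query kept
first, then input order; drop when pairwise identity over shared non-gap
columns exceeds the cutoff) for users who have not already made their MSA
non-redundant with a dedicated clustering tool.

### Conservation and correlation filters

Functionally important positions should not be mutated regardless of
predicted energy. Two per-position profiles drive this:

* **Conservation grades.** Site-specific normalized evolutionary rates
  (more negative = more conserved) are discretized into grades 1–9 by
  `grades_from_rates()`: equal-width binning of the observed rate range,
  grade 9 for the most conserved bin, grade 5 everywhere for a degenerate
  (constant) input. This is a declared stand-in for the ConSurf partition,
  whose exact bin boundaries are not public; externally computed grades
  can be imported with `read_position_scores()` and used verbatim, and
  take precedence when available. Positions with grade ≥ 8 (inclusive)
  are treated as immutable.
* **Correlated mutations.** `correlation_scores()` scores each position
  by the maximum over partner columns of normalized mutual information
  (MI divided by the smaller column entropy; constant columns score 0 by
  convention; only rows non-gapped in both columns enter each pair). This
  is an explicit approximation to dedicated co-variation tools — those
  algorithms are proprietary or unpublished in detail — and external
  scores can again be imported. Positions with score ≥ 0.8 (inclusive)
  are excluded. With fewer than three sequences the statistic is
  meaningless and the function degrades to zeros with a warning.

## Energy arm

`parse_ddg_table()` reads per-structure ΔΔG predictions in a generic TSV
dialect and in lenient FoldX-BuildModel-style and Rosetta-ddg-monomer-
style line formats (documented in the function help, with fixtures in the
test suite). `summarize_ddg()` averages replicates within each structure,
then per-structure means across structures — using several crystal
structures (or the chains of a multimer) smooths structure-specific
artifacts. By default a mutation missing any expected structure is
excluded with a logged reason; a relaxed mode averages what is available
and warns, because discarding data is the kind of decision a user should
make knowingly.

`call_stability()` classifies mean ΔΔG with strict inequalities:
stabilizing below the tool's stabilizing threshold (FoldX −1.0, Rosetta
−2.0 kcal·mol⁻¹ — Rosetta's stricter threshold reflects its wider score
distribution), destabilizing above +0.5, neutral otherwise, so a value
exactly at a threshold is neutral. The boundary semantics ("smaller
than", "greater than") are declared rather than inferred; the test suite
pins them.

`energy_candidates()` intersects the two tools' stabilizing sets and
applies the conservation and correlation filters. A destabilizing call by
either tool vetoes a candidate even if the other calls it stabilizing
(the conservative reading of two-tool agreement; configurable). In the
pipeline driver the evolutionary filters run *before* the energy
evaluation — conservation filtering typically removes a third of the
mutation universe before any expensive calculation — but the result set
is identical either way, and a property test asserts exactly that over
100 random universes.

## Structure filters

`read_structure()` loads the first model of a PDB file (highest-occupancy
alternate locations, no waters or hetero atoms) through `bio3d`.
`find_salt_bridges()` flags Asp/Glu side-chain carboxyl oxygens within
4.0 Å (inclusive) of Arg/Lys/His side-chain nitrogens — His is counted as
positively charged, following common salt-bridge server practice — and
reports the minimum heavy-atom distance per residue pair. Only
intra-chain pairs count by default ("intra-molecular"); multimers are
handled by analysing each chain and taking the union.
`union_interactions()` keeps a contact if present in *at least one*
analysed structure or chain: a bridge seen in any conformation may be
real, so the filter errs on the side of protecting residues.
`filter_interacting()` then discards candidates whose wild-type residue
participates in any retained interaction, with machine-readable reasons.
Residue numbering is assumed to match sequence positions unless a mapping
table is supplied. Broader interaction classes (hydrophobic contacts,
aromatic stacking) influence expert curation in practice, but which
classes should veto a candidate is a judgment call; the package ships the
salt-bridge criterion as the default mechanism and leaves further
exclusions to the user via the same filter interface.

## Combining mutations

Additivity is tested at the level of double-point mutants:
`assess_pairs()` marks a pair antagonistic when its predicted double-
mutant ΔΔG is strictly greater than −3.0 kcal·mol⁻¹. The threshold is an
absolute criterion, not a comparison against the sum of the single
effects: two −2.5 singles whose double only reaches −2.5 are antagonistic
(the combination buys nothing), while a pair summing to −5.0 with no
epistasis passes comfortably. A sum-based alternative is easy to express
with the same table but is deliberately not the default.

`best_per_position()` resolves multiple candidates at one position to the
lowest mean ΔΔG (ties alphabetically by substitution).
`greedy_combine()` then scans candidates from most to least stabilizing
and admits each only if non-antagonistic with every already-admitted
mutation. This is the prescribed sequential procedure — not a maximum-
clique search, which could find larger additive sets but a different,
less reproducible one; given the sorted order and the antagonism
relation, the greedy result is unique, and a 500-instance property test
checks it against an independent re-implementation. The ranking key
defaults to the stricter tool's mean ΔΔG (`ddg_col`), with the other
tool's mean as tie-break (`tie_col`), since which tool's value orders the
scan is otherwise unspecified. `merge_designs()` unions two plans into a
hybrid; positions mutated differently in both plans are an error unless
the caller opts into `prefer_A`.

## Benchmarking stability callers

`curate()` applies the validation-dataset rules to experimental records:
keep |ΔΔG| ≥ 0.5 kcal·mol⁻¹ (inclusive; 0.5 is about the experimental
error of a ΔΔG measurement, so smaller effects are unresolvable), and
deduplicate each (protein, mutation) to the record measured closest to
pH 7, with deterministic tie-breaks (lower pH, then temperature closest
to 25 °C, then record id; missing pH always loses). Because stability
databases disagree on sign conventions, every input must declare one;
records are canonicalized to negative-is-stabilizing and labelled from
the canonical sign. Curation is idempotent, and a test asserts it.

`precision()` (TP/(TP+FP)) and `false_positive_rate()` (FP/(FP+TN))
return `NA` when undefined (no predictions, or no destabilizing records)
rather than 0 — an empty prediction set has no precision.
`threshold_sweep()` evaluates a caller over the grid −2.5 … +2.5
kcal·mol⁻¹ in 0.5 steps (11 thresholds; predict stabilizing iff
mean ΔΔG < t) and `evaluate_pipeline()` scores the combined two-tool rule
with conservation filtering. Whole-percent figures in reports use
half-away-from-zero rounding (`round_percent()`); stored metrics keep
full precision.

## Synthetic data: what it does and does not emulate

The generators exist so that every stage of the pipeline can be exercised
and its ground truth checked without external downloads.

* `simulate_msa()` plants consensus deviations at chosen positions
  (defaults: consensus frequency 0.8, wild-type frequency 0.05 in a
  50-sequence alignment — a strong, unambiguous back-to-consensus signal)
  as deterministic rounded counts, with the realized counts emitted as
  ground truth; background columns carry the query residue as a clear
  majority with 20% noise spread over several residues. Columns are
  i.i.d.: real alignments have phylogenetic correlation between rows,
  alignment errors and gap structure, so perfect recovery here shows the
  decision rules are implemented correctly, not that the rules themselves
  are robust on hard alignments.
* `simulate_ddg()` draws true single-mutant effects from a stabilizing
  tail (uniform −4 … −2) plus a near-neutral bulk (normal, mean +0.5, sd
  0.8 — calculators see many more neutral than stabilizing mutations),
  adds per-record Gaussian noise (default sd 0.1 kcal·mol⁻¹, small
  relative to the ±0.5 margins the planted effects keep from every
  decision threshold), and makes doubles exactly additive except for
  planted antagonistic pairs. Real predictors have correlated,
  heavy-tailed errors; the generator's independence assumptions are a
  clean-room, not a stress test.
* `simulate_structure()` writes minimal PDB records with charged-group
  atoms at exactly requested distances, pairs spaced 50 Å apart, so
  geometric assertions can be exact to 1e-6 Å.
* Each generator derives its own random stream from the master seed and a
  fixed label, so adding one generator never changes another's output;
  `simulate_project()` bundles them into a full study whose expected
  final design is known by construction.

## Problem sizes and numerical conventions

The test suite runs, among others: 200 random alignments (≤ 30 columns)
against a brute-force per-column consensus oracle; 500 random ≤ 12-
candidate combiner instances against an independent greedy oracle plus
clique re-validation; 200 random labelled datasets against a direct-
counting metrics oracle; and all-pairs distance checks on random
30-residue charged toy structures. These sizes make the full suite run in
about a minute while leaving the property space densely sampled. Column
frequencies must sum to 1 within 1e-9 (exclude-gaps); grade binning uses
half-open bins with the top value clamped into bin 9; all threshold
comparisons are exactly as documented (strict for energy calls and
antagonism, inclusive for consensus cutoffs, grade and correlation
filters, and the |ΔΔG| curation bound).

## Limitations

* ΔΔG values are consumed, never computed: the package's calls are only
  as good as the tables supplied.
* The conservation-grade binning and NMI correlation scores are
  documented stand-ins; when the corresponding dedicated tools are
  available, import their output instead.
* The salt-bridge criterion is purely geometric (no hydrogens, no
  electrostatics), and the default interaction filter covers salt bridges
  only.
* Predicting the ΔΔG of the final multi-point mutant — as opposed to
  vetting its pairs — is the external calculator's job; `protstab` stores
  such a value as provenance if supplied but never derives one.

## A complete run

```{r pipeline}
prj <- simulate_project(seed = 42)

consensus <- bind_rows(
  simple_consensus(prj$msa$alignment),
  frequency_ratio(prj$msa$alignment)
)
consensus

calls <- prj$ddg$singles |>
  summarize_ddg() |>
  call_stability()
cand <- energy_candidates(
  filter(calls, tool == "foldx"),
  filter(calls, tool == "rosetta")
)

pairs <- summarize_pairs(prj$ddg$doubles)
plan <- greedy_combine(
  rename(cand, mean_ddg = mean_ddg_b), pairs,
  tie_col = "mean_ddg_a", name = "demo-design"
)
glance(plan)
identical(sort(plan$mutation), prj$truth$expected_plan)
```
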