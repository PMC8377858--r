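---
title: "Designing and scoring pegRNAs with pegforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and scoring pegRNAs with pegforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design problem

A prime editor installs an arbitrary small edit — a substitution, an
insertion of up to tens of bases, or a deletion — through a pegRNA: a
standard 20-nt spacer, the sgRNA scaffold, and a 3' extension consisting
of a reverse-transcription template (RTT) followed by a primer-binding
site (PBS). The Cas9 nickase cuts the PAM strand between protospacer
positions 17 and 18; the PBS anneals to the freed 3' end, and reverse
transcription copies the RTT, writing the edit into the genome. A PE3
design adds a nicking guide (ngRNA) on the opposite strand; a PE3b
ngRNA matches only the *edited* sequence, delaying the second nick until
the edit is installed.

For one variant there are hundreds of admissible spacer × PBS-length ×
RTT-length × ngRNA combinations, and measured editing efficiencies
differ by an order of magnitude between them. pegforge enumerates the
combinations, describes each by 23 features in five categories (Cas9
activity, oligo properties, target-mutation properties, nick-relative
positions, RNA-folding disruption), and ranks designs with a
gradient-boosted regression model of efficiency trained under grouped
nested cross-validation.

## Coordinate conventions

All geometry lives in the *PAM-strand frame*: the design window oriented
so the protospacer reads 5'→3' with its NGG PAM 3' of it. Minus-strand
candidates reuse the same rules on the reverse-complemented window, so
there is a single set of coordinate conventions:

* `target_pos` — distance from the nick to the first edited base; +1 is
  the base immediately 3' of the nick. Edits are first normalized by
  stripping the common prefix, then the common suffix, of ref/alt (the
  VCF anchor base disappears here). The normalization happens once, on
  the window's plus strand, and the resulting physical edit is mapped
  into the minus frame — this makes enumeration exactly strand-symmetric
  even for placement-ambiguous indels.
* `target_end_flank` — template bases 3' of the edit (downstream
  homology): `rtt_len − (target_pos − 1) − (edited-allele length)`.
* `ngrna_pos` — signed nick-to-nick distance on the PAM-strand axis,
  positive 3' of the pegRNA nick. PE2 rows carry the sentinel 0; the PE2
  model never sees the column.
* Windows are 0-based half-open internally; 1-based coordinates appear
  only at the VCF/FASTA boundary.

ngRNA candidates are scanned on the *edited* window (a PE3b protospacer
does not exist before editing). `is_PE3b` = 1 when the protospacer+PAM
23-mer overlaps the edit span and does not occur on the unedited
opposite strand — i.e. the guide binds only the edited locus.

## Enumeration parameters

Defaults (all configurable via `peg_config()` or a key=value file):

| parameter | default | rationale |
|---|---|---|
| PBS length | 8–17 nt | spans the range tested in the foundational prime-editing screens |
| RTT length | 10–30 nt | idem; longer templates add synthesis burden |
| ngRNA distance | ±150 nt | nicks beyond this window contribute little |
| min. downstream homology | 5 nt | below this, flap resolution becomes unreliable |
| max `target_pos` | `rtt_max − min_end_flank` (25) | the template must clear the edit with homology to spare |
| design window | ±200 nt | ample for every admissible spacer |
| scaffold | 76-nt SpCas9 sgRNA scaffold | with a 20-nt spacer, scaffold position 61 is the full-pegRNA G81 implicated in first-template-base C pairing |

Extensions whose first template base is C are *flagged, not filtered*:
the efficiency model learns the scaffold-pairing penalty through the
folding features, and the tool must still be able to score such designs.

## RNA-folding disruption scores

The full pegRNA (spacer + scaffold + extension, T→U) is folded as one
molecule and reduced to
$$D(i) = \max_j P(i',\, j), \qquad j \in \text{scaffold},$$
where $i'$ is extension position $i$ (position 1 abuts the scaffold 3'
end, continuing into the PBS when the template is shorter than $i$) and
$P$ is the base-pair probability matrix. High $D$ means the extension is
predicted to invade the scaffold structure — the mechanism behind the
known first-template-base-C penalty (pairing with scaffold G81). The
ten scores $D(1..10)$ are model features; `position_correlation_profile()`
extends the analysis to 16 positions with permutation p-values.

Two folding engines are provided:

* `simple` — the package's own exact McCaskill-style inside–outside
  recursion under a uniform energy model: every Watson–Crick or GU pair
  has energy −1 (Boltzmann weight $e^{\beta}$, default $\beta = 1$), no
  stacking, minimum hairpin loop of 3. The model is deliberately small
  enough that the whole probability matrix can be verified against
  exhaustive enumeration of every non-crossing structure, which the test
  suite does to $10^{-9}$ on hundreds of short sequences. The recursion
  runs in $O(n^3)$ (long double, compiled), making it fast enough to be
  the default in the pipeline. The global partition function over the
  whole pegRNA replaces a sliding-window computation: at pegRNA lengths
  (≤ ~180 nt) a full-length window is equivalent and simpler.
* `nearest_neighbor` / `external` — the ViennaRNA global partition
  function (`RNAfold -p`, 37 °C nearest-neighbor thermodynamics) for
  production-grade energies when the binary is on the PATH.

Numerical notes: probabilities are clamped to [0, 1]; the length cap
(default 500 nt) keeps the partition function inside long-double range;
GU wobble pairs count in both engines; positions beyond the extension
length score 0.

## The 23 features

`cas9_score`, `pbs_len`, `rtt_len`, `pbs_gc`, `rtt_gc` (fractions, not
percents — scale-free for trees), `is_dPAM`, `is_PE3b`, `n_sub`,
`n_ins`, `n_del`, `target_pos`, `ngrna_pos`, `target_end_flank`,
`fold_d1..fold_d10`. The schema is fixed and ordered; models persist a
schema fingerprint and refuse prediction on a mismatch. The PE2 model
uses 21 features (dropping `ngrna_pos` and `is_PE3b`); PE2 and PE3 are
trained separately.

Edit-operation counts use position-wise comparison for equal-length
alleles and otherwise a global affine alignment (match +1, mismatch −1,
gap open −2, gap extend −1, ties resolved toward substitutions). The
alignment is hand-rolled because the tie-break is part of the contract;
tests compare it against exhaustive alignment enumeration.

Cas9 activity is pluggable: a table scorer (feed any external
predictor's per-spacer scores through a two-column file — the fidelity
path), a documented deterministic surrogate (position-nucleotide weight
matrix with seed-proximal G preference, GC-optimum and poly-T penalties,
logistic-squashed to (0,1)) that keeps the pipeline self-contained, or
any user function. The surrogate is a fixed heuristic, not a trained
model, and is labelled as such.

## Efficiency model and evaluation protocol

Efficiency (percent scale) is regressed with gradient-boosted trees
(XGBoost, squared-error loss, 500 rounds by default). The evaluation
unit is the *target mutation* — genomic position plus target allele —
never the design row: all designs of one mutation share a `group_id`,
and the outer 5-fold cross-validation partitions groups, with a
programmatic leakage assertion. The inner loop is 3-fold grouped CV over
a randomized sample (default cap 60; raise to 3 888 for exhaustive) of
the grid: max_depth {2,5,9,14}, learning_rate {0.01,0.1},
min_child_weight {1,5,10}, colsample_bylevel/bytree {0.2,0.6,1},
subsample {0.2,0.6,1}, reg_alpha {0,0.1,1}, reg_lambda {0,1,2}.
Randomized search keeps desk-scale runs tractable; Spearman correlation
is the selection metric, matching how such models are reported. The
final model refits all rows with the parameter set chosen most often
across outer folds. One seed drives fold assignment, grid sampling and
tree fitting, and is recorded in the model file. An external train/test
split (e.g. one shipped with a public screen) is honored by
`train_test_split_train()`.

Attribution is per-feature mean |SHAP| (TreeSHAP contributions), with
the ten folding features additionally aggregated, mirroring how feature
importance is usually summarized for these models.

## What the synthetic generator does and does not emulate

`make_toy_locus()` engineers A/T-background contigs in which the only
NGG/CCN motifs are the ones placed on purpose, covering: single spacer,
multiple spacers, no spacer, a PE3b-capable site, a PAM-disrupting SNV,
and anchored insertion/deletion edits.

`simulate_training_table()` produces *real* enumerated designs over
random windows and simulates efficiency as
`clip(40 + Σ effect_f · z(feature_f) + N(0, 5), 0, 100)` with effects
(percent per SD) `cas9_score +12`, `fold_d1 −10`, `pbs_gc +6`,
`is_dPAM +5`, `target_pos −6`, `target_end_flank +3`, and weak
`n_sub/n_ins/n_del −0.5` — strong activity, first-position folding, PBS
GC, PAM-disruption and position effects over weak mutation-type effects,
qualitatively matching the attribution ordering reported for real prime
editing data. Simulated windows use a 60-nt flank and PBS 9–13 /
RTT 10–16 enumeration so a 2 000-row table builds in well under a
minute.

The generator reproduces design-feature geometry and a known monotone
feature–efficiency map; it does **not** emulate amplicon-sequencing
error, cell-state covariates, batch structure, or the saturation
behaviour of real efficiencies. Passing tests therefore demonstrate
protocol correctness (no leakage, signal recovery, calibration of the
pipeline machinery), not predictive accuracy on biological data — that
requires training on real screens ingested through the documented
training-table schema.

## Problem sizes used by the checks

The test suite verifies the folding engine against exhaustive
enumeration on 200 random sequences of length ≤ 14, the enumerators
against brute-force scanners on 100 random 80-nt windows across
SNV/insertion/deletion edits, feature extraction exhaustively on a
100-nt locus, and the ML protocol on 2 000-row simulated tables (signal
and null). The acceptance script re-runs the pipeline from scratch:
nested CV on a 1 500-row table, a 50-variant batch design, attribution
shares, and the folding C-vs-A gap. These sizes were chosen as the
smallest at which the statistical checks are stable.

## Known limitations

* NGG PAMs and 20-nt spacers only; no relaxed-PAM variants, no
  dual-pegRNA strategies, no off-target assessment.
* The simple folding engine's uniform energy model is intentionally
  minimal; use the ViennaRNA engine for thermodynamically meaningful
  probabilities.
* The surrogate activity scorer is a stand-in heuristic; supply real
  predictor scores through the table scorer for serious use.
* Chromatin and cell-type context are outside the feature set.
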