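---
title: "Ensemble-MSA consensus profiling and hybrid full-consensus design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-MSA consensus profiling and hybrid full-consensus design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consdesign)
```

## The problem

Consensus design builds a complete, expressible protein sequence by taking,
at every position of a target protein, the residue that appears most often
among its homologs. Two practical obstacles stand in the way. First,
conventional multiple sequence alignment (MSA) tools cap the number of
sequences that can be aligned at once, while useful homolog libraries run to
hundreds or thousands of entries. Second, real libraries are phylogenetically
biased: when one subfamily (say, esterases in an α/β-hydrolase library)
outnumbers another (S-selective hydroxynitrile lyases), the plain consensus
follows the majority and the designed protein inherits the wrong family's
residues at functionally decisive positions.

`consdesign` addresses both with an *ensemble* strategy and a *residue
fixation* curation mechanism, and layers a *hybrid full-consensus* designer
on top.

## The ensemble model

Rather than aligning the whole library at once, the package repeats a small
alignment many times. One *target protein sequence* (the STP — the fixed
coordinate anchor) and `n_pick` library sequences drawn at random form one
input unit; `n_trial` such units are drawn independently, each is aligned,
and every alignment is projected onto target coordinates: alignment columns
where the target row holds a residue map to target positions 1..L, columns
where the target row gaps are discarded. All symbols observed in the other
rows — the 20 amino acids plus the gap symbol — are tallied per position,
and frequencies are the tallies divided by the per-position total.

Three conventions matter and are deliberate:

* **The target row is never tallied.** It anchors coordinates; counting it
  would bias every position toward the target by 1/(`n_pick`+1).
* **Gaps are a 21st observable** and sit in the frequency denominator, but
  consensus selection considers amino acids only, so designs are always
  full-length — a deletion is never designed.
* **`X` (unknown residue) is dropped** from numerator and denominator alike;
  an ambiguity code is a missing observation, not evidence.

Sampling is without replacement inside one unit and independent across
units, so a library sequence may be seen many times across the ensemble. A
single integer seed drives all sampling; two runs from one seed are
byte-identical. Sequences sharing no more than `min_identity_pct` (default
20) percent identity with the target are excluded from the library before
sampling.

The consensus at a position is the amino acid of maximal frequency; ties go
to the target's own residue when it is among the maxima, otherwise to the
alphabetically first candidate. Both tie-break arms exist only to make
output deterministic — with realistic ensembles, exact ties are rare.

## The internal aligner

Published use of this ensemble scheme delegated each round to CLUSTALW.
This package ships its own deterministic engine so that profiles are exactly
reproducible, and an adapter (`external_msa()`) for any ClustalW/MAFFT-style
executable for users who want parity with a particular tool; the adapter
verifies that degapped output reproduces its input and never falls back
silently.

The internal engine is a textbook progressive aligner built on global
Needleman–Wunsch/Gotoh alignment with affine gaps (BLOSUM62, gap open −10,
gap extend −1; a length-k run costs `open + (k−1)·extend`; terminal gaps are
charged like internal ones). The guide tree is UPGMA on pairwise distances
(1 − fractional identity), and profiles are merged in tree order with
frequency-weighted column scores. Every argmax — in the dynamic-programming
traceback (residue pair, then gap in the second sequence, then gap in the
first) and in UPGMA (lexicographically smallest id pair among minimal
distances) — has a fixed preference order, which is what makes whole-profile
byte determinism possible. No attempt is made to reproduce CLUSTALW's
specific heuristics; the contract is optimality of the pairwise score
(verified against brute-force enumeration in the test suite) and
determinism, not parity.

## Residue fixation and diagnostic residues

A *marker residue* `"pos:AA"` names a position whose identity separates
subfamilies (for instance, a position carrying Met in esterases but Lys in
S-HNLs). Under fixation, each ensemble alignment proceeds as usual, but only
rows carrying the marker amino acid at the marker's column are tallied — a
gap there fails. Matching is evaluated inside each unit's own alignment, not
by a separate pre-alignment of every sequence: a sequence may legitimately
pass in one unit and fail in another, and each tally is honest to its
alignment. Multiple markers are ANDed. The fraction of rows passing is
reported; on a mixture library it estimates the marked subfamily's share.

Comparing two fixed profiles (one per subfamily marker) exposes
*family-diagnostic* residues: positions where the two consensus residues
differ while both are strongly conserved. `find_diagnostic_residues()` flags
positions with distinct consensus and both frequencies at or above a
conservation threshold, default 0.8. The threshold is a judgment call — no
published value exists — chosen so that, at the substitution rates used in
validation (≈0.1 per site), within-family noise stays well below it while
engineered diagnostic columns (frequency ≈ 1) clear it comfortably.

## Hybrid full-consensus design

`hybridize()` consumes two profiles: the unfixed *backbone* profile and a
family-fixed profile. The backbone's full consensus is built first; then, at
every position where the family consensus frequency (as a percentage) is
*strictly greater* than the user threshold, the family consensus residue is
overlaid. Strict inequality means threshold 100 changes nothing and
threshold 0 adopts the family consensus wherever it is defined at all; in
between, substitution sets are nested as the threshold falls, so a series of
designs at descending thresholds shows monotonically growing substitution
counts. Where fixation left a position with no observations, the backbone
residue is kept regardless of threshold. Substitutions are recorded only
where the residue actually changes — an eligible position whose family and
backbone consensus agree is not a substitution.

## Downstream calculators

* `sequence_identity()` / `identity_matrix()` — identity is 100 × identical
  columns / alignment columns with at least one residue, over the global
  alignment; terminal gaps count in the denominator. There is no universal
  identity definition, so this one is stated explicitly to make
  identity-table numbers interpretable.
* `specificity_constant()`, `enantioselectivity_E()` — kcat/Km and the
  enantioselectivity E value as the ratio of specificity constants of the
  preferred over the non-preferred enantiomer (≥ 1 by construction, labeled
  S- or R-selective). This ratio form is the one consistent with the kinetic
  tables it is used on; conversion-based E estimators need conversion data
  and are out of scope.
* `fit_melting_curve()` — two-state thermal denaturation,
  θ(T) = θ_U + (θ_F − θ_U)/(1 + exp((T − Tm)/s)), fitted by
  Levenberg–Marquardt with constant baselines; Tm is where the fraction
  folded α = (θ_t − θ_U)/(θ_F − θ_U) is 0.5. Starting values come from the
  curve ends and midpoint crossing; a curve whose end-to-end amplitude is
  within ~4 standard deviations of its point-to-point noise is rejected as
  having no transition. Sloping baselines are a known possible extension.
* `refolding_yield()` — fraction folded of a renaturation curve at the
  lowest shared temperature, using baselines fitted to the denaturation
  curve.
* `mutation_site_distances()` — Euclidean Cα-to-reference-atom distances,
  mean ± sample (n−1) SD, count strictly within a cutoff (default 10 Å; a
  distance of exactly 10 is outside), and the fraction inside inclusive
  residue ranges such as a substrate-entrance region.

## What the synthetic generator emulates — and what it does not

`generate_family()` mutates a known ancestor with i.i.d. per-site
substitutions to a uniformly random different residue, optional short
indels, and diagnostic positions pinned to fixed amino acids;
`generate_biased_library()` mixes two such families at chosen proportions,
returning per-sequence family labels and both ancestors as ground truth.
This emulates exactly the properties the pipeline's claims depend on —
controlled divergence, mixture bias, family-diagnostic columns — and nothing
else: there is no phylogenetic tree structure, no empirical substitution
model, no site-rate heterogeneity, and indels default to off so ancestor
coordinates stay trivial. Passing tests on these libraries therefore show
that the machinery recovers planted signal under its stated model; they do
not show that any particular biological library is unbiased or that 20%
identity is the right admission threshold for a given family.

## Problem sizes and numerical choices in validation

The test suite validates consensus recovery on a one-family library
(ancestor length 200, 50 sequences, rate 0.1) and fixation on an 80/20
two-family mixture of the same scale, both profiled with `n_trial = 40`,
`n_pick = 8`. Forty rounds of eight picks give every member of a ≤100
sequence library ~25 expected observations per position, ample for a 0.9
majority signal; the published default of 1000 rounds targets libraries an
order of magnitude larger, and the guidance that rounds must grow with
library size is qualitative — no automatic rule is implemented. Exhaustive
oracles run at small n: brute-force alignment enumeration on strings of
length ≤ 7, and single-round/full-library ensembles checked against a direct
column tally of one alignment.

Degenerate inputs are defined, not patched around: an empty post-filter
library, a marker matching no row anywhere, a position with zero effective
count in `build_full_consensus()`, and a flat melting curve are all hard
errors with named messages; out-of-range fraction-folded values are allowed
but flagged, since real CD data overshoot baselines.

## Known limitations

* Internal alignments will not match CLUSTALW's output; only score
  optimality and determinism are promised.
* The frequency denominator convention (gaps in, `X` and the target row
  out) is one defensible choice among several; profiles from tools with
  other conventions are not numerically comparable position by position.
* Two-state melting fits assume constant baselines and full equilibrium.
* The E-value is the specificity-constant ratio; conversion-based
  estimators are not implemented.
* Marker discovery is manual by design; the package detects diagnostic
  residues given markers, it does not find markers.

## A compact worked example

```{r example, eval = FALSE}
set.seed(1)
anc <- random_protein(120)
spec <- library_spec(
  family_a = family_model(anc, 0.1, diagnostic_positions = c("40" = "M")),
  family_b = family_model(sub("^(.{39}).", "\\1K", anc), 0.1,
                          diagnostic_positions = c("40" = "K")),
  n_a = 40, n_b = 10, seed = 2)
gen <- generate_biased_library(spec)
stp <- sequence_record("stp", gen$truth$ancestor_a)

cfg <- ensemble_config(n_trial = 30, n_pick = 8, seed = 3)
backbone <- ensemble_profile(stp, gen$library, cfg)
family <- fixed_profile(stp, gen$library, cfg, markers = "40:K")

designs <- design_series(backbone, family, c(85, 54, 30), "HNL")
vapply(designs, function(d) nrow(d$substitutions), integer(1))
```
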