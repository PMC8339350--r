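---
title: "Classifying and comparing docking and dimerization (D/D) domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and comparing docking and dimerization (D/D) domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddscan)
```

## The scientific problem

The docking and dimerization (D/D) domain is a small N-terminal module,
best known from the regulatory subunits of PKA, in which two protomers
form an X-type antiparallel four-helix bundle whose upper groove binds the
amphipathic anchoring helix of AKAPs. The same fold appears in a broader
superfamily that includes the DPY-30 proteins of the COMPASS complex and a
set of PKA-R-like proteins (SPA17, ROPN1, ROPN1L, RIIAD1, CATIP, TPGS1 and
others), which segregate into a type I-like (R1D2) and a type II-like
(R2D2) lineage.

`ddscan` provides a desk-scale, fully reproducible pipeline for this
family: sequence-level classification into DPY-30 / R1D2 / R2D2, a
distance-based phylogeny with bootstrap supports, rigid-body structural
comparison of bundle dimers, and 1:1 binding analysis of AKAP titrations.
Every stochastic stage is seeded, and a synthetic-data module generates
inputs with known ground truth so that each analysis stage can be tested
as a recovery problem.

## Region architecture and classification model

Each candidate N-terminal sequence (roughly 45--80 residues) is globally
aligned to a 77-residue extended D/D reference profile and the profile's
five-region architecture is projected through the alignment:

* `nflank` -- the N-terminal flanking motif (default reference positions
  0--10). In type I-like proteins this region is predicted helical; in
  type II-like proteins it forms a beta strand.
* `helix1` (10--22) and `helix2` (27--40) -- the two core bundle helices.
* `loop` (22--27) -- the inter-helix loop carrying the diagnostic proline
  motif.
* `cflank` -- the remainder of the 77-position window.

The published description of the family gives the architecture but not
numeric boundaries, so the boundaries are configuration (a packaged JSON
file), not hard-coded constants. All coordinates are 0-based, half-open.
The packaged reference profile and its per-class consensus sequences are
*synthetic, family-typical* sequences that embody the documented motif
structure; they are labelled `synthetic` in the fixture files and are not
retrieved database sequences.

Classification uses explicit diagnostic features:

* **Loop motif.** A window spanning the mapped loop plus one residue on
  each side is scanned for P-x-x-Z. Z = P gives `PxxP` (the type I
  hallmark of prolines on both ends of the loop); Z in {I, L, V} gives
  `PxxPhi` (the type II hallmark). Because region boundaries are
  approximate, the one-residue margin keeps end-of-loop prolines in
  scope. When several windows start with a proline, the most N-terminal
  *decisive* window (Z in {P, I, L, V}) wins; this makes the call robust
  to prolines arising by chance immediately before the loop.
* **N-flank secondary structure.** A transparent Chou--Fasman-style
  average: the call is helix if mean helix propensity minus mean strand
  propensity over the flank exceeds `tau` (default 0.1), strand if below
  `-tau`, else ambiguous. Flanks shorter than three usable residues are
  ambiguous. The propensity table ships as configuration; any method
  could be substituted, but a propensity average is reproducible and has
  no hidden training data.
* **Helix marks.** A glycine within the first two positions of helix I
  and the "YF" dipeptide within helix II, both type II marks.
* **Determinant sets.** The fraction of configured dimerization positions
  carrying hydrophobic residues, and the count of configured docking
  positions identical to the reference. These are reported but do not
  enter the lineage score, since they characterise AKAP-binding
  competence rather than lineage. The position lists are configuration:
  the literature marks them graphically without enumerating them.

The lineage score is additive: the loop motif contributes 2 points (to R1
for `PxxP`, to R2 for `PxxPhi`), and the N-flank call, helix-I glycine and
helix-II "YF" contribute 1 point each. The loop motif carries double
weight because it is described as the defining feature, with the flank and
helix marks as secondary determinants; no numeric scheme is published, so
the weights are explicit configuration. When the margin between the two
scores is at most `delta` (default 1), the call is `intermediate` -- a
first-class outcome, because boundary members (TPGS1-like feature
combinations, and to a lesser degree RIIAD1/CATIP) genuinely mix the two
conventions. A feature set of {PxxP loop, helical flank, helix-I Gly,
helix-II YF} scores 3:2 and is deliberately reported as intermediate
rather than forced into either lineage.

Superfamily assignment (DPY-30 vs PKA-R vs none) precedes lineage scoring:
the query is aligned to each consensus and the best-scoring family wins if
its score reaches `min_score` (default 100, roughly a quarter of a
self-match score under the default matrix -- low enough to accept
divergent members, high enough that compositionally uninformative queries
return `none`). Ties are broken toward PKA-R and flagged.

## Alignment conventions

Pairwise alignment is global Needleman--Wunsch with affine gaps
(BLOSUM62, gap open 11, extend 1 -- the standard protein defaults; a gap
of length L costs `open + L * extend`). The ambiguity code `X` scores 0
against everything, so runs of unknown residues neither help nor hurt.
Alignments are computed by `Biostrings::pairwiseAlignment()`; optimal
scores are verified in the test suite against an exhaustive enumeration of
all alignments on short sequences, and tie resolution is deterministic.

## Phylogeny

The phylogeny stage is deliberately simple and self-contained: p-distances
(mismatches over comparable columns, columns with a gap in either sequence
excluded) on a reference-anchored stacking of the pairwise alignments,
neighbor joining, and Felsenstein column-resampling bootstrap supports.
This replaces the external maximum-likelihood stage (RAxML/IQ-Tree class
tooling with LG+Gamma models and transfer-bootstrap supports) that a
full-scale study would use; NJ on p-distances is consistent on additive
distances and adequate for the desk-scale recovery experiments the
package targets, but it is not a substitute for ML on hard, deep
divergences -- a known limitation.

Numerical conventions: negative NJ branch lengths are clamped to zero
with the deficit moved to the sibling edge; each bootstrap replicate
draws from its own seeded substream (`seed + replicate`), so supports are
reproducible regardless of evaluation order; supports are classical
bipartition proportions attached to the full-data tree. Outgroup rooting
(typically on the DPY-30 clade) requires the outgroup to be monophyletic
in the unrooted tree and never changes the bipartition set. Where a
study combines supports across runs with and without an outgroup, the
package reports per-run supports; averaging across runs is left to the
user and flagged as a convention, since rooting cannot change
bipartitions and the combination rule is not standardised.

## Structural comparison

Coordinates are read from PDB or mmCIF files (via `bio3d`; the unit cell
and space group are parsed from the `CRYST1`/`_cell` records directly,
which `bio3d` does not expose). Chains are reduced to C-alpha traces with
first-alternate-location filtering. Superposition is the closed-form
Kabsch solver (SVD of the cross-covariance with a determinant correction,
so reflections are excluded); the test suite checks it against a
multi-start numeric minimiser to 1e-6 Angstrom and against `bio3d`'s
fitting routine. Residue pairing between structures uses global sequence
alignment; dimer-versus-dimer comparisons evaluate both chain-pair
assignments and keep the lower RMSD, making the result invariant to chain
labelling. By default the RMSD is reported over *all* paired C-alpha
atoms with no outlier rejection; an iterative-trim mode (discard pairs
beyond `trim_factor` times the current RMSD, refit, repeat) is also
reported by the pipeline, because published RMSDs do not always state
which convention produced them. Dimer comparisons can be restricted to a
configurable core interval, excluding the flanking strands that differ
most between family members.

Sequence-derived chain masses use average (not monoisotopic) residue
masses plus one water, matching how solution-mass experiments (SEC-MALS)
report monomer masses.

The packaged coordinate sets (`spa17_asu_synthetic.pdb`,
`riia_dd_synthetic.pdb`/`.cif`) are idealized synthetic stand-ins: they
carry the documented chain count, chain length and cell constants of the
SPA17 study system, but their helix-bundle geometry is generated, not
deposited. Structural tests on them validate parsing, pairing and the
superposition machinery; they say nothing about agreement between real
deposited structures, and analyses of real entries should be run on
locally provided coordinate files.

## Binding model

The 1:1 (Langmuir) model is used throughout. Steady state:
`Response = Rmax * c / (KD + c)`, fit by unweighted nonlinear least
squares (initialised at `Rmax = max(response)` and KD at the interpolated
half-max concentration). Kinetics: association
`R(t) = Req (1 - exp(-(kon c + koff) t))` with `Req = Rmax c / (KD + c)`,
dissociation `R(t) = R0 exp(-koff t)`, fit locally per trace and averaged,
with `KD = koff / kon`; a flat dissociation phase yields `koff ~ 0` and
flags the KD as a lower bound. Unweighted loss matches typical instrument
software; when steady-state points are derived from traces, the
equilibrium response is the time-average of the final 5% of the
association phase (the instrument definition of "equilibrium response" is
not otherwise published). Units are molar internally, with
micromolar/nanomolar accepted at the CSV interface via an explicit unit
tag.

The packaged concentration ladders mirror the study's titrations: 50,
16.7, 5.56, 1.85, 0.617, 0.2058 uM for the homodimer and a three-fold
dilution from 2.67 uM for the heterodimer. The published heterodimer list
ends "0.329 uM", which breaks the otherwise exact three-fold series
(2.67, 0.889, 0.2963, 0.0988, ...); the shipped default treats it as
0.0329 uM, completing the series, and the alternative reading remains
available by passing the concentrations explicitly. User-supplied data
are never silently corrected.

## The synthetic-data generators

Each generator is a pure function of its configuration and seed:

* **Family sequences** start from a lineage consensus and mutate each
  position independently at the requested divergence (uniform among the
  other 19 residues). The lineage-defining motif positions are immune to
  mutation, so generated sequences always pass their class's motif checks
  -- a clean ground truth for classifier-recovery tests; a leaky mode
  with a per-motif mutation probability exists for stress testing.
* **Tree evolution** runs an independent-site 20-state Jukes--Cantor-type
  process down a tree. Multiple hits per edge are allowed, so a site
  shows a visible change on an edge of length L with probability
  `(19/20)(1 - exp(-(20/19) rate L))` -- approximately `rate * L` on short
  edges and saturating at 19/20, the uniform-equilibrium limit.
* **BLI data** are exact 1:1-model values times `(1 + eps)` with
  `eps ~ N(0, noise_cv)`; `noise_cv = 0` returns exact curves.
  Multiplicative noise reflects the roughly signal-proportional error of
  optical biosensors.
* **Point clouds** are rigid transforms (proper rotation + translation)
  of a seeded Gaussian cloud with optional isotropic coordinate noise and
  the generating transform recorded.

What the generators do *not* emulate is worth stating: no indels (the
family alignment window is treated as indel-free), no site-rate
heterogeneity or empirical substitution preferences (a matrix-based mode
would be a natural extension), no instrument drift or mass-transport
artifacts in binding traces, and no internal structure in the point
clouds. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated models, not robustness to every property of
real data.

## Problem sizes and determinism

The shipped tests run classifier recovery on 500 generated sequences
(250 per lineage, divergence 0.1), quartet and 5--8-taxon topology
recovery over randomized additive matrices, 30 seeded runs of modal
bootstrap recovery on an 8-taxon tree with 500 sites, 200-replicate
Monte-Carlo KD recovery at 2% noise, and 50-replicate recovery at each of
the two study concentration ladders. These sizes give stable pass/fail
behaviour at fixed seeds while keeping the default suite fast; all
thresholds (95% classification recovery, 5--10% KD tolerance) were fixed
with the study conditions, not tuned to runs.

## Known limitations

* Lineage weights, region boundaries, propensity table and determinant
  position lists are transparent configuration calibrated to the
  documented qualitative feature hierarchy, not learned from data.
* NJ/p-distance phylogeny underestimates multiple substitutions at deep
  divergence; supports are classical proportions, not transfer bootstrap
  expectations.
* The classifier assumes the candidate aligns to the 77-position window;
  heavily truncated queries degrade to `intermediate`/`none` calls rather
  than being force-classified.
* Kinetic fits are local per-trace fits; global fitting with shared
  parameters across traces is deliberately out of scope.
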