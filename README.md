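# ddscan

Classification, phylogeny, structural comparison and binding analysis for
the docking and dimerization (D/D) domain superfamily.

## What this is for

The D/D domain is the small N-terminal module of the PKA regulatory
subunits: two protomers form an X-type antiparallel four-helix bundle
whose groove binds the amphipathic anchoring helix of AKAPs (A-kinase
anchoring proteins). The same fold defines a wider superfamily — the
DPY-30 proteins and a set of PKA-R-like proteins (SPA17, ROPN1, ROPN1L,
RIIAD1, CATIP, TPGS1, …) that segregate into type I-like (**R1D2**) and
type II-like (**R2D2**) lineages by a handful of sequence features:

* the inter-helix loop motif — `PxxP` (type I) versus `Pxx[ILV]` (type II);
* the predicted secondary structure of the N-terminal flank (helix vs
  β-strand);
* a glycine at the start of helix I and a `YF` dipeptide in helix II
  (type II marks).

`ddscan` is for anyone who wants to score candidate N-termini against this
feature system with explicit, configurable rules, place them on a
bootstrapped neighbor-joining tree, superpose bundle dimers
(Kabsch/RMSD), and fit 1:1 AKAP-binding data — all seeded and
reproducible, with a synthetic-data module that generates every input
with known ground truth.

At its core are three small models:

* an additive lineage score: loop motif ±2, N-flank call ±1, helix marks
  +1 each toward R2; calls with margin ≤ δ (default 1) are reported as
  `intermediate`, a first-class outcome for genuine boundary members;
* the Kabsch least-squares rigid superposition
  (RMSD = min over proper rotations R, translations t of
  √(mean‖R·x + t − y‖²));
* the 1:1 Langmuir binding model, steady state
  `Response = Rmax·c / (KD + c)` and kinetic phases
  `R(t) = Req(1 − e^−(kon·c+koff)t)`, `R(t) = R0·e^−koff·t`,
  with `KD = koff/kon`.

## Worked example

Generate a small mixed family at 5% divergence and classify it, then fit
a noisy synthetic titration at the heterodimer concentration ladder:

```r
library(ddscan)
ref  <- dd_reference()
seqs <- rbind(gen_family_sequences("R1D2", 3, 0.05, seed = 11, ref = ref),
              gen_family_sequences("R2D2", 3, 0.05, seed = 12, ref = ref))
class(seqs) <- c("dd_seqs", "data.frame")
classify_sequences(seqs, ref)[, c("id", "superfamily", "lineage",
                                  "score_r1", "score_r2", "margin",
                                  "loop_motif")]
#>        id superfamily lineage score_r1 score_r2 margin loop_motif
#>  R1D2_001        PKAR    R1D2        3        0      3       PxxP
#>  R1D2_002        PKAR    R1D2        3        0      3       PxxP
#>  R1D2_003        PKAR    R1D2        3        0      3       PxxP
#>  R2D2_001        PKAR    R2D2        0        5      5     PxxPhi
#>  R2D2_002        PKAR    R2D2        0        5      5     PxxPhi
#>  R2D2_003        PKAR    R2D2        0        5      5     PxxPhi

d <- gen_bli(Rmax = 1, KD = 82e-9,
             concentrations = c(2.67, 0.889, 0.2963, 0.0988, 0.0329) * 1e-6,
             noise_cv = 0.02, seed = 42)
fit <- steady_state_fit(d$conc, d$response)
sprintf("KD = %.1f nM  (Rmax = %.3f)", fit$KD * 1e9, fit$Rmax)
#> "KD = 82.8 nM  (Rmax = 1.011)"
```

Each R1D2 member scores 3:0 (PxxP loop +2, helical flank +1); each R2D2
member scores 0:5 (Pxx[ILV] loop +2, strand flank +1, helix-I Gly +1,
helix-II YF +1). The fitted KD recovers the generating 82 nM affinity to
within the 2% noise level of the simulated titration.

The pipeline entry points `run_classify()`, `run_structure()` and
`run_binding()` write TSV/JSON/Newick reports plus a resolved-config JSON
per run; `inst/scripts/ddscan.R` wraps them for shell use
(`Rscript inst/scripts/ddscan.R classify --fasta F --out D …`).

Note on fixtures: the packaged reference profile, 18-member inventory and
coordinate sets are *synthetic stand-ins* (labelled `synthetic` in their
file names) that embody the documented family architecture; analyses of
real deposited structures or database sequences should be run on locally
provided files.

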