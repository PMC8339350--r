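Package: ddscan
Title: Classification, Phylogeny and Binding Analysis of Docking and
    Dimerization (D/D) Domain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the docking and dimerization (D/D) domain
    superfamily of four-helix-bundle proteins related to the PKA regulatory
    subunits. Candidate N-terminal sequences are aligned to an extended D/D
    reference, mapped onto a five-region architecture (N-flank, helix I,
    loop, helix II, C-flank), scored for the diagnostic motifs that separate
    the DPY-30, type I-like (R1D2) and type II-like (R2D2) lineages, and
    placed on a neighbor-joining phylogeny with bootstrap supports and
    outgroup rooting. Structural comparison utilities superpose C-alpha
    coordinate sets by the Kabsch algorithm, enumerate chains of an
    asymmetric unit and compute sequence-derived average masses. A 1:1
    (Langmuir) binding module fits steady-state titrations and kinetic
    biolayer-interferometry traces, and a synthetic-data module generates
    family-typical sequences, tree-evolved tip sequences, noisy binding data
    and rigidly transformed point clouds with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
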