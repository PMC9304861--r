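Package: bfuscan
Title: Classification and Mechanistic Modeling of Electron-Bifurcating Bfu (HydABC-Like) Enzyme Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and classifying members of the Bfu family of
    electron-bifurcating enzyme complexes from protein sequences, InterPro-style
    domain annotations and gene coordinates. Candidate BfuB/BfuC/BfuA subunits
    are selected by domain architecture, mapped onto the Acetomicrobium mobile
    reference frame to call iron-sulfur cluster ligands (including the
    pentacoordinate B2 [2Fe-2S] signature), and combined with gene-neighborhood
    evidence to assign one of thirteen functional classes and a structural
    Type (1-4) with the electron entry cluster. A neighbor-joining tree over
    BfuB subunits is partitioned into clades at a branch-length threshold, and
    a redox-couple table supports bifurcation energetics. A discrete ten-state
    simulator encodes the proposed conformationally gated electron-bifurcation
    cycle with exact electron bookkeeping. A synthetic-genome generator plants
    operons of known class, type and clade so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
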