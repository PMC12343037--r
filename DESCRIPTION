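Package: siteseek
Title: Active-Site Geometric Motif Search in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Finds proteins whose local three-dimensional arrangement of
    user-chosen active-site residues matches a seed protein, independently of
    overall sequence or fold similarity. A search template is built from three
    anchor residues (plus optional additional residues and per-position amino
    acid substitution rules) of a seed structure; query structures are
    pre-screened by anchor pairwise-distance compatibility, superposed onto the
    seed by SVD-based least-squares rigid fitting (Kabsch), and scored by a
    penalized average residue distance over anchors, matched additional
    residues and their sequence neighbors. Per-hit whole-structure similarity
    metrics (structural mapping percentage and local structural similarity) are
    computed by dynamic-programming alpha-carbon pairing. Includes a
    deterministic batch driver over local PDB/mmCIF files and a synthetic
    fixture generator that plants active sites on pseudo-helical backbones with
    controlled geometric jitter and stage-specific decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
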