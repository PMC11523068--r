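Package: tabstrings
Title: Torsion Angular Bin Strings and Conformer-Ensemble Size Bounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discrete vector labels for molecular conformers based on
    binned torsion angles (torsion angular bin strings, TABS), and a
    symmetry-reduced upper bound on the size of a molecule's
    conformational ensemble (nTABS). Torsion states are derived from
    truncated Fourier torsion potentials matched via a SMARTS-keyed
    profile library; topological symmetry is handled through graph
    automorphisms and Burnside orbit counting, and small/medium rings and
    macrocycles are collapsed to literature state counts. Includes the
    evaluation protocol comparing TABS grouping against heavy-atom RMSD
    grouping (confusion matrices, PPV/NPV threshold scans) and the
    comparison descriptors rotatable-bond count and Kier phi.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
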