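Package: dfscan
Title: Double Force Scanning for Rescue Site Prediction in Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate rescue (second-site suppressor) sites in a
    protein from its native structure alone. Residues are coarse-grained to
    C-alpha nodes of an anisotropic network model (ANM); pairs of external
    forces mimicking a pathogenic mutation and a candidate rescue mutation
    are applied under linear response theory, and a rescuability index
    measures whether the second-site perturbation cancels the structural
    effect of the first. Pair scores under fixed-force and fixed-RMSD
    magnitude schemes are aggregated into a per-residue compensatory power,
    with an evaluation layer for reference site sets (sensitivity,
    specificity, enrichment, optimal threshold), proximity analysis of
    unpredicted sites, normal-mode decomposition of compensatory motions
    (RMSIP, collectivity), binding-pocket rescue classification and
    divergent-site extraction from pairwise alignments. Deterministic
    synthetic structures (helices, polyhedra, jittered lattices, globules)
    make the whole pipeline testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    Biostrings,
    optparse,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
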