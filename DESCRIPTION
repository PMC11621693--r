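Package: remcoil
Title: Coiled-Coil Dimer Interface Analysis and Density-Biased Adaptive Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pre-structured coiled-coil dimers of
    remorin-family proteins: reading multi-model NMR structure bundles and
    restraint tables, superposition-based ensemble statistics (pairwise RMSD,
    RMSF, restraint violation bookkeeping), intermolecular contact maps and
    minimal-distance maps, extraction of symmetric hydrophobic zipper motifs
    from center-anchored homolog alignments, dihedral-region and
    chemical-shift-index secondary-structure classification, and the
    density-biased adaptive-sampling scheme (PCA landscape, Gaussian kernel
    density, inverse-density seed selection, unbiasing weights for
    reweighted observables). Includes parametric generators for synthetic
    coiled-coil dimers, perturbed ensembles, planted motif families and
    two-state conformational clouds so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
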