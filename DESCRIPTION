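Package: foldscape
Title: Conformational-Ensemble Analysis of Designed Mini-Protein Folding Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the folding of the de novo designed
    beta-alpha-beta mini-protein DS119 from conformational ensembles: segment
    RMSD order parameters (alpha-RMSD, beta-RMSD), radius of gyration,
    tryptophan ring distances, hydrophobic-core solvent accessibility and a
    minimal secondary-structure assignment; two-dimensional free-energy
    landscapes with basin detection and minimax barrier estimation; intra- and
    inter-chain residue contact-probability maps; a two-chain aggregation
    pipeline (binding detection, flat-stage windowing, interface maps, common
    binding-segment reports, projection of dimer monomers onto the monomer
    landscape); and a synthetic-ensemble generator that plants known basins
    and scripted association events with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
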