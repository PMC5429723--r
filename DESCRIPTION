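Package: nanoforge
Title: Construction and Analysis of Polysaccharide-Coated Faceted Nanoparticle Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds atomistic models of faceted metal-oxide nanoparticles and
    their polysaccharide coatings, and analyses their interaction with lipid
    membranes. Reads crystallographic unit cells from CIF, derives the Wulff
    equilibrium morphology from facet surface energies, carves the faceted
    core from a bulk supercell, classifies surface iron coordination sites,
    grafts branched polysaccharide (gum-arabic-like) chains at a chosen count
    or density, enumerates molecular-dynamics topologies (bonds, angles,
    dihedrals, partial charges), assembles solvated nanoparticle-bilayer
    systems, and provides trajectory hydrogen-bond analysis (including weak
    CH...O bonds), nanoparticle-membrane distance series, and region-of-
    interest image statistics (SNR/CNR) plus tumor-volume caliper formulas.
    All structures are tidy tibbles (one row per atom) so every stage chains
    with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
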