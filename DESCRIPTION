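Package: thinmem
Title: Membrane Thinning Simulations and Lipid Packing Defect Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal coarse-grained membrane simulator built around a
    zone-scaled harmonic thinning field that locally squeezes a flat lipid
    bilayer to induce lipid packing defects, together with the analysis
    pipeline needed to study the consequences: binned thickness profiles
    with sigmoid fits, grid-based packing-defect detection with exponential
    size-constant estimation, composition histograms for thinness-induced
    lipid sorting, and umbrella sampling with WHAM unbiasing to measure the
    defect-sensing force on an amphipathic probe. Lipids are represented by
    a three-bead-per-chain implicit-solvent model integrated with Langevin
    dynamics; all initial configurations and synthetic test fixtures are
    generated internally from seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Config/testthat/start-first: geometry_field, membrane_builder, cg_dynamics,
    thickness_profile, defect_analysis, sorting_analysis, free_energy,
    io_cli
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
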