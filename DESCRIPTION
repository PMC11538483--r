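Package: protarc
Title: Proton Arc Versus IMPT Plan Quality and Robustness Analysis on
    Synthetic 4D Thorax Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale research pipeline for comparing proton arc
    therapy (PAT) with intensity-modulated proton therapy (IMPT) on
    moving lung targets.  Generates synthetic 4D breathing thorax
    phantoms with analytically known deformation fields and a
    time-weighted mid-position reference image, places pencil-beam
    scanning spots for 3-beam IMPT and single-energy-layer-per-direction
    arc plans, optimizes spot weights by worst-case minimax robust
    optimization over a setup/range/phase scenario grid, and evaluates
    plans: scenario-based worst-case dosimetry against clinical goals,
    4D dynamic dose interplay simulation with DVH-band statistics,
    logistic NTCP models driven by mean organ doses, beam delivery time
    models, and paired Wilcoxon signed-rank comparison.  The dose engine
    is a simplified analytic Bragg-curve pencil-beam model with
    water-equivalent path length, intended for methodological studies,
    not clinical use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
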