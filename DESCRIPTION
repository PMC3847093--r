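Package: smoligo
Title: Single-Molecule Quantification of Membrane-Bound Amyloid-Beta Oligomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule confocal measurements of
    amyloid-beta (Abeta40/Abeta42) oligomers on neuronal membranes. Provides a
    synthetic-field generator with full ground truth (diffraction-limited spots on
    curvilinear neurite masks, per-monomer photon budgets, membrane quenching,
    intra-oligomer FRET, Poisson shot noise, autofluorescent impostors,
    mono-exponential TCSPC decays), intensity-based oligomer sizing with
    lifetime-derived quenching correction, FLIM autofluorescence gating,
    three-channel FRET species classification, and oligomer size, stoichiometry,
    density and distribution statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
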