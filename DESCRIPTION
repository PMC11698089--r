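Package: palmap
Title: Photoaffinity-Labeling Mass Spectrometry Mapping of Ligand Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for localizing ligand binding sites on ion
    channels by photoaffinity labeling (PAL) middle-down mass spectrometry,
    with companion electrophysiology and simulation analyses. Provides
    in-silico tryptic digestion with missed cleavages, monoisotopic peptide
    and b/y fragment-ion mass computation with fixed and variable
    modifications including a diazirine photo-adduct, adduct-shifted MS1
    feature detection under predetermined acceptance criteria, fragment-ion
    site localization with explicit site-determining-ion logic and ambiguity
    sets, labeling-efficiency quantification from extracted-ion chromatogram
    areas, competition (prevention-of-labeling) statistics by one-way ANOVA
    with Dunnett many-to-one comparisons, Boltzmann conductance-voltage
    fitting of tail-current activation curves, and dual-cutoff ligand-residue
    contact occupancy plus time-averaged density grids on coordinate
    trajectories. A synthetic-data module generates ground-truth LC-MS/MS
    runs, G-V datasets and trajectories so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    multcomp,
    Biostrings,
    bio3d
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
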