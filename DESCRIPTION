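Package: quinateMS
Title: Mass-Spectral and NMR Interpretation of Malonyl-Caffeoylquinic Acids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational interpretation of LC-MS/MS and NMR data for
    malonyl-caffeoylquinic acids (MDiCQAs) and flavonoid malonyl-glucosides.
    Provides elemental-formula arithmetic and exact m/z computation for
    deprotonated and protonated ions, regioisomer enumeration over the quinic
    acid core, a neutral-loss fragmentation grammar with theoretical fragment
    trees and peak annotation, detection of in-source catechol-oxidation ion
    series (-2H/-4H satellites), a two-stage collision-energy-dependent
    intensity-ratio key that discriminates the four malonyl-dicaffeoylquinic
    acid regioisomers, coupling-constant rules separating quinic from
    epi-quinic cores, four-parameter logistic IC50 estimation, tissue-level
    abundance summaries, and seeded synthetic-data generators that make every
    stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: MassSpectrometry, Metabolomics, Software
RoxygenNote: 7.3.3
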