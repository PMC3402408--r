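Package: tillkit
Title: Simulation and Analysis of EMS-Mutagenized TILLING Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing TILLING (Targeting Induced
    Local Lesions IN Genomes) screens of EMS-mutagenized plant populations.
    Provides a seeded forward simulator of EMS mutagenesis (G:C to A:T
    transition spectrum), M1 chimerism and Mendelian segregation into M2
    families; a model of pooled heteroduplex mismatch-cleavage screening
    with amplicon end-trimming, per-method detection sensitivity and pool
    deconvolution; band-based (RAPD/ISJ) and amplicon-based mutation-density
    estimators with genome-wide mutation-load extrapolation; variant effect
    classification against simple gene models; and phenotype-census
    frequency tabulation. Ships the screen and census tables of a hexaploid
    wheat ('Jinmai47') TILLING population as plain-text fixtures so the full
    analysis pathway can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
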