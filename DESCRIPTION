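Package: mlglucan
Title: Fine Structure of Mixed-Linkage Beta-Glucans by Simulated
    Enzymatic Digestion and Glycan Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reasoning about the fine structure of linear
    beta-1,3:1,4-glucans (mixed-linkage glucans, MLG) in silico: a compact
    chain notation and mass arithmetic for native and permethylated
    glucan oligosaccharides; a subsite-rule model of glycoside hydrolase
    action (GH12 endo-beta-1,4-glucanase, GH16 endo-beta-1,3(4)-glucanase,
    GH17 endo-beta-1,3-glucanase, lichenase) with limit digestion, product
    multisets and degree-of-polymerization mass fractions; prediction of
    partially methylated alditol acetate (PMAA) linkage profiles and
    candidate-structure enumeration; first-principles fragment m/z tables
    for high-energy CID of permethylated sodiated oligosaccharides
    (Domon-Costello B/C/Y/Z, 3,5A and 0,2X cross-ring ions, D/E/G/V
    elimination ions) with linkage-dependent feasibility; comparative
    diagnostic-ion inference of linkage positions from peak lists; and a
    seedable synthetic-data generator for barley-like MLG chain
    populations and simulated CID spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
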