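Package: breedsim
Title: Stochastic Simulation of Crop Breeding Programs with Overlapping
    Cycles, Genomic Selection and Speed Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-plant, locus-level forward-in-time simulation of
    self- and cross-pollinated crop breeding programs. Generates founder
    linkage disequilibrium with a Fisher-Wright mutation-drift-selection
    model, simulates meiosis with Poisson-distributed crossovers, supports
    finite-locus and infinitesimal trait models with residual-variance
    calibration from plot heritability, pedigree- and marker-based
    (VanRaden) relationship matrices, BLUP and GBLUP breeding-value
    prediction, optimum-contribution selection, and a breeding-program
    engine with overlapping cycles, germplasm stores, burn-in switching and
    speed-breeding calendars. Ships three wheat line-breeding plans
    (phenotypic selection, genomic selection, and speed breeding with
    genomic selection) as runnable configurations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
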