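Package: boagblup
Title: Genomic Prediction of Crossbred Performance with Breed-of-Origin
    Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for genomic prediction of
    purebred sires for crossbred performance in a three-way terminal cross.
    Provides a gene-drop simulator for a sire line and two dam lines with a
    configurable purebred-crossbred genetic correlation and per-allele
    breed-of-origin truth labels; the data-cleaning filters used in
    commercial broiler evaluations (outlier, call-rate, Mendelian
    consistency and minor-allele-frequency rules); single-breed,
    multi-breed and breed-of-origin partial genomic relationship matrices;
    GBLUP animal and sire models with EM-REML variance-component
    estimation; and a cross-validation scenario engine that computes
    reliability-weighted validation correlations and dispersion bias of
    genomic estimated breeding values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
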