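Package: neoclocks
Title: Epigenetic Age Acceleration Analysis for Newborn Methylation Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes epigenetic age and gestational age clocks from DNA
    methylation beta-value matrices, derives age-independent epigenetic age
    acceleration anchored on a reference-group regression, estimates blood
    cell-type proportions by constrained projection onto a methylation
    reference, calls full and likely mosaic/partial trisomy 21 from binned
    array-intensity log2 copy ratios, and fits the association and
    sensitivity models used in newborn Down syndrome aging studies. A
    synthetic-cohort generator with known ground truth (clock signal, cell
    mixtures, chromosome 21 dosage, GATA1 variant allele fraction effects)
    makes every stage testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
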