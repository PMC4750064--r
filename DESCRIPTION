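Package: puresort
Title: Digital Sorting Analysis of Pure Tumor and Stromal Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for image-based dielectrophoretic cell sorting
    of formalin-fixed paraffin-embedded (FFPE) tumor samples. Gates
    fluorescently stained cell events into pure keratin-positive (tumor) and
    vimentin-positive (stromal) subpopulations, estimates DNA index from DAPI
    intensity histograms, classifies sequence variants into genetic variant
    classes by comparing variant allele frequencies across pure populations,
    infers allele dosage, anchors low-pass whole-genome copy-number profiles
    at ploidy = 2 x DNA index, and quantifies FFPE false-positive noise via a
    singleton-variant statistic. A synthetic-cohort generator emulates the
    mixed aneuploid/diploid populations, FFPE template scarcity and
    deamination artifacts that the analysis is designed to resolve.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
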