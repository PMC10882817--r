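Package: tuberTrace
Title: Vertical Transmission Accounting for Seed Tuber Microbiomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify intergenerational inheritance of microbiota
    in vegetatively propagated crops from amplicon sequence variant (ASV)
    count tables. Implements detection-set algebra for field-unique ASV
    identification and exclusive overlap partitions, shared/lost/acquired
    transmission accounting between plant generations with relative-abundance
    attribution, source attribution of sprout microbiota across seed tuber
    compartments, and distance-based community statistics (Bray-Curtis,
    principal coordinates analysis, PERMANOVA with permutation p-values,
    richness and Kruskal-Wallis tests) implemented from first principles.
    A Dirichlet-multinomial community simulator with recorded ground truth
    supports validation of every pipeline stage without access to raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    biomformat,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
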