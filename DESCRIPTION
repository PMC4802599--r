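Package: senmiR
Title: Small RNA, Degradome and Phenotype Analysis of Maize Leaf Senescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable re-implementation of a maize leaf-senescence small-RNA
    workflow: adapter trimming and quality filtering of sRNA-seq reads, 18-32 nt
    tag collapsing, exact genome mapping, structural ncRNA removal, known-miRNA
    annotation with isomiR end-shift tolerance, novel miRNA prediction from
    hairpin secondary structure, RPM normalization with a two-genotype log2
    fold-change contrast that defines candidate senescence-associated miRNAs,
    degradome (PARE) target and cleavage-site calling with 0-4 peak categories,
    2^-ddCt relative quantification, and spectrophotometric chlorophyll
    determination. Ships a synthetic-data generator with planted ground truth
    (miRNA loci, expression contrasts, cleavage sites, phenotype trajectories)
    so every stage can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
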