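Package: peakarch
Title: Regulatory Architecture Analysis of ATAC-Seq Peaks over Developmental Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the regulatory architecture of gene sets from
    replicate ATAC-seq peak calls across a developmental time course.
    Builds replicate-consensus peak sets, excludes blacklist and repeat
    regions, assigns peaks to genomic features and nearest genes, and
    compares genomic-feature and peaks-per-gene distributions between a
    gene set and the genome-wide background using non-parametric bootstrap
    confidence intervals. Also classifies transcriptionally repressed genes
    from expression count matrices over ordered time points, partitions
    peaks by overlap with housekeeping and developmental enhancer sets,
    builds average accessibility metaprofiles around peak centers or TSSs,
    and ships a fully deterministic synthetic-data generator with ground
    truth so the entire pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
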