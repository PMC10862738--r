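Package: pamtrace
Title: Tumor-Specific CRISPR PAM Targets and Their Maintenance Across Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects somatic single-base substitutions that create novel NGG
    protospacer adjacent motif (PAM) sites from tumor-normal variant calls,
    models the relationship between variant allele fraction, purity and copy
    number, classifies genomic regions by zygosity and truncal versus private
    loss of heterozygosity (LOH), and quantifies how well PAM targets are
    maintained across a patient's metastases. Ships a metastatic
    clonal-evolution simulator with explicit homolog tracking and read-level
    sampling that provides ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
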