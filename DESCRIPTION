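Package: microhapr
Title: Microhaplotype Marker Databases, Population Frequencies, and
    Variation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with microhaplotype (microhap) forensic
    markers: a portable tab-delimited database model for marker
    definitions, population samples, and haplotype frequencies;
    estimation of per-population microhaplotype frequencies from phased
    genotype panels in VCF; marker-ranking statistics (effective number
    of alleles, Rosenberg informativeness for assignment, Weir-Cockerham
    FST) and marker geometry (core length, overlap, closest
    non-overlapping neighbor); query, detail-view, FASTA, and
    amplicon-design operations; and a synthetic phased-panel simulator
    with known generating haplotype distributions for testing and
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
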