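Package: arraycnv
Title: Consensus CNV Calling, Mosaicism and Trio Analytics for SNP Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for clinical interpretation of SNP-array
    copy-number data. Combines CNV callsets from multiple HMM callers
    (QuantiSNP, PennCNV or any column-mapped TSV) by probe-level majority
    vote with conservative delineation, runs sample quality control with
    GC-wave correction and chromosome-level B-allele-frequency screening
    that triggers mosaicism analysis, segments mirrored BAF to quantify
    mosaic cell fractions, classifies trio genotypes for Mendelian
    inconsistency, uniparental disomy, non-paternity and parent of origin
    of de novo events, and annotates and reports regions against control
    and gene tracks with ISCN-style naming and BED export. A seeded
    synthetic-data generator plants CNVs, mosaic events, UPD regions and
    trio transmission so every stage is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
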