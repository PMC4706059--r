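Package: hicditag
Title: Processing and Quality Control of Hi-C and Capture Hi-C Di-Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Read-level processing pipeline for Hi-C and Capture Hi-C
    paired-end sequencing libraries. Derives the ligation-junction sequence
    from a restriction-enzyme specification and truncates reads at it,
    digests a reference genome in silico into a restriction-fragment map,
    aligns mates independently and re-pairs them into putative di-tags,
    classifies each di-tag as valid or as a protocol artifact (circularised,
    dangling end, internal fragment, re-ligation, contiguous run, wrong
    insert size), removes PCR duplicates, and summarises every stage in
    machine-readable tables and a self-contained HTML quality-control
    report. A barcode-concordance module quantifies whether duplicate
    di-tags share adapter barcodes, discriminating PCR amplification from
    coincidental identity. A seeded simulator generates synthetic genomes
    and libraries with per-read ground truth for every artifact class, so
    the whole pipeline is testable without external data or an external
    aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
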