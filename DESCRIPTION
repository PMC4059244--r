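Package: mosaicmap
Title: SNP Recombination Exclusion Mapping for EMS Mosaic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying EMS-induced causative mutations in
    Drosophila germline mosaic screens. Simulates the mutagenesis,
    meiotic-recombination and SNP-genotyping experiment on a chromosome
    arm; performs two-stage SNP exclusion mapping (anchor-marker
    recombinant classification followed by minimal-interval inference);
    intersects mapped intervals with whole-genome-sequencing lesion
    lists and classifies coding effects; detects two-locus synthetic
    phenotypes; and quantifies mapping resolution and candidate yield
    by Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
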