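Package: scaftag
Title: Truth-Known Evaluation of Genome Assembly Scaffolders via Unique Sequence Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates truth-known contig and paired-read datasets, builds
    error-free taggable contigs from assembler output aligned to a reference,
    locates a unique sequence tag in every contig, classifies each join made
    by a scaffolding tool as correct, incorrect or skipping (and each tag as
    found or lost), and ranks tools with min-max scaled metrics combined under
    a constrained family of integer weightings. Includes perfect paired-end
    read simulation with normally distributed fragment lengths, reference
    tiling into fixed-length contigs, merging of nucmer show-coords alignment
    hits into artificial contigs, N50 and corrected N50 statistics, and
    enumeration of the deduplicated weight space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    graphics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
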