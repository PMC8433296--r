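Package: dnastore
Title: Self-Contained DNA Data Storage with Primer-Indexed Random Access
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico DNA data storage system in which stored files carry
    the tools needed to restore them. Files and tool blobs are packed into
    fixed-offset binary container records, transcoded to nucleotide sequences
    by pluggable codecs, split into addressed oligo fragments flanked by
    primer pairs that double as file indexes, and kept in an unordered oligo
    pool supporting PCR-style random access. Three self-containment
    strategies (one-to-one continuous storage, many-to-one chain indexing,
    one-to-many chain indexing) trade stored bases against sequencing
    rounds; closed-form overhead models quantify each. Includes a primer
    designer with GC, homopolymer and pairwise-distance constraints, a
    seeded synthetic-corpus generator, and an end-to-end verification
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
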