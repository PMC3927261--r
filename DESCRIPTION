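Package: fqsim
Title: Reference-Free FASTQ Read Simulation with Tunable Repeat Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates FASTQ files without a reference genome by generating
    the three channels of a read independently: syntactically valid headers
    for Illumina, ABI-SOLiD, Roche-454 and Ion Torrent instruments (with
    base-36 well-location accessions and chip-bounded coordinates); DNA base
    streams over {A,C,G,T,N} with configurable composition and planted
    exact, approximate and reverse-complement repeats that tune the
    post-compression ratio of the output; and quality-score strings drawn
    from uniform or Gaussian distributions over sparse printable-ASCII
    alphabets, with rank-even quantization. Includes SOLiD color-space
    conversion, a structural FASTQ validator, and an adaptive finite-context
    information profiler for verifying the planted repeat structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
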