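Package: irscan
Title: Genome-Scale Detection of Perfect and Imperfect DNA Inverted Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects perfect and imperfect DNA inverted repeats (palindromes
    and quasipalindromes with stem mismatches and/or a central non-palindromic
    spacer) at genome scale. Nucleotides are mapped to complex scores
    (A -> 1, T -> -1, C -> i, G -> -i) so that reverse-complementary bases
    cancel; prefix sums turn window scoring into vector arithmetic, a
    zero-score (perfect) or |Re|+|Im| <= m (imperfect) filter nominates
    candidate windows, and validated hits are grown by one base per end with
    incremental mismatch bookkeeping. Hits carry a stem-mismatch/spacer
    decomposition and dot-bracket structure strings, and can be written as
    three-line dot-bracket records, TSV, or BED. Brute-force reference
    detectors and a synthetic-sequence generator with planted inverted
    repeats support property-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
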