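# irscan

Genome-scale detection of perfect and imperfect DNA inverted repeats in R.

An inverted repeat (IR) is a nucleotide segment whose first half is
(approximately) the reverse complement of its second half. Perfect IRs
(palindromes, e.g. `GAATTC`) are necessarily of even length; imperfect IRs
(quasipalindromes) tolerate non-complementary pairs in the pairing stem
and/or a central non-palindromic spacer, and can extrude cruciforms in
double-stranded DNA or fold into hairpins in single strands — structures
involved in replication stalling, recombination hotspots, transposon
boundaries and transcriptional regulation. `irscan` is for genomicists who
want an exact, exhaustive scan for such motifs in sequences from plasmid to
chromosome scale, with structure-aware output (dot-bracket strings, BED/TSV
tables) ready for downstream genomic analysis.

## The algorithm

Instead of string comparison, each base is mapped to a complex score

    A -> 1,  T -> -1,  C -> i,  G -> -i

so a base and its reverse complement cancel exactly. With the cumulative
score V (prefix sums of the per-base scores), the score of the window of
length *h* starting at *i* is

    C(i) = V(i+h-1) - V(i-1)

computed for all windows of one length at once. Two facts drive the search:

* a perfect IR has window score exactly 0 (necessary, not sufficient);
* for any window, |Re C| + |Im C| ≤ m, its mismatch count — the number of
  nucleotides in non-complementary stem pairs (2 per failed pair) plus the
  nucleotides of the central spacer (1 each, including the unpaired centre of
  every odd-length window).

Candidate windows of the minimum length *l* are nominated by the score test
(`= 0` for perfect, `≤ m` for imperfect), verified by direct pairing, and
grown one base per end: an IR of length *h* always contains a same-centre IR
of length *h−2*, so only the two new terminal bases need checking, with the
mismatch count updated incrementally (+0 if they pair, +2 otherwise). Two
passes seeded at *l* and *l+1* cover both length parities in imperfect mode.
A reported imperfect hit has `1 ≤ mismatch ≤ m` and reverse-complementary
terminal bases; windows containing N or other ambiguity codes are never
reported. Each hit's mismatch total is decomposed into central spacer
("gap") nucleotides — the centre-anchored run of non-pairing pairs — versus
stem mismatches.

## Worked example

```r
library(irscan)

hits <- findInvertedRepeats("ATCGAACGAATTCGTTAACC", mode = "both",
                            minLength = 4, maxLength = 20, maxMismatch = 4)
hits
#> IRHits: 21 inverted repeats (both mode)
#>   length range [4, 20], max mismatch 4
#>   1 sequence record(s); lengths 4-12 nt; mismatch 0-4
#>   seqnames start end irLength mismatchStem gapCount mismatchTotal          seq    structure
#> 1     seq1     2   9        8            0        2             2     TCGAACGA     (((..)))
#> 2     seq1     2   6        5            0        3             3        TCGAA        (...)
#> 3     seq1     2   5        4            0        0             0         TCGA         (())
#> 4     seq1     3  14       12            0        4             4 CGAACGAATTCG ((((....))))
#> 5     seq1     3   8        6            0        2             2       CGAACG       ((..))
#> 6     seq1     4  13       10            0        4             4   GAACGAATTC   (((....)))
#>   ... and 15 more
```

Each row is one hit with 1-based closed coordinates inside its own sequence
record: row 1 is an 8-mer starting at position 2 whose three outer pairs all
pair (brackets) around a 2-nucleotide central spacer (dots), hence mismatch
total 2 = 0 stem + 2 gap. The classic quasipalindrome worked through the
package documentation:

```r
writeLines(formatRecords(findImperfectIRs("AACAACTTTCTT", 12, 12, 4)))
#> >1|12|2|2
#> AACAACTTTCTT
#> ((.((..)).))
```

The header reads `>start|length|stemMismatches|gapCount`; the 12-mer carries
4 mismatch nucleotides in total — one failed stem pair (positions 3/10, 2
nucleotides) plus a 2-nucleotide central spacer. `writeIRHits()` exports
this three-line record format, a TSV table, or BED6 intervals;
`asGRanges()` hands hits to the GenomicRanges ecosystem. Brute-force
reference detectors (`bruteForcePerfectIRs()`, `bruteForceImperfectIRs()`)
and a generator of random DNA with planted IRs (`randomDna()`, `plantIR()`)
support independent validation, and the installed `exec/irscan` script
exposes `detect`, `synth` and `oracle` subcommands for shell use.

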