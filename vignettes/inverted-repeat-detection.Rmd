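---
title: "Detecting perfect and imperfect inverted repeats with complex scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting perfect and imperfect inverted repeats with complex scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irscan)
```

## The problem

A DNA inverted repeat (IR) is a segment whose 5' half is, exactly or
approximately, the reverse complement of its 3' half. Perfect IRs
(palindromes) pair completely and are necessarily of even length. Imperfect
IRs (quasipalindromes) tolerate two kinds of defect: non-complementary pairs
inside the pairing stem, and a central non-palindromic spacer — the loop of a
hairpin or the unpaired tip of a cruciform. Both structures matter
biologically (replication stalling, recombination hotspots, protein binding
sites, transposon termini), so a detector should enumerate *all* IRs in a
length window, exactly, at chromosome scale.

`irscan` replaces string comparison with arithmetic. Each base is scored

$$A \mapsto 1,\quad T \mapsto -1,\quad C \mapsto i,\quad G \mapsto -i,$$

the unique feature being that a base and its reverse complement cancel:
$score(b) + score(\mathrm{revcomp}(b)) = 0$, and *only* complementary bases
cancel (A/T on the real axis, C/G on the imaginary axis, so cross-axis
cancellation is impossible). Which of the two axes carries A/T is an
arbitrary labelling; any consistent relabelling gives an equivalent
algorithm. With prefix sums $V$ of the score vector, every length-$h$ window
score is one subtraction, $C(i) = V(i+h-1) - V(i-1)$, computed for all
windows of one length simultaneously.

## Mismatch accounting

The mismatch count of a window is measured in nucleotides: each
non-complementary mirrored pair contributes 2 and each spacer nucleotide 1.
The centre base of an odd-length window can never pair, so it always
contributes 1 — hence odd-length hits always have odd mismatch totals and
even-length hits even totals (the *parity law*, asserted in the tests). The
score bound

$$|\mathrm{Re}\,C| + |\mathrm{Im}\,C| \le m$$

holds for every window with true mismatch count $m$: complementary pairs
contribute 0 to both sides, a non-complementary pair contributes at most 2
to the left side and exactly 2 to the right, and an unpaired centre at most
1 to each. The bound is therefore a *sound* candidate filter — it can admit
false candidates (e.g. `TACG` scores 0 without being a palindrome) but never
rejects a true one. Every candidate is verified by direct pairing before it
is reported.

## The search

**Perfect mode.** At the minimum length $l$, windows with $C = 0$ and no
ambiguous base are candidates; direct pairing of all $h/2$ mirrored pairs
validates them. A perfect IR of length $h$ must contain a same-centre perfect
IR of length $h-2$, so longer hits are found by extending each validated hit
one base per end and keeping those whose two new terminal bases pair —
interior bases are never rescanned. This repeats until the maximum length
$L$.

**Imperfect mode.** Seeding at length $l$, windows passing the score bound
get their exact mismatch count $\alpha$ computed by direct pairing. A window
is *reported* iff (1) $\alpha \le m$, (2) its terminal bases are
reverse-complementary, and (3) $\alpha > 0$; it is *carried* for extension
iff (1) alone holds, because the nested interior of a longer qualifying IR
need not itself have pairing ends. Extension updates $\alpha$ incrementally:
+0 when the two new ends pair, +2 otherwise; carries exceeding $m$ are
dropped, and carries flush against either sequence end cannot be extended.
Because extension changes length by 2, a second pass seeded at $l+1$ covers
the other length parity. Condition (3) makes the perfect and imperfect
outputs disjoint by construction.

## Parameters

* `minLength` / `maxLength` — inclusive length bounds in nucleotides.
  Defaults: 10–1000 (perfect), 20–1000 (imperfect), the ranges commonly used
  for genome-scale surveys of cruciform-competent motifs. Both bounds must be
  even in perfect mode; `maxLength` may be any value up to the sequence
  length (there is no hard 1000-nt ceiling).
* `maxMismatch` — maximum mismatch nucleotides per imperfect hit; default 6.
  Must be at least 1: with 0 allowed, condition (3) would leave nothing
  reportable, so the detector rejects `maxMismatch = 0` with an explanatory
  error rather than silently returning an empty set. Note this single budget
  covers stem mismatches *and* spacer; tools that budget "mismatches" and
  "gaps" separately (e.g. EMBOSS `palindrome`) count the same window
  differently.
* `maximalOnly` — by default every qualifying length is reported, so a long
  palindrome also appears as its nested same-centre family (the literal
  per-length enumeration of the search). `maximalOnly = TRUE` suppresses
  hits nested inside a longer reported same-centre hit, for users who want
  one row per locus.

## Conventions and degenerate inputs

* Coordinates are 1-based and fully closed everywhere except BED output
  (0-based, half-open, per the format).
* Hits are ordered by input record, then start, then descending length;
  ties cannot occur because (record, start, length) is unique.
* N and all other IUPAC ambiguity codes score $0+0i$ but are flagged, and
  any window containing one is rejected at the candidate stage; during
  extension, growing onto an ambiguous base drops the carry. Ambiguous bases
  never pair — an N-run is not an inverted repeat.
* Soft-masked (lowercase) input is uppercased and treated as normal
  sequence; `U` is accepted and read as `T`; empty sequences and gap or
  whitespace characters are errors.
* Multi-record FASTA inputs are scanned per record with each record's own
  coordinates.

## Mismatch decomposition and output

Reported totals are decomposed for annotation: walking outward from the
centre, the maximal run of consecutive non-pairing pairs (plus the unpaired
centre of an odd window) is the central spacer, reported as `gapCount` in
nucleotides; any non-pairing pair separated from the centre by at least one
pairing pair is a stem mismatch (`mismatchStem`, 2 per pair). The two always
sum to the total. This centre-anchored rule is a design choice: it matches
the three canonical hit architectures (mismatch-only, mismatch plus spacer,
spacer-only) and makes the header fields of the three-line record format —
`>start|length|mismatchStem|gapCount`, window sequence, dot-bracket string —
sum to the detector's own mismatch accounting. In the dot-bracket string,
pairing positions get brackets and every mismatch/spacer nucleotide a dot,
so dots count the mismatch total exactly.

## The synthetic test bed

Verification rests on two independent routes. The brute-force oracles check
every window of every length by direct character pairing — no complex
scores, no prefix sums, no extension — so detector–oracle agreement is
evidence rather than tautology. The generator produces i.i.d. uniform
random DNA at a chosen GC content, and `plantIR()` splices in windows with a
prescribed architecture (stem pairs, spacer length, stem-mismatch count);
spacer bases are drawn so that no spacer pair is complementary, and
mismatched stem pairs avoid the outermost pair (which must pair for the hit
to be reportable) and the innermost pair (so the centre-anchored gap run
stays exactly the spacer), making the planted window's mismatch total and
decomposition known by construction. The random background can legitimately
extend a planted repeat, so recovery tests assert membership of the planted
hit, and equivalence tests assert exact hit-set equality with the oracle
rather than counts.

The test suite runs the oracle-equivalence campaign on 108 random sequences
of 200–2000 nt across minimum lengths {4, 10, 20} and mismatch budgets
{2, 4, 6, 7}, plus exhaustive bound-soundness and parity checks on smaller
instances — sizes chosen so the quadratic oracles stay fast while covering
every code path (both parities, N handling, boundary windows). Uniform
random DNA has no repeat families, GC isochores or masked regions, so
passing tests demonstrate algorithmic correctness of the search, not
biological realism of hit densities; on real genomes the same exact
algorithm applies unchanged, and the genome-count checks in the acceptance
tests can be run by dropping the reference FASTA files into `inst/extdata`.

## Limitations

* Indels within the pairing stem are not modelled: the two halves must have
  equal length, and a bulged stem is only found as a shorter flanking IR.
* No thermodynamic scoring, GU wobble pairing, or RNA folding: pairing is
  strict Watson–Crick on the DNA alphabet.
* The detector holds per-sequence score vectors in memory (a few machine
  words per base), comfortable for chromosome-scale input on a workstation
  but not streaming.
* The brute-force oracles are quadratic and intended for kilobase-scale
  validation only.
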