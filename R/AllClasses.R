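#' Complex-score encoding of a DNA sequence
#'
#' Per-base complex scores for one sequence: A = 1+0i, T = -1+0i, C = 0+1i,
#' G = 0-1i, chosen so that a base and its reverse complement sum to exactly
#' zero. Bases outside ACGT (N and other IUPAC ambiguity codes) carry score
#' 0+0i and are flagged invalid so that windows containing them can be
#' rejected: ambiguous bases never pair.
#'
#' @slot scores complex vector, one score per base.
#' @slot valid logical vector, `TRUE` iff the base is one of A, C, G, T.
#'
#' @seealso [mapBases()], [cumulativeScore()], [windowScores()]
#' @export
setClass("ComplexMapping",
    representation(scores = "complex", valid = "logical"))

setValidity("ComplexMapping", function(object) {
    if (length(object@scores) != length(object@valid))
        return("'scores' and 'valid' must have the same length")
    if (any(object@scores[!object@valid] != 0 + 0i))
        return("invalid positions must carry score 0+0i")
    TRUE
})

#' Set of detected inverted repeats
#'
#' Container for inverted-repeat hits on one or more sequences. Each hit
#' records its 1-based, fully-closed coordinates, its total mismatch count in
#' nucleotides (every non-complementary stem pair contributes 2, every spacer
#' nucleotide 1), the decomposition of that total into stem mismatches versus
#' central spacer ("gap") nucleotides, the window sequence, and a dot-bracket
#' structure string in which brackets mark pairing positions and dots mark
#' mismatch/spacer positions.
#'
#' @slot hits a [S4Vectors::DataFrame] with columns `seqnames`, `start`,
#'   `irLength`, `mismatchStem`, `gapCount`, `mismatchTotal`, `seq`,
#'   `structure`.
#' @slot params list of the search parameters that produced the hits.
#'
#' @seealso [findPerfectIRs()], [findImperfectIRs()], [writeIRHits()]
#' @aliases IRHits
#' @export
setClass("IRHits",
    representation(hits = "DataFrame", params = "list"))

setValidity("IRHits", function(object) {
    h <- object@hits
    need <- c("seqnames", "start", "irLength", "mismatchStem", "gapCount",
              "mismatchTotal", "seq", "structure")
    if (!all(need %in% colnames(h)))
        return(paste("missing hit columns:",
                     paste(setdiff(need, colnames(h)), collapse = ", ")))
    if (nrow(h) == 0L)
        return(TRUE)
    if (any(h$start < 1L) || any(h$irLength < 1L))
        return("coordinates are 1-based and lengths positive")
    if (any(h$mismatchStem + h$gapCount != h$mismatchTotal))
        return("mismatchStem + gapCount must equal mismatchTotal")
    if (any(nchar(h$structure) != h$irLength))
        return("structure strings must have length irLength")
    ndot <- nchar(gsub("[()]", "", h$structure))
    if (any(ndot != h$mismatchTotal))
        return("number of '.' in structure must equal mismatchTotal")
    if (anyDuplicated(paste(h$seqnames, h$start, h$irLength)))
        return("hits must be unique on (seqnames, start, irLength)")
    TRUE
})
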