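# Integer base codes: A=1, C=2, G=3, T=4, anything else 0. Complementary
# pairs (A/T, C/G) are exactly those whose codes sum to 5.
.BASE_CODE <- local({
    tbl <- integer(256L)
    tbl[utf8ToInt("A")] <- 1L; tbl[utf8ToInt("a")] <- 1L
    tbl[utf8ToInt("C")] <- 2L; tbl[utf8ToInt("c")] <- 2L
    tbl[utf8ToInt("G")] <- 3L; tbl[utf8ToInt("g")] <- 3L
    tbl[utf8ToInt("T")] <- 4L; tbl[utf8ToInt("t")] <- 4L
    tbl[utf8ToInt("U")] <- 4L; tbl[utf8ToInt("u")] <- 4L   # RNA input
    tbl
})

# Complex score per code (index = code + 1): invalid=0, A=1, C=i, G=-i, T=-1
.CODE_SCORE <- c(0 + 0i, 1 + 0i, 0 + 1i, 0 - 1i, -1 + 0i)

.CODE_CHAR <- c("N", "A", "C", "G", "T")

# Encode one sequence string to integer codes. Whitespace/gaps are rejected:
# ingest must have stripped them.
.encodeDNA <- function(s) {
    if (!is.character(s) || length(s) != 1L || is.na(s))
        stop("expected a single sequence string")
    if (nchar(s) == 0L)
        stop("empty sequence")
    ints <- utf8ToInt(s)
    if (any(ints > 255L))
        stop("non-ASCII character in sequence")
    code <- .BASE_CODE[ints]
    bad <- ints %in% utf8ToInt(" \t\r\n-.")
    if (any(bad))
        stop("sequence contains whitespace or gap characters")
    code
}

# Normalise detector input to a named list of uppercase character strings.
# Accepts character vectors (optionally named), DNAString, DNAStringSet.
.ingestSeqs <- function(x) {
    if (is(x, "DNAString"))
        x <- Biostrings::DNAStringSet(x)
    if (is(x, "DNAStringSet")) {
        ids <- names(x)
        x <- as.character(x)
        names(x) <- ids
    }
    if (!is.character(x) || length(x) == 0L)
        stop("input must be a character vector, DNAString or DNAStringSet")
    ids <- names(x)
    if (is.null(ids) || any(!nzchar(ids)))
        ids <- if (length(x) == 1L) "seq1" else paste0("seq", seq_along(x))
    # first word of a FASTA-style description
    ids <- sub("\\s.*$", "", ids)
    x <- chartr("u", "U", toupper(x))
    x <- chartr("U", "T", x)
    names(x) <- ids
    as.list(x)
}

#' Map a DNA sequence to complex scores
#'
#' Converts a sequence into its complex score vector: A maps to 1, T to -1,
#' C to i and G to -i, so the scores of reverse-complementary bases cancel
#' exactly. Non-ACGT bases (N and other IUPAC ambiguity codes) score 0+0i and
#' are flagged invalid; `U` is accepted as `T`; lowercase is uppercased.
#'
#' @param x a single sequence: one-element character vector or
#'   [Biostrings::DNAString].
#' @return a [ComplexMapping-class] object.
#' @examples
#' m <- mapBases("ATCG")
#' m@scores   # 1, -1, i, -i
#' @export
mapBases <- function(x) {
    s <- .ingestSeqs(x)
    if (length(s) != 1L)
        stop("mapBases() expects a single sequence")
    code <- .encodeDNA(s[[1L]])
    new("ComplexMapping",
        scores = .CODE_SCORE[code + 1L],
        valid = code != 0L)
}

#' Cumulative complex score
#'
#' Running sum of the complex scores with a leading zero, so that the score of
#' the window `[i, i+h-1]` (1-based, closed) is `V[i+h] - V[i]`. The returned
#' vector has length N+1.
#'
#' @param mapping a [ComplexMapping-class] from [mapBases()].
#' @return complex vector of length `length(mapping@scores) + 1`.
#' @export
cumulativeScore <- function(mapping) {
    stopifnot(is(mapping, "ComplexMapping"))
    c(0 + 0i, cumsum(mapping@scores))
}

#' Window scores for a fixed window length
#'
#' Scores of all length-`h` windows, computed as prefix-sum differences. Entry
#' `i` is the sum of the complex scores over the window starting at 1-based
#' position `i`; there are exactly `N - h + 1` entries.
#'
#' @param cumulative the length-(N+1) vector from [cumulativeScore()].
#' @param h window length, `1 <= h <= N`.
#' @return complex vector of length `N - h + 1`.
#' @export
windowScores <- function(cumulative, h) {
    n <- length(cumulative) - 1L
    h <- as.integer(h)
    if (length(h) != 1L || is.na(h) || h < 1L || h > n)
        stop("window length must satisfy 1 <= h <= sequence length")
    cumulative[(1L + h):(n + 1L)] - cumulative[seq_len(n - h + 1L)]
}

# Prefix counts of invalid positions (leading 0); window [i, i+h-1] is
# all-valid iff vc[i+h] - vc[i] == 0.
.invalidPrefix <- function(code) c(0L, cumsum(code == 0L))
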