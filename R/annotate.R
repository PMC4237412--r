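# Pairing tests on integer base codes. A window [s, s+h-1] has floor(h/2)
# pairs (s+k-1, s+h-k); a pair is complementary iff the codes sum to 5 (A=1,
# C=2, G=3, T=4: A+T = C+G = 5; any invalid base, code 0, can never pair).

# Total mismatch count (nucleotides) per start, fixed window length h:
# 2 per non-complementary pair, +1 for the unpaired centre of odd h.
.mmCount <- function(code, starts, h) {
    acc <- integer(length(starts))
    for (k in seq_len(h %/% 2L))
        acc <- acc + 2L * (code[starts + k - 1L] + code[starts + h - k] != 5L)
    if (h %% 2L == 1L)
        acc <- acc + 1L
    acc
}

# Centre-anchored decomposition of the mismatch total: the maximal run of
# consecutive non-pairing pairs walking outward from the centre (plus the
# unpaired centre base of odd windows) is the spacer ("gaps"); every other
# non-pairing pair is a stem mismatch. Counts are in nucleotides.
.decompose <- function(code, starts, h) {
    n <- length(starts)
    half <- h %/% 2L
    gap <- rep.int(if (h %% 2L == 1L) 1L else 0L, n)
    stem <- integer(n)
    inrun <- rep.int(TRUE, n)
    for (k in rev(seq_len(half))) {          # innermost pair first
        fail <- code[starts + k - 1L] + code[starts + h - k] != 5L
        gap <- gap + 2L * (inrun & fail)
        stem <- stem + 2L * (fail & !inrun)
        inrun <- inrun & fail
    }
    list(stem = stem, gap = gap)
}

.dotBracket1 <- function(code, s, h) {
    ch <- rep.int(".", h)
    for (k in seq_len(h %/% 2L)) {
        if (code[s + k - 1L] + code[s + h - k] == 5L) {
            ch[k] <- "("
            ch[h + 1L - k] <- ")"
        }
    }
    paste(ch, collapse = "")
}

.checkWindowArgs <- function(code, start, width) {
    start <- as.integer(start)
    width <- as.integer(width)
    n <- max(length(start), length(width))
    start <- rep_len(start, n)
    width <- rep_len(width, n)
    if (any(is.na(start)) || any(is.na(width)) ||
        any(start < 1L) || any(width < 1L) ||
        any(start + width - 1L > length(code)))
        stop("window out of sequence bounds")
    for (i in seq_len(n))
        if (any(code[start[i]:(start[i] + width[i] - 1L)] == 0L))
            stop("window contains a non-ACGT base")
    list(start = start, width = width)
}

#' Mismatch count of candidate inverted-repeat windows
#'
#' Counts, in nucleotides, how far a window deviates from a perfect inverted
#' repeat: each non-reverse-complementary pair between mirrored positions
#' contributes 2, and the unpaired centre base of an odd-length window
#' contributes 1 (it is necessarily a spacer nucleotide). A perfect palindrome
#' scores 0. This is the quantity bounded from below by |Re|+|Im| of the
#' window's complex score.
#'
#' @param x a single sequence (character or [Biostrings::DNAString]).
#' @param start,width 1-based window starts and widths (recycled against each
#'   other). Windows must lie inside the sequence and contain only ACGT.
#' @return integer vector of mismatch counts.
#' @examples
#' mismatchCount("AACAACTTTCTT", 1, 12)   # 4
#' mismatchCount("GAATTC", 1, 6)          # 0
#' @export
mismatchCount <- function(x, start = 1L, width = NULL) {
    s <- .ingestSeqs(x)
    if (length(s) != 1L)
        stop("mismatchCount() expects a single sequence")
    code <- .encodeDNA(s[[1L]])
    if (is.null(width))
        width <- length(code) - start + 1L
    w <- .checkWindowArgs(code, start, width)
    out <- integer(length(w$start))
    for (h in unique(w$width)) {
        i <- w$width == h
        out[i] <- .mmCount(code, w$start[i], h)
    }
    out
}

#' Decompose a window's mismatch total into stem mismatches and spacer gaps
#'
#' Walking outward from the window centre, the maximal run of consecutive
#' non-pairing pairs (plus the unpaired centre base of an odd-length window)
#' is counted as the central spacer, reported in nucleotides as `gapCount`;
#' every non-pairing pair separated from the centre by at least one pairing
#' pair is a stem mismatch (2 nucleotides each), reported as `mismatchStem`.
#' The two always sum to [mismatchCount()].
#'
#' @inheritParams mismatchCount
#' @return a data.frame with integer columns `mismatchStem` and `gapCount`.
#' @examples
#' decomposeMismatches("AACAACTTTCTT", 1, 12)  # stem 2, gap 2
#' decomposeMismatches("CAAAAATTTTG", 1, 11)   # stem 0, gap 1
#' @export
decomposeMismatches <- function(x, start = 1L, width = NULL) {
    s <- .ingestSeqs(x)
    if (length(s) != 1L)
        stop("decomposeMismatches() expects a single sequence")
    code <- .encodeDNA(s[[1L]])
    if (is.null(width))
        width <- length(code) - start + 1L
    w <- .checkWindowArgs(code, start, width)
    stem <- gap <- integer(length(w$start))
    for (h in unique(w$width)) {
        i <- w$width == h
        d <- .decompose(code, w$start[i], h)
        stem[i] <- d$stem
        gap[i] <- d$gap
    }
    data.frame(mismatchStem = stem, gapCount = gap)
}

#' Dot-bracket structure of an inverted-repeat window
#'
#' Renders the pairing pattern of a window: position `i` gets `(` and its
#' mirror `h+1-i` gets `)` when the two bases are reverse-complementary; both
#' get `.` otherwise, and the centre base of an odd-length window is always
#' `.`.
#'
#' @inheritParams mismatchCount
#' @return character vector of structure strings, one per window.
#' @examples
#' dotBracket("GAATTC", 1, 6)        # "((()))"
#' dotBracket("AACAACTTTCTT", 1, 12) # "((.((..)).))"
#' @export
dotBracket <- function(x, start = 1L, width = NULL) {
    s <- .ingestSeqs(x)
    if (length(s) != 1L)
        stop("dotBracket() expects a single sequence")
    code <- .encodeDNA(s[[1L]])
    if (is.null(width))
        width <- length(code) - start + 1L
    w <- .checkWindowArgs(code, start, width)
    vapply(seq_along(w$start),
           function(i) .dotBracket1(code, w$start[i], w$width[i]),
           character(1))
}

#' Render hits as three-line dot-bracket records
#'
#' Each hit becomes three lines: a header
#' `>start|length|mismatchStem|gapCount`, the window sequence, and the
#' dot-bracket structure string. Coordinates are 1-based within the hit's own
#' sequence record.
#'
#' @param x an [IRHits-class] object.
#' @return character vector of output lines (three per hit).
#' @export
formatRecords <- function(x) {
    stopifnot(is(x, "IRHits"))
    h <- x@hits
    if (nrow(h) == 0L)
        return(character(0))
    header <- paste0(">", h$start, "|", h$irLength, "|",
                     h$mismatchStem, "|", h$gapCount)
    as.vector(rbind(header, h$seq, h$structure))
}
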