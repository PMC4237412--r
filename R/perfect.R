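.checkPerfectParams <- function(l, L, n) {
    if (length(l) != 1L || length(L) != 1L || is.na(l) || is.na(L))
        stop("minLength and maxLength must be single integers")
    if (l %% 2L != 0L || L %% 2L != 0L)
        stop("perfect inverted repeats have even length: ",
             "minLength and maxLength must be even")
    if (l < 2L || l > L)
        stop("need 2 <= minLength <= maxLength")
    if (L > n)
        stop("maxLength (", L, ") exceeds sequence length (", n, ")")
    invisible(TRUE)
}

# Starts of all-valid zero-score windows of length h: the candidate set.
# A zero score is necessary but not sufficient (e.g. 'TACG' scores 0).
.perfectCandidates <- function(V, vc, h) {
    n <- length(V) - 1L
    idx <- seq_len(n - h + 1L)
    C <- V[idx + h] - V[idx]
    which(C == 0 + 0i & vc[idx + h] - vc[idx] == 0L)
}

# Keep starts whose length-h window pairs perfectly: position k against
# h+1-k for all k <= h/2.
.validatePerfect <- function(code, starts, h) {
    for (k in seq_len(h %/% 2L)) {
        if (!length(starts)) break
        starts <- starts[code[starts + k - 1L] + code[starts + h - k] == 5L]
    }
    starts
}

# One-base-per-end extension of validated perfect IRs of length h: keeps
# s-1 where the two new terminal bases are reverse-complementary; interior
# bases are not rescanned. Hits flush against either sequence end are
# never extended.
.extendPerfect <- function(code, starts, h) {
    n <- length(code)
    starts <- starts[starts > 1L & starts + h <= n]
    starts[code[starts - 1L] + code[starts + h] == 5L] - 1L
}

.detectPerfectOne <- function(code, l, L) {
    n <- length(code)
    V <- c(0 + 0i, cumsum(.CODE_SCORE[code + 1L]))
    vc <- .invalidPrefix(code)
    h <- as.integer(l)
    P <- .validatePerfect(code, .perfectCandidates(V, vc, h), h)
    out <- list(data.frame(start = P, irLength = rep.int(h, length(P))))
    while (h + 2L <= L && length(P)) {
        P <- .extendPerfect(code, P, h)
        h <- h + 2L
        out[[length(out) + 1L]] <-
            data.frame(start = P, irLength = rep.int(h, length(P)))
    }
    res <- do.call(rbind, out)
    res$mismatchTotal <- rep.int(0L, nrow(res))
    res
}

#' Detect perfect inverted repeats (palindromes)
#'
#' Finds every even-length window in `[minLength, maxLength]` whose first half
#' is exactly the reverse complement of its second half. Candidate windows of
#' the minimum length are nominated by a zero complex score computed from
#' prefix sums, verified by direct pairing, and then grown by one base per end
#' (a perfect IR of length h always contains a perfect IR of length h-2 with
#' the same centre, so only the two new terminal bases need checking). Windows
#' containing non-ACGT bases are never reported.
#'
#' By default a hit is reported at every qualifying length, so a long
#' palindrome also appears as its nested, same-centre shorter palindromes;
#' `maximalOnly = TRUE` suppresses hits nested inside a longer reported hit
#' with the same centre.
#'
#' @param x sequences to scan: character vector (optionally named),
#'   [Biostrings::DNAString] or [Biostrings::DNAStringSet]. Each record is
#'   scanned independently with its own 1-based coordinates.
#' @param minLength,maxLength inclusive even length bounds; must satisfy
#'   `minLength <= maxLength <= nchar(x)`.
#' @param maximalOnly drop hits fully nested in a longer same-centre hit.
#' @return an [IRHits-class] object, sorted by record, start, then descending
#'   length.
#' @examples
#' findPerfectIRs("ATCGAACGAATTCGTTAACC", minLength = 4, maxLength = 20)
#' @export
setMethod("findPerfectIRs", "ANY",
    function(x, minLength = 10L, maxLength = 1000L, maximalOnly = FALSE) {
        seqs <- .ingestSeqs(x)
        l <- as.integer(minLength)
        L <- as.integer(maxLength)
        found <- vector("list", length(seqs))
        for (i in seq_along(seqs)) {
            code <- .encodeDNA(seqs[[i]])
            .checkPerfectParams(l, L, length(code))
            found[[i]] <- .detectPerfectOne(code, l, L)
        }
        hits <- .buildIRHits(seqs, found,
                             params = list(mode = "perfect", minLength = l,
                                           maxLength = L,
                                           maximalOnly = isTRUE(maximalOnly)))
        if (isTRUE(maximalOnly))
            hits@hits <- S4Vectors::DataFrame(
                .maximalOnly(as.data.frame(hits@hits)))
        hits
    })
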