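.checkImperfectParams <- function(l, L, m, n) {
    if (length(l) != 1L || length(L) != 1L || length(m) != 1L ||
        is.na(l) || is.na(L) || is.na(m))
        stop("minLength, maxLength and maxMismatch must be single integers")
    if (l < 2L || l > L)
        stop("need 2 <= minLength <= maxLength")
    if (L > n)
        stop("maxLength (", L, ") exceeds sequence length (", n, ")")
    if (m < 1L)
        stop("maxMismatch must be >= 1: with 0 mismatches allowed every ",
             "reportable hit would be a perfect palindrome, which the ",
             "imperfect detector excludes by definition")
    invisible(TRUE)
}

# Starts of all-valid windows of length h whose score passes the candidate
# bound |Re(C)| + |Im(C)| <= m. The bound never exceeds the true mismatch
# count, so no qualifying window is lost.
.imperfectCandidates <- function(V, vc, h, m) {
    n <- length(V) - 1L
    idx <- seq_len(n - h + 1L)
    C <- V[idx + h] - V[idx]
    which(abs(Re(C)) + abs(Im(C)) <= m & vc[idx + h] - vc[idx] == 0L)
}

# One parity pass: seed at length h0, then extend by one base per end.
# At every length, a window is REPORTED iff (1) its mismatch count alpha is
# <= m, (2) its terminal bases are reverse-complementary, and (3) alpha > 0;
# it is CARRIED for further extension iff alpha <= m, regardless of (2)/(3).
.imperfectPass <- function(code, V, vc, h0, L, m) {
    n <- length(code)
    out <- list()
    S <- .imperfectCandidates(V, vc, h0, m)
    A <- .mmCount(code, S, h0)
    keep <- A <= m
    S <- S[keep]
    A <- A[keep]
    h <- h0
    rep <- A >= 1L & code[S] + code[S + h - 1L] == 5L
    out[[1L]] <- data.frame(start = S[rep], irLength = rep.int(h, sum(rep)),
                            mismatchTotal = A[rep])
    while (h + 2L <= L && length(S)) {
        # windows flush against a sequence end cannot be extended
        ok <- S > 1L & S + h <= n
        S <- S[ok]
        A <- A[ok]
        a <- code[S - 1L]
        b <- code[S + h]
        pair <- a + b == 5L
        A2 <- A + 2L * !pair
        # extending onto a non-ACGT base disqualifies the window
        keep <- a != 0L & b != 0L & A2 <= m
        S <- S[keep] - 1L
        A <- A2[keep]
        pair <- pair[keep]
        h <- h + 2L
        rep <- pair & A >= 1L
        out[[length(out) + 1L]] <-
            data.frame(start = S[rep], irLength = rep.int(h, sum(rep)),
                       mismatchTotal = A[rep])
    }
    do.call(rbind, out)
}

.detectImperfectOne <- function(code, l, L, m) {
    V <- c(0 + 0i, cumsum(.CODE_SCORE[code + 1L]))
    vc <- .invalidPrefix(code)
    seeds <- c(l, l + 1L)                       # one pass per length parity
    seeds <- seeds[seeds <= L & seeds <= length(code)]
    do.call(rbind, lapply(seeds, .imperfectPass,
                          code = code, V = V, vc = vc, L = L, m = m))
}

#' Detect imperfect inverted repeats (quasipalindromes)
#'
#' Finds windows of any length in `[minLength, maxLength]` that fold into an
#' inverted repeat with at most `maxMismatch` mismatch nucleotides, where
#' every non-reverse-complementary pair between mirrored positions counts 2
#' and the unpaired centre of an odd-length window counts 1 (the spacer).
#' A reported hit additionally has reverse-complementary terminal bases and a
#' non-zero mismatch count, so the output is disjoint from [findPerfectIRs()].
#'
#' Candidate windows are nominated by the score bound |Re(C)|+|Im(C)| <= m
#' (the bound never exceeds the true mismatch count, so no qualifying window
#' is filtered away), verified by direct pairing, and grown one base per end with the mismatch
#' count updated incrementally: +0 when the two new terminal bases pair, +2
#' otherwise. Two passes, seeded at `minLength` and `minLength + 1`, cover
#' both length parities. Odd-length hits always contain the unpaired centre,
#' so their mismatch totals are odd and even-length totals are even. Windows
#' containing non-ACGT bases are never reported.
#'
#' @param x sequences to scan: character vector (optionally named),
#'   [Biostrings::DNAString] or [Biostrings::DNAStringSet].
#' @param minLength,maxLength inclusive length bounds (any parity);
#'   `minLength <= maxLength <= nchar(x)`.
#' @param maxMismatch maximum total mismatch nucleotides per hit; must be
#'   >= 1.
#' @return an [IRHits-class] object, sorted by record, start, then descending
#'   length.
#' @examples
#' findImperfectIRs("AACAACTTTCTT", minLength = 12, maxLength = 12,
#'                  maxMismatch = 4)
#' @export
setMethod("findImperfectIRs", "ANY",
    function(x, minLength = 20L, maxLength = 1000L, maxMismatch = 6L) {
        seqs <- .ingestSeqs(x)
        l <- as.integer(minLength)
        L <- as.integer(maxLength)
        m <- as.integer(maxMismatch)
        found <- vector("list", length(seqs))
        for (i in seq_along(seqs)) {
            code <- .encodeDNA(seqs[[i]])
            .checkImperfectParams(l, L, m, length(code))
            found[[i]] <- .detectImperfectOne(code, l, L, m)
        }
        .buildIRHits(seqs, found,
                     params = list(mode = "imperfect", minLength = l,
                                   maxLength = L, maxMismatch = m))
    })

#' Detect perfect and/or imperfect inverted repeats
#'
#' Convenience wrapper running [findPerfectIRs()], [findImperfectIRs()] or
#' both and concatenating the results. The two hit sets are disjoint by
#' construction: the imperfect detector excludes zero-mismatch windows.
#'
#' @param x sequences to scan (character, DNAString or DNAStringSet).
#' @param mode `"perfect"`, `"imperfect"` or `"both"`.
#' @param minLength minimum hit length; defaults to 10 for perfect and 20 for
#'   imperfect scanning when `NULL`.
#' @param maxLength maximum hit length (inclusive).
#' @param maxMismatch maximum mismatch nucleotides (imperfect mode).
#' @param maximalOnly drop perfect hits nested in longer same-centre hits.
#' @return an [IRHits-class] object.
#' @export
findInvertedRepeats <- function(x, mode = c("both", "perfect", "imperfect"),
                                minLength = NULL, maxLength = 1000L,
                                maxMismatch = 6L, maximalOnly = FALSE) {
    mode <- match.arg(mode)
    res <- list()
    if (mode %in% c("both", "perfect"))
        res$perfect <- findPerfectIRs(x,
            minLength = if (is.null(minLength)) 10L else minLength,
            maxLength = maxLength, maximalOnly = maximalOnly)
    if (mode %in% c("both", "imperfect"))
        res$imperfect <- findImperfectIRs(x,
            minLength = if (is.null(minLength)) 20L else minLength,
            maxLength = maxLength, maxMismatch = maxMismatch)
    if (length(res) == 1L)
        return(res[[1L]])
    tab <- rbind(as.data.frame(res$perfect@hits),
                 as.data.frame(res$imperfect@hits))
    ids <- unique(tab$seqnames)
    tab <- tab[order(match(tab$seqnames, ids), tab$start, -tab$irLength), ,
               drop = FALSE]
    rownames(tab) <- NULL
    params <- res$perfect@params
    params$mode <- "both"
    params$maxMismatch <- res$imperfect@params$maxMismatch
    params$minLengthImperfect <- res$imperfect@params$minLength
    new("IRHits", hits = S4Vectors::DataFrame(tab), params = params)
}
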