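# Brute-force reference detectors. These deliberately share no machinery with
# the production detectors -- no complex scores, no prefix sums, no extension:
# every window of every length is checked independently by direct character
# pairing, so agreement between the two routes is evidence of correctness.

.oracleChars <- function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    list(chars = chars, comp = unname(comp[chars]),
         valid = chars %in% c("A", "C", "G", "T"))
}

#' Brute-force perfect inverted repeat search
#'
#' Reference implementation: every window of every even length in
#' `[minLength, maxLength]` is tested by directly pairing all h/2 mirrored
#' base pairs. No candidate filtering and no extension are used, so the result
#' is an independent check on [findPerfectIRs()]. Quadratic; intended for
#' small sequences in tests.
#'
#' @param x sequences (character, DNAString or DNAStringSet).
#' @param minLength,maxLength inclusive even length bounds.
#' @return data.frame with columns `seqnames`, `start`, `irLength`.
#' @export
bruteForcePerfectIRs <- function(x, minLength = 10L, maxLength = 1000L) {
    seqs <- .ingestSeqs(x)
    l <- as.integer(minLength)
    L <- as.integer(maxLength)
    stopifnot(l %% 2L == 0L, L %% 2L == 0L, l >= 2L, l <= L)
    out <- list()
    for (id in names(seqs)) {
        o <- .oracleChars(seqs[[id]])
        n <- length(o$chars)
        for (h in seq(l, min(L, n), by = 2L)) {
            starts <- seq_len(n - h + 1L)
            ok <- rep.int(TRUE, length(starts))
            for (k in seq_len(h %/% 2L)) {
                cc <- o$comp[starts + k - 1L]
                ok <- ok & !is.na(cc) & cc == o$chars[starts + h - k]
                if (!any(ok)) break
            }
            if (any(ok))
                out[[length(out) + 1L]] <-
                    data.frame(seqnames = id, start = starts[ok],
                               irLength = h, stringsAsFactors = FALSE)
        }
    }
    res <- if (length(out)) do.call(rbind, out) else NULL
    if (is.null(res))
        res <- data.frame(seqnames = character(0), start = integer(0),
                          irLength = integer(0))
    res[order(match(res$seqnames, names(seqs)), res$start, -res$irLength), ,
        drop = FALSE]
}

#' Brute-force imperfect inverted repeat search
#'
#' Reference implementation: every window of every length in
#' `[minLength, maxLength]` is scored by direct pairing (2 per
#' non-complementary pair, 1 for the unpaired centre of odd windows) and
#' reported iff `1 <= mismatch <= maxMismatch`, its terminal bases are
#' reverse-complementary, and it contains only ACGT. Independent check on
#' [findImperfectIRs()]; quadratic, for tests.
#'
#' @param x sequences (character, DNAString or DNAStringSet).
#' @param minLength,maxLength inclusive length bounds (any parity).
#' @param maxMismatch maximum mismatch nucleotides, >= 1.
#' @return data.frame with columns `seqnames`, `start`, `irLength`,
#'   `mismatchTotal`.
#' @export
bruteForceImperfectIRs <- function(x, minLength = 20L, maxLength = 1000L,
                                   maxMismatch = 6L) {
    seqs <- .ingestSeqs(x)
    l <- as.integer(minLength)
    L <- as.integer(maxLength)
    m <- as.integer(maxMismatch)
    stopifnot(l >= 2L, l <= L, m >= 1L)
    out <- list()
    for (id in names(seqs)) {
        o <- .oracleChars(seqs[[id]])
        n <- length(o$chars)
        for (h in seq(l, min(L, n), by = 1L)) {
            starts <- seq_len(n - h + 1L)
            mm <- rep.int(if (h %% 2L == 1L) 1L else 0L, length(starts))
            okvalid <- rep.int(TRUE, length(starts))
            for (k in seq_len(h %/% 2L)) {
                a <- o$comp[starts + k - 1L]
                bval <- o$valid[starts + h - k]
                okvalid <- okvalid & !is.na(a) & bval
                pairok <- !is.na(a) & a == o$chars[starts + h - k]
                mm <- mm + 2L * !pairok
            }
            if (h %% 2L == 1L)
                okvalid <- okvalid & o$valid[starts + (h - 1L) %/% 2L]
            term <- o$comp[starts]
            termok <- !is.na(term) & term == o$chars[starts + h - 1L]
            hit <- okvalid & termok & mm >= 1L & mm <= m
            if (any(hit))
                out[[length(out) + 1L]] <-
                    data.frame(seqnames = id, start = starts[hit],
                               irLength = h, mismatchTotal = mm[hit],
                               stringsAsFactors = FALSE)
        }
    }
    res <- if (length(out)) do.call(rbind, out) else NULL
    if (is.null(res))
        res <- data.frame(seqnames = character(0), start = integer(0),
                          irLength = integer(0), mismatchTotal = integer(0))
    res[order(match(res$seqnames, names(seqs)), res$start, -res$irLength), ,
        drop = FALSE]
}
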