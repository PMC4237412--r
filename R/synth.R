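# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old))
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Generate a uniform-random DNA sequence
#'
#' Bases are drawn i.i.d. with P(C) = P(G) = `gc`/2 and
#' P(A) = P(T) = (1-`gc`)/2.
#'
#' @param n sequence length, >= 1.
#' @param gc target GC fraction in `[0, 1]`.
#' @param seed optional integer; when given, the draw is reproducible and the
#'   caller's RNG state is left untouched.
#' @return a single named character string.
#' @examples
#' randomDna(30, gc = 0.5, seed = 1)
#' @export
randomDna <- function(n, gc = 0.5, seed = NULL) {
    n <- as.integer(n)
    stopifnot(length(n) == 1L, n >= 1L, gc >= 0, gc <= 1)
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    s <- .withSeed(seed,
        paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = ""))
    names(s) <- "random"
    s
}

#' Plant an inverted repeat in a background sequence
#'
#' Constructs a window with a prescribed architecture -- `stemLength` pairs of
#' stem, `spacerLength` central spacer nucleotides chosen so that no spacer
#' pair is reverse-complementary, and `stemMismatches` non-pairing stem pairs
#' -- and splices it into `x` at `position`. The planted window has total
#' mismatch count `2*stemMismatches + spacerLength`, decomposing into
#' `2*stemMismatches` stem-mismatch and `spacerLength` gap nucleotides.
#'
#' Mismatched stem pairs are placed away from both the outermost pair (which
#' must pair for the hit to be reportable) and the innermost pair (so the
#' centre-anchored gap run remains exactly the spacer); this requires
#' `stemMismatches <= stemLength - 2` when any mismatch is requested. The
#' random background around the planted window may itself pair, so detectors
#' can legitimately report extensions of the planted repeat as well.
#'
#' @param x background sequence (single character string or DNAString).
#' @param stemLength number of stem pairs, >= 1.
#' @param spacerLength central spacer nucleotides, >= 0.
#' @param stemMismatches number of non-pairing stem pairs, >= 0.
#' @param position 1-based splice position of the window start.
#' @param seed optional integer for a reproducible construction.
#' @return a list with `seq` (the modified sequence, single named string) and
#'   `truth` (one-row data.frame: `start`, `irLength`, `mismatchStem`,
#'   `gapCount`, `mismatchTotal`).
#' @export
plantIR <- function(x, stemLength, spacerLength = 0L, stemMismatches = 0L,
                    position = 1L, seed = NULL) {
    s <- .ingestSeqs(x)
    if (length(s) != 1L)
        stop("plantIR() expects a single background sequence")
    id <- names(s)
    s <- s[[1L]]
    stemLength <- as.integer(stemLength)
    spacerLength <- as.integer(spacerLength)
    stemMismatches <- as.integer(stemMismatches)
    position <- as.integer(position)
    stopifnot(stemLength >= 1L, spacerLength >= 0L, stemMismatches >= 0L,
              position >= 1L)
    if (stemMismatches > 0L && stemMismatches > stemLength - 2L)
        stop("need stemMismatches <= stemLength - 2 so that the outermost ",
             "and innermost stem pairs both pair")
    h <- 2L * stemLength + spacerLength
    if (position + h - 1L > nchar(s))
        stop("planted window (length ", h, ") does not fit in the sequence ",
             "at position ", position)
    w <- .withSeed(seed, {
        left <- sample(.BASES, stemLength, replace = TRUE)
        right <- unname(.COMP[rev(left)])   # right[j] pairs with left[stem+1-j]
        if (stemMismatches > 0L) {
            mmAt <- sample(2:(stemLength - 1L), stemMismatches)
            for (k in mmAt) {
                # break pair k: replace the mirrored right-half base
                right[stemLength + 1L - k] <-
                    sample(setdiff(.BASES, .COMP[left[k]]), 1L)
            }
        }
        spacer <- character(spacerLength)
        if (spacerLength > 0L) {
            for (j in seq_len(spacerLength %/% 2L)) {
                spacer[j] <- sample(.BASES, 1L)
                spacer[spacerLength + 1L - j] <-
                    sample(setdiff(.BASES, .COMP[spacer[j]]), 1L)
            }
            if (spacerLength %% 2L == 1L)
                spacer[(spacerLength + 1L) %/% 2L] <- sample(.BASES, 1L)
        }
        paste(c(left, spacer, right), collapse = "")
    })
    out <- paste0(substr(s, 1L, position - 1L), w,
                  substring(s, position + h))
    names(out) <- id
    list(seq = out,
         truth = data.frame(start = position, irLength = h,
                            mismatchStem = 2L * stemMismatches,
                            gapCount = spacerLength,
                            mismatchTotal = 2L * stemMismatches +
                                spacerLength))
}
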