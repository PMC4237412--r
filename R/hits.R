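# Assemble an IRHits object from raw detector output. `found` is a list,
# parallel to `seqs`, of data.frames with columns start, irLength,
# mismatchTotal; annotation (decomposition, structure, window sequence) is
# computed here so both detectors share it.
.buildIRHits <- function(seqs, found, params) {
    rows <- vector("list", length(seqs))
    ids <- names(seqs)
    for (i in seq_along(seqs)) {
        f <- found[[i]]
        if (is.null(f) || nrow(f) == 0L) next
        code <- .encodeDNA(seqs[[i]])
        stem <- gap <- integer(nrow(f))
        structure <- character(nrow(f))
        for (h in unique(f$irLength)) {
            j <- which(f$irLength == h)
            if (all(f$mismatchTotal[j] == 0L)) {
                stem[j] <- 0L
                gap[j] <- 0L
                structure[j] <- strrep("(", h %/% 2L)
            } else {
                d <- .decompose(code, f$start[j], h)
                stem[j] <- d$stem
                gap[j] <- d$gap
                structure[j] <- vapply(f$start[j], .dotBracket1,
                                       character(1), code = code, h = h)
            }
        }
        perf <- f$mismatchTotal == 0L
        structure[perf] <- paste0(structure[perf],
                                  strrep(")", f$irLength[perf] %/% 2L))
        rows[[i]] <- data.frame(
            seqnames = ids[i],
            start = f$start,
            irLength = f$irLength,
            mismatchStem = stem,
            gapCount = gap,
            mismatchTotal = f$mismatchTotal,
            seq = substring(seqs[[i]], f$start, f$start + f$irLength - 1L),
            structure = structure,
            stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    tab <- if (length(rows)) do.call(rbind, rows) else NULL
    if (is.null(tab))
        tab <- data.frame(seqnames = character(0), start = integer(0),
                          irLength = integer(0), mismatchStem = integer(0),
                          gapCount = integer(0), mismatchTotal = integer(0),
                          seq = character(0), structure = character(0))
    # deterministic order: input sequence order, start ascending,
    # length descending
    ord <- order(match(tab$seqnames, ids), tab$start, -tab$irLength)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    new("IRHits", hits = S4Vectors::DataFrame(tab), params = params)
}

# Drop hits fully nested (same centre) in a longer reported hit.
.maximalOnly <- function(tab) {
    if (nrow(tab) == 0L)
        return(tab)
    key <- paste(tab$seqnames, tab$start, tab$irLength)
    parent <- paste(tab$seqnames, tab$start - 1L, tab$irLength + 2L)
    tab <- tab[!(parent %in% key), , drop = FALSE]
    rownames(tab) <- NULL
    tab
}

#' @describeIn IRHits-accessors number of hits.
#' @export
setMethod("length", "IRHits", function(x) nrow(x@hits))

#' Accessors for IRHits
#'
#' Coordinates are 1-based and fully closed: `start(x)` and `end(x)` delimit
#' each hit inside its own sequence record, `width(x)` is the hit length.
#' `mismatchTotal(x)` is the total mismatch count in nucleotides,
#' `mismatchStem(x)` and `gapCount(x)` its stem/spacer decomposition,
#' `irStructure(x)` the dot-bracket strings, `irSequence(x)` the window
#' sequences, and `isPerfect(x)` flags hits with zero mismatches.
#'
#' @param x an [IRHits-class] object.
#' @name IRHits-accessors
#' @aliases start,IRHits-method end,IRHits-method width,IRHits-method
NULL

#' @rdname IRHits-accessors
#' @export
setMethod("start", "IRHits", function(x) x@hits$start)

#' @rdname IRHits-accessors
#' @export
setMethod("end", "IRHits", function(x) x@hits$start + x@hits$irLength - 1L)

#' @rdname IRHits-accessors
#' @export
setMethod("width", "IRHits", function(x) x@hits$irLength)

#' @rdname IRHits-accessors
#' @export
setMethod("mismatchTotal", "IRHits", function(x) x@hits$mismatchTotal)

#' @rdname IRHits-accessors
#' @export
setMethod("mismatchStem", "IRHits", function(x) x@hits$mismatchStem)

#' @rdname IRHits-accessors
#' @export
setMethod("gapCount", "IRHits", function(x) x@hits$gapCount)

#' @rdname IRHits-accessors
#' @export
setMethod("irStructure", "IRHits", function(x) x@hits$structure)

#' @rdname IRHits-accessors
#' @export
setMethod("irSequence", "IRHits", function(x) x@hits$seq)

#' @rdname IRHits-accessors
#' @export
setMethod("isPerfect", "IRHits", function(x) x@hits$mismatchTotal == 0L)

#' @describeIn IRHits-accessors convert to a [GenomicRanges::GRanges] with hit
#'   annotation in `mcols`.
#' @export
setMethod("asGRanges", "IRHits", function(x) {
    h <- x@hits
    gr <- GenomicRanges::GRanges(
        seqnames = if (nrow(h)) h$seqnames else character(0),
        ranges = IRanges::IRanges(start = h$start, width = h$irLength),
        strand = "+")
    S4Vectors::mcols(gr) <- h[, c("mismatchStem", "gapCount",
                                  "mismatchTotal", "seq", "structure"),
                              drop = FALSE]
    gr
})

#' @export
#' @method as.data.frame IRHits
as.data.frame.IRHits <- function(x, row.names = NULL, optional = FALSE, ...) {
    df <- as.data.frame(x@hits, row.names = row.names, optional = optional,
                        ...)
    df$end <- df$start + df$irLength - 1L
    df[, c("seqnames", "start", "end", "irLength", "mismatchStem",
           "gapCount", "mismatchTotal", "seq", "structure"), drop = FALSE]
}

setMethod("as.data.frame", "IRHits", as.data.frame.IRHits)

#' @describeIn IRHits-accessors subset hits.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "IRHits", function(x, i, j, ..., drop = FALSE) {
    new("IRHits", hits = x@hits[i, , drop = FALSE], params = x@params)
})

setMethod("show", "IRHits", function(object) {
    h <- object@hits
    p <- object@params
    mode <- if (!is.null(p$mode)) p$mode else "?"
    cat(sprintf("IRHits: %d inverted repeat%s (%s mode)\n",
                nrow(h), if (nrow(h) == 1L) "" else "s", mode))
    if (!is.null(p$minLength))
        cat(sprintf("  length range [%d, %d]%s\n", p$minLength, p$maxLength,
                    if (!is.null(p$maxMismatch))
                        sprintf(", max mismatch %d", p$maxMismatch) else ""))
    if (nrow(h)) {
        cat(sprintf("  %d sequence record(s); lengths %d-%d nt; mismatch 0-%d\n",
                    length(unique(h$seqnames)), min(h$irLength),
                    max(h$irLength), max(h$mismatchTotal)))
        df <- head(as.data.frame(object), 6L)
        df$seq <- ifelse(nchar(df$seq) > 24, paste0(substr(df$seq, 1, 21), "..."),
                         df$seq)
        df$structure <- ifelse(nchar(df$structure) > 24,
                               paste0(substr(df$structure, 1, 21), "..."),
                               df$structure)
        print(df)
        if (nrow(h) > 6L)
            cat(sprintf("  ... and %d more\n", nrow(h) - 6L))
    }
    invisible(NULL)
})
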