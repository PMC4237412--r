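# Shared test utilities.

# Canonical multiset key for hit tables, for exact set comparisons.
hitKey <- function(df, mismatch = FALSE) {
    if (nrow(df) == 0L)
        return(character(0))
    k <- paste(df$seqnames, df$start, df$irLength)
    if (mismatch)
        k <- paste(k, df$mismatchTotal)
    sort(k)
}

# Naive per-window complex score by direct summation, independent of the
# prefix-sum path.
naiveWindowScores <- function(s, h) {
    m <- mapBases(s)
    n <- length(m@scores)
    vapply(seq_len(n - h + 1L),
           function(i) sum(m@scores[i:(i + h - 1L)]),
           complex(1))
}

# Random ACGT-only sequence via the package generator (unnamed string).
rdna <- function(n, gc = 0.5) unname(randomDna(n, gc))

TOY20 <- "ATCGAACGAATTCGTTAACC"
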