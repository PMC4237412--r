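test_that("a zero window score is necessary but not sufficient", {
    # 'TACG' scores 0 yet is not a palindrome (T/G ends): nominated as a
    # candidate, rejected by pairing validation
    expect_equal(windowScores(cumulativeScore(mapBases("TACG")), 4), 0 + 0i)
    expect_length(findPerfectIRs("TACG", 4, 4), 0L)
    # every reported hit scores exactly zero
    set.seed(11)
    s <- rdna(400)
    hits <- as.data.frame(findPerfectIRs(s, 4, 12))
    V <- cumulativeScore(mapBases(s))
    for (h in unique(hits$irLength)) {
        C <- windowScores(V, h)
        expect_true(all(C[hits$start[hits$irLength == h]] == 0 + 0i))
    }
})

test_that("the toy 20-mer yields its full nested family of perfect IRs", {
    hits <- as.data.frame(findPerfectIRs(TOY20, minLength = 4,
                                         maxLength = 20))
    expect_identical(nrow(hits), 8L)
    expect_identical(
        hitKey(hits),
        sort(paste("seq1",
                   c(2L, 9L, 15L, 8L, 14L, 7L, 6L, 5L),
                   c(4L, 4L, 4L, 6L, 6L, 8L, 10L, 12L))))
    expect_true(all(hits$mismatchTotal == 0L))
    expect_true(all(hits$gapCount == 0L))
    # one-base-per-end extension: the length-8 hit at 7 grows to (6, 10),
    # while the length-4 hit at 2 does not grow (A/A would-be ends)
    expect_true("seq1 6 10" %in% hitKey(hits))
    expect_false("seq1 1 6" %in% hitKey(hits))
})

test_that("maximalOnly keeps exactly the longest hit of each centre", {
    hits <- as.data.frame(findPerfectIRs(TOY20, 4, 20, maximalOnly = TRUE))
    expect_identical(hitKey(hits),
                     sort(paste("seq1", c(2L, 5L, 14L), c(4L, 12L, 6L))))
})

test_that("sequences that cannot pair yield nothing", {
    expect_length(findPerfectIRs("AAAAAAAA", 4, 8), 0L)
    # ambiguous bases never pair, even inside an otherwise perfect palindrome
    expect_length(findPerfectIRs("GANTC", 4, 4), 0L)
    expect_identical(hitKey(as.data.frame(findPerfectIRs("AATTNGGATCC",
                                                          4, 10))),
                     c("seq1 1 4", "seq1 6 6", "seq1 7 4"))
})

test_that("every longer perfect hit contains its same-centre nested hit", {
    set.seed(22)
    for (rep in 1:5) {
        s <- rdna(sample(100:500, 1))
        hits <- as.data.frame(findPerfectIRs(s, 4, 20))
        key <- hitKey(hits)
        longer <- hits[hits$irLength > 4L, , drop = FALSE]
        if (nrow(longer))
            expect_true(all(paste(longer$seqnames, longer$start + 1L,
                                  longer$irLength - 2L) %in% key))
    }
})

test_that("perfect detector matches the brute-force oracle exactly", {
    # EcoRI site: the 6-mer and its nested 4-mer
    ecoRI <- bruteForcePerfectIRs("GAATTC", 4, 6)
    expect_identical(hitKey(ecoRI), c("seq1 1 6", "seq1 2 4"))
    expect_identical(hitKey(as.data.frame(findPerfectIRs("GAATTC", 4, 6))),
                     hitKey(ecoRI))
    set.seed(33)
    for (rep in 1:12) {
        n <- sample(80:1200, 1)
        s <- rdna(n, runif(1, 0.2, 0.8))
        l <- sample(c(4L, 6L, 10L), 1)
        L <- min(n, l + 2L * sample(4:12, 1))
        if (L %% 2L == 1L) L <- L - 1L
        got <- as.data.frame(findPerfectIRs(s, l, L))
        want <- bruteForcePerfectIRs(s, l, L)
        expect_identical(hitKey(got), hitKey(want))
    }
})

test_that("planted palindromes are recovered at their coordinates", {
    set.seed(44)
    for (rep in 1:8) {
        stem <- sample(5:12, 1)
        pos <- sample(5:150, 1)
        pl <- plantIR(rdna(300), stemLength = stem, spacerLength = 0,
                      stemMismatches = 0, position = pos)
        hits <- as.data.frame(findPerfectIRs(pl$seq, 4, 2L * stem))
        expect_true(paste("seq1", pos, 2L * stem) %in% hitKey(hits))
    }
})

test_that("multi-record input is scanned per record with own coordinates", {
    x <- Biostrings::DNAStringSet(c(chrA = "GGGAATTGGG",
                                    chrB = "TTGAATTCTT"))
    hits <- as.data.frame(findPerfectIRs(x, 4, 8))
    expect_identical(hitKey(hits),
                     sort(c("chrA 4 4", "chrB 3 6", "chrB 4 4")))
})

test_that("perfect-mode parameters are validated", {
    expect_error(findPerfectIRs(TOY20, 5, 10), "even")
    expect_error(findPerfectIRs(TOY20, 4, 9), "even")
    expect_error(findPerfectIRs(TOY20, 12, 10), "minLength <= maxLength")
    expect_error(findPerfectIRs(TOY20, 4, 22), "exceeds sequence length")
})
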