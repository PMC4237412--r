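test_that("mismatch counting matches the worked quasipalindromes", {
    expect_identical(mismatchCount("AACAACTTTCTT", 1, 12), 4L)
    expect_identical(mismatchCount("CAAAAATTTTG", 1, 11), 1L)
    expect_identical(mismatchCount("ATCAGATGCTAAAGCATATGAT", 1, 22), 4L)
    expect_identical(mismatchCount("GAATTC", 1, 6), 0L)
    expect_identical(mismatchCount("AAAAATTTCT", 1, 10), 2L)
    expect_identical(mismatchCount("AAAATTTC", 1, 8), 2L)
    expect_error(mismatchCount("AANTT", 1, 5), "non-ACGT")
    expect_error(mismatchCount("AATT", 2, 4), "bounds")
})

test_that("score bound admits exactly the windows it should", {
    # 'AACAACTTTCTT' scores -1+3i: bound 4, so admitted at m = 4 and
    # rejected at m <= 3 before any pairing work
    expect_identical(
        hitKey(as.data.frame(findImperfectIRs("AACAACTTTCTT", 12, 12, 4)),
               mismatch = TRUE),
        "seq1 1 12 4")
    expect_length(findImperfectIRs("AACAACTTTCTT", 12, 12, 2), 0L)
    expect_length(findImperfectIRs("AACAACTTTCTT", 12, 12, 3), 0L)
})

test_that("reporting needs pairing ends and a non-zero mismatch count", {
    # 'AAAAATTTCT': 2 mismatches, A/T ends -> reported
    expect_identical(
        hitKey(as.data.frame(findImperfectIRs("AAAAATTTCT", 10, 10, 2)),
               mismatch = TRUE),
        "seq1 1 10 2")
    # 'AAAATTTC': 2 mismatches but A/C ends -> not reported at its own length
    expect_length(findImperfectIRs("AAAATTTC", 8, 8, 2), 0L)
    # ... yet carried: one extension later it becomes the reported 10-mer
    hits <- as.data.frame(findImperfectIRs("AAAAATTTCT", 8, 10, 2))
    expect_true("seq1 1 10 2" %in% hitKey(hits, mismatch = TRUE))
    expect_false("seq1 2 8" %in% hitKey(hits))
    # perfect palindromes are never imperfect hits
    expect_length(findImperfectIRs("GAATTC", 6, 6, 6), 0L)
})

test_that("windows flush against a sequence end are not extended", {
    # 'AATTTC' (start 1) has 2 mismatches and would extend only leftward of
    # position 1; no hit longer than the seed can start at position 0
    hits <- as.data.frame(findImperfectIRs("AATTTCGG", 6, 8, 4))
    expect_true(all(hits$start >= 1L))
    expect_true(all(hits$start + hits$irLength - 1L <= 8L))
})

test_that("extension onto an ambiguous base disqualifies the window", {
    # NAATTN: the inner AATT is perfect (not reportable); growing it would
    # put N at both ends
    expect_length(findImperfectIRs("NAATTN", 4, 6, 6), 0L)
    # NAACAACTTTCTTN: the 12-mer hit is still found, but nothing longer
    hits <- as.data.frame(findImperfectIRs("NAACAACTTTCTTN", 12, 14, 6))
    expect_identical(hitKey(hits, mismatch = TRUE), "seq1 2 12 4")
})

test_that("imperfect detector matches the brute-force oracle exactly", {
    set.seed(55)
    for (rep in 1:12) {
        n <- sample(80:1200, 1)
        s <- rdna(n, runif(1, 0.2, 0.8))
        l <- sample(c(6L, 10L, 12L), 1)
        L <- min(n, l + sample(5:18, 1))
        m <- sample(c(2L, 4L, 6L, 7L), 1)
        got <- as.data.frame(findImperfectIRs(s, l, L, m))
        want <- bruteForceImperfectIRs(s, l, L, m)
        expect_identical(hitKey(got, mismatch = TRUE),
                         hitKey(want, mismatch = TRUE))
    }
})

test_that("reported mismatch totals agree with recomputation from scratch", {
    set.seed(66)
    s <- rdna(800)
    hits <- as.data.frame(findImperfectIRs(s, 8, 24, 7))
    expect_gt(nrow(hits), 0L)
    expect_identical(hits$mismatchTotal,
                     mismatchCount(s, hits$start, hits$irLength))
})

test_that("mismatch totals share the parity of the hit length", {
    set.seed(77)
    s <- rdna(1000)
    hits <- as.data.frame(findImperfectIRs(s, 7, 20, 7))
    expect_gt(nrow(hits), 0L)
    expect_true(any(hits$irLength %% 2L == 1L))
    expect_true(any(hits$irLength %% 2L == 0L))
    expect_identical(hits$mismatchTotal %% 2L, hits$irLength %% 2L)
})

test_that("perfect and imperfect outputs never overlap", {
    set.seed(88)
    for (rep in 1:4) {
        s <- rdna(600)
        p <- as.data.frame(findPerfectIRs(s, 6, 20))
        i <- as.data.frame(findImperfectIRs(s, 6, 20, 6))
        expect_length(intersect(hitKey(p), hitKey(i)), 0L)
    }
})

test_that("imperfect-mode parameters are validated", {
    expect_error(findImperfectIRs(TOY20, 10, 20, 0), "maxMismatch")
    expect_error(findImperfectIRs(TOY20, 21, 20, 6), "minLength <= maxLength")
    expect_error(findImperfectIRs(TOY20, 10, 30, 6),
                 "exceeds sequence length")
})

test_that("both-mode wrapper concatenates disjoint hit sets", {
    set.seed(99)
    s <- rdna(500)
    both <- as.data.frame(findInvertedRepeats(s, mode = "both",
                                              minLength = 8,
                                              maxLength = 20,
                                              maxMismatch = 4))
    p <- as.data.frame(findPerfectIRs(s, 8, 20))
    i <- as.data.frame(findImperfectIRs(s, 8, 20, 4))
    expect_identical(hitKey(both), sort(c(hitKey(p), hitKey(i))))
})
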