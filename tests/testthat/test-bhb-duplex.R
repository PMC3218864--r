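test_that("maxDuplex finds exact complements and is symmetric", {
    a <- "GGAACCGGTTACC"
    expect_equal(maxDuplex(a, revComp(a))$len, 13L)
    expect_equal(maxDuplex("AAAA", "CCCC")$len, 0L)
    set.seed(41)
    for (i in 1:60) {
        a <- randSeq(sample(10:60, 1))
        b <- randSeq(sample(10:60, 1))
        f <- maxDuplex(a, b)$len
        expect_equal(f, maxDuplex(b, a)$len)
        expect_equal(f, oracleMaxDuplex(a, b))
    }
})

test_that("maxDuplex reports usable duplex coordinates", {
    set.seed(42)
    stem <- randSeq(12, gc = 0.9)
    a <- paste0(randSeq(9), stem, randSeq(7))
    b <- paste0(randSeq(5), revComp(stem), randSeq(11))
    d <- maxDuplex(a, b)
    expect_gte(d$len, 12L)
    ## reported regions must actually pair antiparallel
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    for (t in 0:(d$len - 1L)) {
        expect_true(oraclePairable(va[d$aStart + t], vb[d$bEnd - t]))
    }
    expect_equal(maxDuplex(stem, revComp(stem), wcOnly = TRUE)$len, 12L)
    expect_error(maxDuplex("", "ACGT"), "empty")
})

test_that("findBhb recovers a designed canonical junction and rejects poly-A", {
    set.seed(43)
    for (i in 1:10) {
        ## build a canonical hBHBh' by construction
        h <- randSeq(5, gc = 0.8)        # outer helix (h)
        H <- randSeq(4, gc = 0.8)        # central helix
        hp <- randSeq(4, gc = 0.8)       # h' helix
        b1 <- "AAA"; b2 <- "AAA"
        ctx1 <- paste0(randSeq(6), h, b1, H, hp, randSeq(6))
        ctx2 <- paste0(randSeq(6), revComp(hp), b2, revComp(H),
                       revComp(h), randSeq(6))
        site1 <- 6 + 5 + 2                # cut inside bulge1
        site2 <- 6 + 4 + 2                # cut inside bulge2
        m <- findBhb(ctx1, site1, ctx2, site2)
        expect_gt(nrow(m), 0)
        expect_true(any(m$strictness == "canonical_hBHBh" &
                        m$central == 4 & m$bulge1 == 3 & m$bulge2 == 3))
    }
    empty <- findBhb(strrep("A", 30), 15, strrep("A", 30), 15)
    expect_equal(nrow(empty), 0L)
    expect_error(findBhb("ACGT", 2, strrep("A", 30), 15), "15 nt")
})

test_that("findBhb agrees with exhaustive enumeration on random contexts", {
    set.seed(44)
    for (i in 1:150) {
        n1 <- sample(15:40, 1); n2 <- sample(15:40, 1)
        ctx1 <- randSeq(n1, gc = 0.6); ctx2 <- randSeq(n2, gc = 0.6)
        s1 <- sample(5:(n1 - 5), 1); s2 <- sample(5:(n2 - 5), 1)
        got <- findBhb(ctx1, s1, ctx2, s2)
        want <- oracleBhb(ctx1, s1, ctx2, s2)
        expect_equal(bhbKey(got), bhbKey(want))
    }
})
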