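test_that("FASTA reading normalizes records and preserves order", {
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">x", "ACGT"), fa)
    s <- readGenomeFasta(fa)
    expect_length(s, 1L)
    expect_equal(as.character(s[[1]]), "ACGT")

    writeLines(c(">u_rec", "acgu", "UUga"), fa)
    s <- readGenomeFasta(fa)
    expect_equal(as.character(s[[1]]), "ACGTTTGA")

    set.seed(11)
    recs <- replicate(3, randSeq(120))
    writeLines(c(rbind(paste0(">rec", 1:3, " some description"), recs)), fa)
    s <- readGenomeFasta(fa)
    oracle <- oracleReadFasta(fa)
    expect_equal(names(s), names(oracle))
    expect_equal(unname(as.character(s)), unname(oracle))

    writeLines(c(">a", "ACGT", ">empty", "", ">b", "AC"), fa)
    expect_error(readGenomeFasta(fa), "empty")
})

test_that("interval extraction is strand-aware and bounds-checked", {
    g <- Biostrings::DNAStringSet(c(chr = "ACGTT"))
    plus <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 4), "+")
    minus <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 4), "-")
    expect_equal(extractInterval(g, plus), "ACGT")
    expect_equal(extractInterval(g, minus), "ACGT")  # palindrome
    oob <- GenomicRanges::GRanges("chr", IRanges::IRanges(3, 9), "+")
    expect_error(extractInterval(g, oob), "out of bounds")
    expect_equal(extractInterval(g, oob, circular = TRUE), "GTTACGT")

    set.seed(2)
    s <- randSeq(100)
    g2 <- Biostrings::DNAStringSet(c(chr = s))
    for (i in 1:25) {
        a <- sample(1:90, 1); b <- a + sample(1:9, 1)
        fwd <- extractInterval(g2, GenomicRanges::GRanges(
            "chr", IRanges::IRanges(a, b), "+"))
        rev <- extractInterval(g2, GenomicRanges::GRanges(
            "chr", IRanges::IRanges(a, b), "-"))
        expect_equal(fwd, substr(s, a, b))
        expect_equal(rev, oracleRevComp(substr(s, a, b)))
    }
})

test_that("reverse complement is an involution", {
    set.seed(3)
    for (i in 1:20) {
        s <- randSeq(sample(5:80, 1))
        expect_equal(revComp(revComp(s)), s)
    }
})

test_that("Markov training recovers conditional probabilities", {
    bg0 <- suppressWarnings(trainMarkov("AAAAAA", order = 0))
    expect_gt(markovProb(bg0)[1, 1], 0.8)
    expect_equal(sum(markovProb(bg0)), 1)

    bg1 <- suppressWarnings(trainMarkov(strrep("AC", 40), order = 1))
    p <- markovProb(bg1)
    expect_gt(p[1, 2], 0.95)   # P(C | A)
    expect_gt(p[2, 1], 0.95)   # P(A | C)

    ## order-5 estimates match direct 6-mer count ratios on 100 kb
    set.seed(4)
    s <- randSeq(100000, gc = 0.6)
    bg5 <- trainMarkov(s, order = 5, pseudocount = 0.25)
    kmers <- substring(s, 1:(nchar(s) - 5L), 6:nchar(s))
    lv6 <- do.call(paste0, expand.grid(rep(list(.B), 6))[, 6:1])
    cnt <- table(factor(kmers, levels = sort(lv6)))
    mat <- matrix(as.numeric(cnt), ncol = 4, byrow = TRUE) + 0.25
    expect_equal(unname(markovProb(bg5)), unname(mat / rowSums(mat)),
                 tolerance = 1e-12)
    expect_true(all(abs(rowSums(markovProb(bg5)) - 1) < 1e-9))
    expect_error(trainMarkov("ACGT", order = -1), "order")
})

test_that("virtual genome sampling is deterministic and follows the chain", {
    ## with a vanishing pseudocount the estimated transitions are
    ## effectively deterministic, so the sample must alternate A/C
    bg1 <- suppressWarnings(trainMarkov(strrep("AC", 40), order = 1,
                                        pseudocount = 1e-9))
    v1 <- sampleVirtualGenome(bg1, 500, seed = 9, as = "character")
    v2 <- sampleVirtualGenome(bg1, 500, seed = 9, as = "character")
    expect_identical(v1, v2)
    body <- substr(v1, 2, 500)
    expect_false(grepl("AA|CC|G|T", body))

    bgU <- uniformBackground(0.5)
    x <- sampleVirtualGenome(bgU, 2000, seed = 1, as = "character")
    expect_equal(nchar(x), 2000)
    expect_false(grepl("N", x))
})

test_that("substitution counting matches a Needleman-Wunsch oracle", {
    expect_equal(as.integer(countSubstitutions("ACGT", "ACGT")), 0L)
    expect_error(countSubstitutions("", "ACGT"), "empty")
    set.seed(5)
    for (i in 1:20) {
        a <- randSeq(70)
        k <- sample(0:5, 1)
        pos <- sample(70, k)
        bv <- strsplit(a, "")[[1]]
        for (p in pos) bv[p] <- sample(setdiff(.B, bv[p]), 1)
        b <- paste(bv, collapse = "")
        expect_equal(as.integer(countSubstitutions(a, b)), k)
        expect_equal(oracleSubstitutions(a, b), k)
    }
    ## an indel is reported separately, not as substitutions
    res <- countSubstitutions("ACGTACGTAC", "ACGTCGTAC")
    expect_equal(attr(res, "indels"), 1L)
})
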