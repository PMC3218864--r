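test_that("joinSplit inverts cutTrna at every enumerable junction", {
    t <- makeTrnaSequence("GTC", seed = 201)
    for (a in 8:59) {
        fr <- cutTrna(t$seq, t$structure, a)
        expect_equal(joinSplit(fr$five, fr$three), t$seq)
    }
    fr <- cutTrna(t$seq, t$structure, "37/38")
    expect_equal(nchar(fr$five$seq), 37L)
    expect_error(joinSplit(fr$five, fr$five), "five_prime")
    fr2 <- cutTrna(t$seq, t$structure, 30)
    expect_error(joinSplit(fr$five, fr2$three), "gap or overlap")
})

test_that("cis intron span measures the implied read-through intron", {
    five <- list(start = 1000L, end = 1036L, strand = "+")
    three <- list(start = 1158L, end = 1196L, strand = "+")
    expect_equal(cisIntronSpan(five, three), 121L)
    ## overlap or wrong strand is not applicable
    expect_true(is.na(cisIntronSpan(three, five)))
    expect_true(is.na(cisIntronSpan(five, list(start = 1158L, end = 1196L,
                                               strand = "-"))))
    ## minus-strand pair
    f2 <- list(start = 5000L, end = 5036L, strand = "-")
    t2 <- list(start = 4800L, end = 4838L, strand = "-")
    expect_equal(cisIntronSpan(f2, t2), 161L)
})

test_that("intron classification separates canonical from noncanonical", {
    set.seed(202)
    blk <- plantStandard("GAA", intronLen = 20L)
    genome <- Biostrings::DNAStringSet(c(syn = paste0(
        randSeq(700), trnarr:::intToDna(blk$block), randSeq(700))))
    scan <- scanGenome(genome, runConfig(), seqid = "syn")
    calls <- classifyIntron(scan$genes[1], genome)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$class, "canonical")
    expect_equal(calls$length, 20L)
    expect_false(is.na(calls$bhbClass))

    ## a constructed gene with an insert at 32/33 is noncanonical
    t <- makeTrnaSequence("GTC", seed = 203)
    i32 <- posOfSprinzl(t$structure, 32)
    pre <- paste0(substr(t$seq, 1, i32), randSeq(18),
                  substr(t$seq, i32 + 1, nchar(t$seq)))
    calls2 <- classifyIntron(list(precursor = pre, exon1Len = i32,
                                  intronLen = 18L, sprinzl = "32/33"))
    expect_equal(calls2$class, "noncanonical")
    ## intronless gene yields no calls
    sim <- generateGenome(plantConfig(genomeLength = 30000, nStandard = 1,
                                      nSplit = 0L, nPermuted = 0L, nCds = 2L,
                                      seed = 204))
    scan2 <- scanGenome(sim$genome, runConfig(), seqid = "synthetic")
    expect_equal(nrow(classifyIntron(scan2$genes[1], sim$genome)), 0L)
})

test_that("orphan trans-pairing search reconstructs planted split pairs", {
    for (cfg in list(list(j = 30L, stem = 13L, o = "distant"),
                     list(j = 37L, stem = 14L, o = "convergent"))) {
        set.seed(210 + cfg$j)
        blk <- plantSplit("CTT", junction = cfg$j, stem = cfg$stem,
                          orientation = cfg$o)
        genome <- Biostrings::DNAStringSet(c(syn = paste0(
            randSeq(800), trnarr:::intToDna(blk$block), randSeq(800))))
        scan <- scanGenome(genome, runConfig(), seqid = "syn")
        cand <- searchSplitPartners(scan$fragments, genome[[1]], runConfig())
        cand <- as.data.frame(cand)
        expect_equal(nrow(cand), 1L)
        expect_equal(cand$junction, paste0(cfg$j, "/", cfg$j + 1L))
        expect_gte(cand$stemLen, cfg$stem)
        expect_equal(cand$bhbClass, "canonical_hBHBh")
        expect_gte(cand$joinedScore, 20)
        tr <- blk$truth
        expect_equal(cand$fiveStart, tr$fiveStart + 800L)
        expect_equal(cand$threeStart, tr$threeStart + 800L)
        ## "distant" is a same-strand arrangement with a large separation
        if (cfg$o == "distant") {
            expect_equal(cand$orientation, "same_strand")
            expect_gte(cand$separation, 4000L)
        } else {
            expect_equal(cand$orientation, cfg$o)
        }
    }
})

test_that("no partner means no split candidate", {
    ## plant only the 3'-half cassette (the 5' half is absent)
    set.seed(220)
    blk <- plantSplit("CTT", junction = 30L, stem = 13L,
                      orientation = "distant")
    tr <- blk$truth
    threeCassette <- blk$block[(tr$threeStart - 60L):length(blk$block)]
    genome <- Biostrings::DNAStringSet(c(syn = paste0(
        randSeq(900), trnarr:::intToDna(threeCassette), randSeq(900))))
    scan <- scanGenome(genome, runConfig(), seqid = "syn")
    cand <- searchSplitPartners(scan$fragments, genome[[1]], runConfig())
    expect_equal(nrow(cand), 0L)
})
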