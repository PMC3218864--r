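test_that("planted intronless tRNAs are recovered exactly with no false calls", {
    sim <- generateGenome(plantConfig(genomeLength = 90000, nStandard = 8,
                                      nSplit = 0L, nPermuted = 0L,
                                      nCds = 6L, seed = 101))
    scan <- scanGenome(sim$genome, runConfig(), seqid = "synthetic")
    g <- as.data.frame(scan$genes)
    std <- sim$truth[sim$truth$class == "standard", ]
    expect_equal(nrow(g), nrow(std))
    expect_setequal(g$start, std$fiveStart)
    expect_setequal(g$end, std$fiveEnd)
    key <- paste(g$start, g$strand)
    tkey <- paste(std$fiveStart, std$fiveStrand)
    expect_setequal(key, tkey)
    ## isotype/anticodon agree with the planted genes
    m <- match(g$start, std$fiveStart)
    expect_equal(g$anticodon, std$anticodon[m])
    expect_true(all(g$score >= 20))
})

test_that("canonical introns at 37/38 are detected with their length", {
    set.seed(102)
    blk <- plantStandard("GAA", intronLen = 20L)
    genome <- Biostrings::DNAStringSet(c(syn = paste0(
        randSeq(700), trnarr:::intToDna(blk$block), randSeq(700))))
    scan <- scanGenome(genome, runConfig(), seqid = "syn")
    g <- as.data.frame(scan$genes)
    expect_equal(nrow(g), 1L)
    expect_equal(g$intronLen, 20L)
    expect_equal(g$intronSprinzl, "37/38")
    expect_false(is.na(g$bhbClass))
    ## mature sequence excludes the intron and still folds
    st <- foldCloverleaf(g$matureSeq)
    expect_gte(structureScore(st), 20)
})

test_that("detection is strand-symmetric", {
    sim <- generateGenome(plantConfig(genomeLength = 60000, nStandard = 5,
                                      nSplit = 0L, nPermuted = 0L,
                                      nCds = 4L, seed = 103))
    fwd <- scanGenome(sim$genome, runConfig(), seqid = "syn")
    rc <- Biostrings::DNAStringSet(
        c(syn = revComp(as.character(sim$genome[[1]]))))
    bwd <- scanGenome(rc, runConfig(), seqid = "syn")
    n <- length(sim$genome[[1]])
    gf <- as.data.frame(fwd$genes)
    gb <- as.data.frame(bwd$genes)
    expect_equal(nrow(gf), nrow(gb))
    ## mirrored coordinates and flipped strands
    mapped <- data.frame(start = n - gb$end + 1L, end = n - gb$start + 1L,
                         strand = ifelse(gb$strand == "+", "-", "+"))
    expect_setequal(paste(gf$start, gf$end, gf$strand),
                    paste(mapped$start, mapped$end, mapped$strand))
    expect_setequal(round(gf$score, 6), round(gb$score, 6))
})

test_that("reported genes re-fold to the same structure from their mature sequence", {
    sim <- generateGenome(plantConfig(genomeLength = 60000, nStandard = 5,
                                      nSplit = 0L, nPermuted = 0L,
                                      nCds = 4L, seed = 104))
    scan <- scanGenome(sim$genome, runConfig(), seqid = "syn")
    g <- as.data.frame(scan$genes)
    for (i in seq_len(nrow(g))) {
        st <- foldCloverleaf(g$matureSeq[i])
        expect_false(is.null(st))
        expect_equal(c(st@d, st@dloop, st@varlen, st@cca),
                     c(g$d[i], g$dl[i], g$v[i], g$cca[i]))
        expect_equal(structureScore(st), g$score[i])
    }
})
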