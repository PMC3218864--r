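test_that("a planted permuted gene is recovered at its exact junction", {
    set.seed(301)
    blk <- plantPermuted("CAT", junction = 59L, intervening = 7L)
    genome <- Biostrings::DNAStringSet(c(syn = paste0(
        randSeq(600), trnarr:::intToDna(blk$block), randSeq(600))))
    scan <- scanGenome(genome, runConfig(), seqid = "syn")
    fr <- as.data.frame(scan$fragments)
    expect_true(any(fr$kind == "five_prime"))
    tr <- blk$truth
    i5 <- which(fr$kind == "five_prime")[1]
    expect_equal(fr$start[i5], tr$fiveStart + 600L)
    ## feed the known outlier offset (promoter at block start)
    prOff <- blk$promoters$offset[1]
    out <- data.frame(geneId = paste0("frag", seq_len(nrow(fr))),
                      offset = NA_integer_, outlier = FALSE)
    out$offset[i5] <- prOff
    out$outlier[i5] <- TRUE
    cand <- as.data.frame(detectPermuted(scan$fragments, out, genome[[1]],
                                         runConfig()))
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$junction, "59/60")
    expect_equal(cand$intervening, 7L)
    expect_false(cand$intronPresent)
    expect_equal(cand$bhbClass, "canonical_hBHBh")
    expect_equal(cand$fiveStart, tr$fiveStart + 600L)
    expect_equal(cand$threeStart, tr$threeStart + 600L)
    expect_equal(cand$isotype, "iMet")
})

test_that("permuted genes with a canonical intron are flagged as such", {
    set.seed(302)
    blk <- plantPermuted("GTA", junction = 59L, intervening = 1L,
                         intronLen = 15L)
    genome <- Biostrings::DNAStringSet(c(syn = paste0(
        randSeq(600), trnarr:::intToDna(blk$block), randSeq(600))))
    scan <- scanGenome(genome, runConfig(), seqid = "syn")
    fr <- as.data.frame(scan$fragments)
    i5 <- which(fr$kind == "five_prime")
    expect_length(i5, 1L)
    expect_equal(fr$intronLen[i5], 15L)
    out <- data.frame(geneId = paste0("frag", seq_len(nrow(fr))),
                      offset = NA_integer_, outlier = FALSE)
    out$offset[i5] <- blk$promoters$offset[1]
    out$outlier[i5] <- TRUE
    cand <- as.data.frame(detectPermuted(scan$fragments, out, genome[[1]],
                                         runConfig()))
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$junction, "59/60")
    expect_equal(cand$intervening, 1L)
    expect_true(cand$intronPresent)
    expect_equal(cand$intronSprinzl, "37/38")
    expect_equal(cand$isotype, "Tyr")
})

test_that("no spacing outliers means no permuted candidates", {
    sim <- generateGenome(plantConfig(genomeLength = 60000, nStandard = 5,
                                      nSplit = 0L, nPermuted = 0L,
                                      nCds = 4L, seed = 303))
    scan <- scanGenome(sim$genome, runConfig(), seqid = "synthetic")
    out <- data.frame(geneId = character(0), offset = integer(0),
                      outlier = logical(0))
    cand <- detectPermuted(scan$fragments, out, sim$genome[[1]], runConfig())
    expect_equal(nrow(cand), 0L)
})
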