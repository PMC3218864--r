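test_that("designed tRNA sequences are self-consistent and score above cutoff", {
    set.seed(501)
    for (i in 1:25) {
        ac <- sample(c("GTC", "CTT", "GAA", "CAT", "TGC", "GTA"), 1)
        t <- makeTrnaSequence(ac, gcBias = runif(1, 0.4, 0.9))
        expect_gte(structureScore(t$structure), 20)
        st <- foldCloverleaf(t$seq)
        expect_equal(st@d, t$structure@d)
        expect_equal(st@varlen, t$structure@varlen)
        i34 <- posOfSprinzl(t$structure, 34)
        expect_equal(substr(t$seq, i34, i34 + 2), ac)
    }
    ## gcBias 1 forces all-G/C stem pairs
    t <- makeTrnaSequence("GTC", seed = 502, gcBias = 1)
    pr <- structurePairs(t$structure)
    v <- strsplit(t$seq, "")[[1]]
    ## non-conserved stem positions must be G or C on both strands
    cons <- c(1, 49, 53, 61, 65)  # positions constrained by the consensus
    free <- setdiff(seq_len(nrow(pr)),
                    which(pr[, 1] %in% cons | pr[, 2] %in% cons))
    gcOnly <- vapply(free, function(r)
        all(v[pr[r, ]] %in% c("G", "C")), TRUE)
    expect_true(all(gcOnly))
})

test_that("truth records are consistent with the emitted genome", {
    sim <- generateGenome(plantConfig(genomeLength = 150000, nStandard = 8,
                                      nSplit = 2L, nPermuted = 1L,
                                      nCds = 10L, seed = 503))
    tr <- sim$truth
    g <- sim$genome
    ## standard genes: locus sequence equals the recorded gene body
    std <- tr[tr$class == "standard" & tr$intronLen == 0, ]
    for (i in seq_len(nrow(std))) {
        got <- extractInterval(g, GenomicRanges::GRanges(
            "synthetic", IRanges::IRanges(std$fiveStart[i], std$fiveEnd[i]),
            std$fiveStrand[i]))
        expect_equal(got, std$matureSeq[i])
    }
    ## split halves: extracting and joining both exon loci reproduces the
    ## recorded mature sequence
    sp <- tr[tr$class == "split", ]
    for (i in seq_len(nrow(sp))) {
        five <- extractInterval(g, GenomicRanges::GRanges(
            "synthetic", IRanges::IRanges(sp$fiveStart[i], sp$fiveEnd[i]),
            sp$fiveStrand[i]))
        three <- extractInterval(g, GenomicRanges::GRanges(
            "synthetic", IRanges::IRanges(sp$threeStart[i], sp$threeEnd[i]),
            sp$threeStrand[i]))
        expect_equal(paste0(five, three), sp$matureSeq[i])
    }
    ## permuted: 3' part upstream of 5' part on the same strand
    pm <- tr[tr$class == "permuted", ]
    five <- extractInterval(g, GenomicRanges::GRanges(
        "synthetic", IRanges::IRanges(pm$fiveStart, pm$fiveEnd),
        pm$fiveStrand))
    three <- extractInterval(g, GenomicRanges::GRanges(
        "synthetic", IRanges::IRanges(pm$threeStart, pm$threeEnd),
        pm$threeStrand))
    expect_equal(paste0(five, three), pm$matureSeq)
    expect_equal(pm$fiveStrand, pm$threeStrand)
})

test_that("planted features never overlap and respect minimum spacing", {
    sim <- generateGenome(plantConfig(genomeLength = 150000, nStandard = 8,
                                      nSplit = 2L, nPermuted = 1L,
                                      nCds = 10L, seed = 504,
                                      minSpacing = 500L))
    tr <- sim$truth
    iv <- rbind(
        data.frame(s = tr$fiveStart, e = tr$fiveEnd, id = tr$id),
        data.frame(s = tr$threeStart, e = tr$threeEnd, id = tr$id))
    iv <- iv[!is.na(iv$s), ]
    iv <- iv[order(iv$s), ]
    same <- sub("b$", "", iv$id)
    for (k in seq_len(nrow(iv) - 1L)) {
        if (same[k] == same[k + 1L]) next   # parts of one feature block
        expect_gte(iv$s[k + 1L], iv$e[k] + 1L)
    }
})

test_that("generation is deterministic for a fixed seed", {
    cfg <- plantConfig(genomeLength = 50000, nStandard = 3, nSplit = 1L,
                       nPermuted = 1L, nCds = 5L, seed = 505)
    a <- generateGenome(cfg)
    b <- generateGenome(cfg)
    expect_identical(as.character(a$genome[[1]]), as.character(b$genome[[1]]))
    expect_identical(a$truth, b$truth)
    expect_identical(a$promoters, b$promoters)
    c2 <- generateGenome(plantConfig(genomeLength = 50000, nStandard = 3,
                                     nSplit = 1L, nPermuted = 1L, nCds = 5L,
                                     seed = 506))
    expect_false(identical(as.character(a$genome[[1]]),
                           as.character(c2$genome[[1]])))
})

test_that("written outputs are plain-text and re-readable", {
    sim <- generateGenome(plantConfig(genomeLength = 40000, nStandard = 2,
                                      nSplit = 1L, nPermuted = 0L,
                                      nCds = 4L, seed = 507))
    dir <- tempfile("simout")
    paths <- writeSyntheticGenome(sim, dir)
    expect_true(all(file.exists(file.path(dir, c("genome.fa", "truth.tsv",
                                                 "truth.json",
                                                 "annotations.gff3")))))
    back <- readGenomeFasta(file.path(dir, "genome.fa"))
    expect_equal(as.character(back[[1]]), as.character(sim$genome[[1]]))
    ann <- readAnnotations(file.path(dir, "annotations.gff3"))
    expect_equal(length(ann), sum(sim$truth$class == "cds"))
})

test_that("an infeasible packing is rejected", {
    expect_error(generateGenome(plantConfig(genomeLength = 5000,
                                            nStandard = 10, nCds = 10,
                                            seed = 508)),
                 "infeasible")
})

test_that("background composition follows the configured Markov model", {
    ## featureless genome sampled from an order-5 background trained on a
    ## structured source; the chain preserves (order+1)-mer composition,
    ## so 6-mer counts of source and sample must be homogeneous
    set.seed(509)
    src <- paste(sample(c("AAC", "ACG", "GGT", "TTA", "CGC"), 80000,
                        replace = TRUE, prob = c(.3, .25, .2, .15, .1)),
                 collapse = "")
    bg <- trainMarkov(src, order = 5)
    sim <- generateGenome(plantConfig(genomeLength = 240000, nStandard = 0L,
                                      nSplit = 0L, nPermuted = 0L,
                                      nCds = 0L, bg = bg, seed = 510))
    gseq <- as.character(sim$genome[[1]])
    k6 <- function(s) {
        km <- substring(s, 1:(nchar(s) - 5L), 6:nchar(s))
        table(factor(km, levels = sort(do.call(
            paste0, expand.grid(rep(list(.B), 6))[, 6:1]))))
    }
    o <- as.numeric(k6(gseq))
    e <- as.numeric(k6(src))
    keep <- (o + e) > 10
    chi <- suppressWarnings(chisq.test(rbind(o[keep], e[keep])))
    expect_gt(chi$p.value, 0.001)
})
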