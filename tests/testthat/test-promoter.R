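## toy annotation helper
toyAnnotation <- function(df, seqid = "chr") {
    gr <- GenomicRanges::GRanges(seqid,
                                 IRanges::IRanges(df$start, df$end),
                                 df$strand)
    S4Vectors::mcols(gr)$ID <- df$id
    S4Vectors::mcols(gr)$product <- df$product
    gr
}

test_that("training-set selection applies the operon-leader and product rules", {
    set.seed(401)
    genome <- Biostrings::DNAStringSet(c(chr = randSeq(6000)))
    ann <- toyAnnotation(data.frame(
        id = c("g1", "g2", "g3", "g4"),
        start = c(1000, 1450, 3000, 4500), end = c(1400, 1900, 3400, 4900),
        strand = c("+", "+", "+", "+"),
        product = c("elongation factor", "ribosomal protein",
                    "hypothetical protein", "ATPase subunit")))
    tr <- selectTrainingGenes(ann, genome, runConfig())
    ## g2 is 49 nt behind g1 (intra-operon), g3 is hypothetical
    expect_setequal(tr$geneId, c("g1", "g4"))
    expect_equal(nchar(tr$window), c(90L, 90L))

    ## random toy genome checked against a rule-by-rule oracle
    set.seed(402)
    n <- 30L
    starts <- sort(sample(seq(500, 55000, by = 120), n))
    len <- sample(200:500, n, replace = TRUE)
    df <- data.frame(id = paste0("g", 1:n), start = starts,
                     end = starts + len,
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     product = sample(c("kinase", "putative transporter",
                                        "hypothetical protein", "ligase"),
                                      n, replace = TRUE))
    df <- df[df$end < 59000, ]
    genome2 <- Biostrings::DNAStringSet(c(chr = randSeq(60000)))
    got <- selectTrainingGenes(toyAnnotation(df), genome2, runConfig())
    want <- character(0)
    for (i in seq_len(nrow(df))) {
        if (grepl("putative|hypothetical", df$product[i])) next
        same <- df[df$strand == df$strand[i] & df$id != df$id[i], ]
        gap <- if (df$strand[i] == "+") {
            up <- same$end[same$end < df$start[i]]
            if (length(up)) df$start[i] - max(up) - 1L else Inf
        } else {
            dn <- same$start[same$start > df$end[i]]
            if (length(dn)) min(dn) - df$end[i] - 1L else Inf
        }
        if (gap >= 100) want <- c(want, df$id[i])
    }
    expect_setequal(got$geneId, want)
})

test_that("EM motif discovery recovers a planted 16-mer", {
    set.seed(403)
    planted <- "AAATTTAAAAGTTTCA"
    windows <- vapply(1:50, function(i) {
        w <- randSeq(90)
        pos <- sample(1:(90 - 16 + 1), 1)
        paste0(substr(w, 1, pos - 1), planted, substr(w, pos + 16, 90))
    }, character(1))
    motif <- discoverMotif(windows, width = 16, restarts = 20, seed = 5)
    cons <- strsplit(motifConsensus(motif), "")[[1]]
    tgt <- strsplit(planted, "")[[1]]
    expect_gte(sum(cons == tgt), 14L)
    ## windows without a planted motif yield lower information content
    set.seed(404)
    noise <- vapply(1:50, function(i) randSeq(90), character(1))
    motif0 <- discoverMotif(noise, width = 16, restarts = 20, seed = 5)
    expect_gt(motifInformation(motif), motifInformation(motif0))
    expect_identical(
        motifConsensus(discoverMotif(windows, seed = 5)),
        motifConsensus(discoverMotif(windows, seed = 5)))
})

test_that("the packaged template motif carries an A-run plus TATA box", {
    m <- promoterTemplate()
    cons <- motifConsensus(m)
    expect_true(grepl("A{1,3}TTTATATA", cons))
    expect_equal(colSums(motifProb(m)), rep(1, 16))
})

test_that("upstream scanning reports the best placement per gene", {
    m <- promoterTemplate(strength = 0.97)
    cons <- motifConsensus(m)
    set.seed(405)
    win <- paste0(randSeq(60), cons, randSeq(150 - 60 - 16))
    h <- scanUpstream(m, data.frame(geneId = "g", window = win))
    expect_equal(h$offset, 60 - 150)       # motif start at position 61
    ## two identical best sites: the most upstream one is reported
    win2 <- paste0(randSeq(10), cons, randSeq(30), cons, randSeq(78))
    h2 <- scanUpstream(m, data.frame(geneId = "g", window = win2))
    expect_equal(h2$offset, 10 - nchar(win2))
    ## window shorter than the motif is skipped with NA
    h3 <- scanUpstream(m, data.frame(geneId = c("a", "b"),
                                     window = c("ACGT", win)))
    expect_true(is.na(h3$offset[1]))
    expect_false(is.na(h3$offset[2]))
})

test_that("null distribution P-values behave and are deterministic", {
    bg <- uniformBackground(0.5)
    m <- promoterTemplate()
    n1 <- buildNull(m, bg, genomeLength = 30000, n = 3, seed = 7)
    n2 <- buildNull(m, bg, genomeLength = 30000, n = 3, seed = 7)
    expect_identical(nullScores(n1), nullScores(n2))
    ## monotone non-increasing in score
    s <- seq(min(nullScores(n1)) - 1, max(nullScores(n1)) + 1, length.out = 25)
    p <- pvalueFromNull(n1, s)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p > 0 & p <= 1))
    ## a strong planted site is extreme against the null (smallest
    ## attainable P is 1/(n+1) for a null of n best-hit scores)
    expect_equal(pvalueFromNull(n1, max(nullScores(n1)) + 5),
                 1 / (length(nullScores(n1)) + 1))
    expect_lt(pvalueFromNull(n1, max(nullScores(n1)) + 5), 0.01)
})

test_that("hit filtering applies the expected-position and threshold rules", {
    null <- new("NullDistribution", scores = sort(rnorm(999)),
                nGenomes = 10L, seed = 1L)
    ## scores chosen so that training-worst P ~ 0.03
    trainScores <- quantile(nullScores(null), c(0.999, 0.99, 0.97))
    hits <- data.frame(geneId = c("a", "b", "c", "d"),
                       offset = c(-40L, -45L, -200L, -35L),
                       score = c(quantile(nullScores(null), 0.95),  # P ~ .05
                                 quantile(nullScores(null), 0.98),  # P ~ .02
                                 quantile(nullScores(null), 0.999),
                                 quantile(nullScores(null), 0.999)))
    kept <- filterHits(hits, null, trainScores, positionWindow = c(-100, -16))
    expect_setequal(kept$geneId, c("b", "d"))   # a: P too high; c: position
    ## training hits never violate their own threshold
    trHits <- data.frame(geneId = paste0("t", 1:3), offset = rep(-40L, 3),
                         score = as.numeric(trainScores))
    keptTr <- filterHits(trHits, null, trainScores,
                         positionWindow = c(-100, -16))
    expect_equal(nrow(keptTr), 3L)
    expect_error(filterHits(hits, null, numeric(0)), "threshold")
})

test_that("spacing outliers reproduce the published configuration", {
    ## 44 offsets in the normal band plus -72 and -65: exactly two flagged
    set.seed(406)
    offs <- c(sample(seq(-49L, -30L), 44L, replace = TRUE), -72L, -65L)
    df <- data.frame(geneId = paste0("t", seq_along(offs)), offset = offs)
    out <- spacingOutliers(df)
    expect_equal(sum(out$outlier), 2L)
    expect_setequal(out$offset[out$outlier], c(-72L, -65L))
    ## all offsets in the band: none flagged
    df2 <- df[1:44, ]
    expect_equal(sum(spacingOutliers(df2)$outlier), 0L)
    ## k planted far outliers are all flagged
    for (k in 1:3) {
        df3 <- rbind(df2, data.frame(geneId = paste0("o", 1:k),
                                     offset = rep(-80L, k)))
        expect_equal(sum(spacingOutliers(df3)$outlier), k)
    }
    ## too few hits disables calling
    expect_warning(out4 <- spacingOutliers(df[1:5, ]), "disabled")
    expect_false(any(out4$outlier))
})
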