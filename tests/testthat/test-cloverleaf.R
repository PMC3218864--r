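## independent exhaustive fold oracle: enumerate every in-range arm-length
## combination, count pairable stem positions, and pick the assignment
## with the most pairable positions (requiring near-complete stems).
oracleFold <- function(seq) {
    v <- strsplit(seq, "")[[1]]
    L <- length(v)
    best <- NULL
    for (cca in c(0L, 3L)) for (d in 3:4) for (dl in 4:12) {
        vv <- L - 52L - 2L * d - dl - cca
        if (vv < 3L || vv > 21L) next
        sD3 <- 10L + d + dl; sAc5 <- 11L + 2L * d + dl
        sAc3 <- 23L + 2L * d + dl; sT5 <- 28L + 2L * d + dl + vv
        sT3 <- sT5 + 12L; sAcc3 <- sT3 + 5L
        pr <- rbind(cbind(1:7, sAcc3 + 7L - (1:7)),
                    cbind(10L + seq_len(d) - 1L, sD3 + d - seq_len(d)),
                    cbind(sAc5 + 0:4, sAc3 + 5L - (1:5)),
                    cbind(sT5 + 0:4, sT3 + 5L - (1:5)))
        ok <- oraclePairable(v[pr[, 1]], v[pr[, 2]])
        stems <- rep(c(7L, d, 5L, 5L), c(7L, d, 5L, 5L))
        grp <- rep(1:4, c(7L, d, 5L, 5L))
        mm <- tapply(!ok, grp, sum)
        if (any(mm > 1L)) next
        if (is.null(best) || sum(ok) > best$npair)
            best <- list(d = d, dl = dl, v = vv, cca = cca == 3L,
                         npair = sum(ok))
    }
    best
}

test_that("folding rejects unpairable sequences and recovers designs", {
    expect_null(foldCloverleaf(strrep("A", 76)))
    expect_error(foldCloverleaf(strrep("A", 30)), "length")
    set.seed(21)
    for (i in 1:12) {
        d <- sample(3:4, 1); dl <- sample(4:12, 1); v <- sample(3:21, 1)
        t <- makeTrnaSequence(sample(c("GTC", "CTT", "GAA", "TGC"), 1),
                              gcBias = 0.65, d = d, dl = dl, v = v)
        st <- foldCloverleaf(t$seq)
        expect_false(is.null(st))
        expect_equal(c(st@d, st@dloop, st@varlen), c(d, dl, v))
        orc <- oracleFold(t$seq)
        expect_equal(c(orc$d, orc$dl, orc$v), c(d, dl, v))
        expect_gte(structureScore(st), 20)
    }
})

test_that("folding is invariant to genomic strand placement", {
    set.seed(22)
    t <- makeTrnaSequence("GTC")
    flank1 <- randSeq(40); flank2 <- randSeq(40)
    genome <- Biostrings::DNAStringSet(
        c(chr = oracleRevComp(paste0(flank1, t$seq, flank2))))
    iv <- GenomicRanges::GRanges("chr", IRanges::IRanges(41, 40 + nchar(t$seq)), "-")
    back <- extractInterval(genome, iv)
    ## minus-strand extraction of the reverse-complemented placement
    ## returns a sequence whose fold matches the original design
    st <- foldCloverleaf(back)
    expect_equal(st@d, t$structure@d)
    expect_equal(st@varlen, t$structure@varlen)
    expect_equal(structureScore(st), structureScore(t$structure))
})

test_that("scoring penalizes every single disruptive stem mutation", {
    set.seed(23)
    t <- makeTrnaSequence("GAA", gcBias = 0.7)
    base <- scoreTrna(t$seq, t$structure)
    pr <- structurePairs(t$structure)
    v <- strsplit(t$seq, "")[[1]]
    for (r in seq_len(nrow(pr))) {
        i <- pr[r, 1]
        mut <- v
        mut[i] <- setdiff(.B, c(v[i], v[pr[r, 2]]))[1]
        sc <- scoreTrna(paste(mut, collapse = ""), t$structure)
        expect_lt(sc, base)
    }
})

test_that("Sprinzl numbering anchors the anticodon and T loop", {
    t76 <- makeTrnaSequence("GTC", seed = 31)           # canonical 76-mer
    lab <- sprinzlNumber(t76$structure)
    expect_equal(lab, as.character(1:76))
    expect_equal(posOfSprinzl(t76$structure, 34:36), 34:36)

    t75 <- makeTrnaSequence("GTC", seed = 32, dl = 7)   # 1-nt shorter D loop
    expect_equal(posOfSprinzl(t75$structure, 34:36), 33:35)
    expect_equal(sprinzlNumber(t75$structure)[33:35], c("34", "35", "36"))
    ## deleted position is a non-conserved D-loop slot
    expect_false("17" %in% sprinzlNumber(t75$structure))

    tv <- makeTrnaSequence("GTC", seed = 33, v = 8)     # long variable loop
    expect_true("47a" %in% sprinzlNumber(tv$structure))
    expect_equal(sprinzlNumber(tv$structure)[posOfSprinzl(tv$structure, 59)], "59")
})

test_that("anticodon decoding and inventory bookkeeping", {
    expect_equal(anticodonToIsotype("GTC"), "Asp")
    expect_equal(anticodonToIsotype("CTT"), "Lys")
    expect_equal(anticodonToIsotype("CAT"), "Met")
    expect_equal(anticodonToIsotype("CAT", imet = TRUE), "iMet")
    full <- archaealAnticodons()
    expect_length(full, 46L)
    expect_equal(inventoryCheck(full), character(0))
    expect_equal(inventoryCheck(setdiff(full, "Lys(CUU)")), "Lys(CUU)")
    set.seed(24)
    for (i in 1:10) {
        k <- sample(1:6, 1)
        drop <- sample(full, k)
        expect_setequal(inventoryCheck(setdiff(full, drop)), drop)
    }
})
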