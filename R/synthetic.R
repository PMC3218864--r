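## Synthetic-genome generator. Plants consensus-derived tRNA genes
## (standard, intron-containing, split, permuted) plus archaeal-style
## promoters and decoy protein-coding annotations on a Markov-chain
## background, and records machine-readable ground truth. All sampling
## goes through R's RNG, so generate() is deterministic per seed.

#' Uniform (order-0) background model
#'
#' @param gc G+C fraction.
#' @return a [MarkovBackground-class] of order 0.
#' @export
uniformBackground <- function(gc = 0.5) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    new("MarkovBackground", order = 0L, prob = matrix(p, 1L, 4L),
        contextFreq = 1, trainedOn = sprintf("uniform(gc=%.2f)", gc))
}

## sample from a background using the current RNG state (no re-seeding)
.sampleBg <- function(bg, len) {
    if (len <= 0L) return(integer(0))
    k <- bg@order
    if (k > 0L) {
        ctxCode <- sample.int(nrow(bg@prob), 1L, prob = bg@contextFreq) - 1L
        init <- integer(k)
        for (i in k:1) { init[i] <- ctxCode %% 4L + 1L; ctxCode <- ctxCode %/% 4L }
    } else init <- integer(0)
    if (len <= k) return(init[seq_len(len)])
    cum <- t(apply(bg@prob, 1L, cumsum))
    if (nrow(bg@prob) == 1L) cum <- matrix(cumsum(bg@prob[1L, ]), nrow = 1L)
    .sampleMarkovCpp(cum, init, as.integer(len))
}

## ---- tRNA sequence design ----------------------------------------------

#' Design a consensus-derived tRNA sequence
#'
#' Builds a mature tRNA with the requested anticodon: stems are sampled at
#' the configured G/C fraction (hyperthermophile-style G-C rich stems at
#' high `gcBias`), conserved positions are set to the consensus used by the
#' scoring model, and all remaining positions are randomized. The result
#' is checked to re-fold to the designed structure with a score of at
#' least `minScore` (resampled otherwise).
#'
#' @param anticodon 3-mer DNA anticodon (e.g. `"GTC"` for Asp).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param gcBias probability that a sampled stem pair is G-C.
#' @param d,dl,v D-stem, D-loop and variable-loop lengths.
#' @param cca include a genomically encoded 3'-terminal CCA.
#' @param minScore minimum accepted re-fold score in bits.
#' @return list with `seq` (character), `structure`
#'   ([CloverleafStructure-class]) and `int` (integer-coded sequence).
#' @export
makeTrnaSequence <- function(anticodon, seed = NULL, gcBias = 0.6, d = 4L,
                             dl = 8L, v = 5L, cca = TRUE, minScore = 20) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    anticodon <- toupper(chartr("U", "T", anticodon))
    acInt <- dnaToInt(anticodon)
    if (length(acInt) != 3L || anyNA(acInt)) stop("invalid anticodon")
    layout <- .cloverleafLayout(d, dl, v, cca)
    for (try in 1:50) {
        vfull <- sample.int(4L, layout$len, replace = TRUE)
        for (r in seq_len(nrow(layout$pairs))) {
            i <- layout$pairs[r, 1L]; j <- layout$pairs[r, 2L]
            if (runif(1) < gcBias) {
                vfull[i] <- sample(c(2L, 3L), 1L)
            } else {
                vfull[i] <- sample(c(1L, 4L), 1L)
            }
            vfull[j] <- 5L - vfull[i]
        }
        for (r in seq_along(layout$cons$idx)) {
            i <- layout$cons$idx[r]
            b <- layout$cons$base[r]
            if (b == 0L) b <- 1L          # R -> A
            vfull[i] <- b
            pr <- which(layout$pairs[, 1L] == i | layout$pairs[, 2L] == i)
            if (length(pr)) {
                q <- setdiff(layout$pairs[pr, ], i)
                vfull[q] <- 5L - b
            }
        }
        idx34 <- match("34", layout$sprinzl)
        vfull[idx34:(idx34 + 2L)] <- acInt
        seq <- intToDna(vfull)
        st <- foldCloverleaf(seq)
        if (!is.null(st) && st@d == layout$d && st@dloop == layout$dl &&
            st@varlen == layout$v && st@cca == layout$cca &&
            st@score >= minScore)
            return(list(seq = seq, structure = st, int = vfull))
    }
    stop("failed to design a self-consistent tRNA sequence")
}

#' Cut a tRNA at a Sprinzl junction
#'
#' Splits a mature tRNA into a 5' fragment (Sprinzl 1..a) and a 3'
#' fragment (a+1..end); the inverse of [joinSplit()].
#'
#' @param seq mature tRNA sequence.
#' @param structure its [CloverleafStructure-class].
#' @param junction integer Sprinzl position `a` (cut between a and a+1),
#'   or a string `"a/b"`.
#' @return list of two fragments, each a list with `kind`, `seq`,
#'   `sprinzlFrom`, `sprinzlTo`.
#' @export
cutTrna <- function(seq, structure, junction) {
    a <- if (is.character(junction)) as.integer(sub("/.*", "", junction))
         else as.integer(junction)
    ia <- posOfSprinzl(structure, a)
    if (is.na(ia) || ia >= structure@len) stop("junction outside structure")
    seq <- as.character(seq)
    lastLab <- structure@sprinzl[structure@len]
    list(five = list(kind = "five_prime", seq = substr(seq, 1L, ia),
                     sprinzlFrom = "1", sprinzlTo = as.character(a)),
         three = list(kind = "three_prime",
                      seq = substr(seq, ia + 1L, structure@len),
                      sprinzlFrom = structure@sprinzl[ia + 1L],
                      sprinzlTo = lastLab))
}

## ---- junction / intron construction ------------------------------------

## GC-rich complementary helix arms of length fl
.gcHelix <- function(fl, gcFrac = 0.85) {
    arm <- ifelse(runif(fl) < gcFrac, sample(c(2L, 3L), fl, replace = TRUE),
                  sample(c(1L, 4L), fl, replace = TRUE))
    arm <- as.integer(arm)
    list(arm1 = arm, arm2 = rev(5L - arm))
}

## choose a base that cannot pair with `against`
.nonPairing <- function(against) {
    cand <- which(.PAIR$cls[, against][1:4] == 0L)
    cand[sample.int(length(cand), 1L)]
}

## Force the exon-side flanking helix of a canonical hBHBh' at the cut
## after index `cpos` and build the trailing/leading extensions carrying
## the central helix and a trans-pairing stem of length `stem`.
## Modifies vfull in the 3' exon (flank positions + stem-partner repair);
## returns NULL when the forced positions would touch the anticodon.
.forceJunction <- function(vfull, layout, cpos, u1, u2, stem,
                           stemGc = 0.85) {
    idx34 <- match("34", layout$sprinzl)
    antic <- idx34:(idx34 + 2L)
    hArm1 <- (cpos - u1 - 2L):(cpos - u1)
    forced <- cpos + ((8L - u2):(10L - u2))
    if (any(forced %in% antic)) return(NULL)
    if (min(hArm1) < 1L || max(forced) > layout$len) return(NULL)
    for (t in 0:2) {
        f <- cpos + (8L - u2) + t
        vfull[f] <- 5L - vfull[cpos - u1 - t]
        pr <- which(layout$pairs[, 1L] == f | layout$pairs[, 2L] == f)
        if (length(pr)) {
            q <- setdiff(layout$pairs[pr, ], f)
            if (q %in% antic || q %in% forced || q %in% hArm1) return(NULL)
            vfull[q] <- 5L - vfull[f]
        }
    }
    hArm2 <- cpos + ((4L - u2):(7L - u2))      # central-helix arm in exon2
    HArm1 <- 5L - rev(vfull[hArm2])
    hx <- .gcHelix(stem, stemGc)
    pad1 <- c(1L, sample.int(4L, 2L, replace = TRUE))
    b2first <- .nonPairing(HArm1[4L])
    bulge1 <- if (u1 < 3L) sample.int(4L, 3L - u1, replace = TRUE) else integer(0)
    bulge2 <- c(b2first,
                if (u2 > 1L) sample.int(4L, u2 - 1L, replace = TRUE) else integer(0))
    trailer <- c(bulge1, HArm1, hx$arm1, pad1)
    leader <- c(sample.int(4L, 2L, replace = TRUE), 1L, hx$arm2, bulge2)
    list(vfull = vfull, trailer = trailer, leader = leader)
}

## Build a canonical intron (length >= 15) for insertion after Sprinzl 37,
## with its own BHB at the boundaries. Returns modified vfull + intron.
.makeIntron <- function(vfull, layout, ivLen) {
    if (ivLen < 15L) stop("plantable canonical introns need >= 15 nt")
    cpos <- match("37", layout$sprinzl)
    u1 <- 1L; u2 <- 2L
    fr <- .forceJunction(vfull, layout, cpos, u1, u2, stem = 4L)
    if (is.null(fr)) stop("intron junction construction failed")
    vfull <- fr$vfull
    hArm2 <- cpos + ((4L - u2):(7L - u2))
    HArm1 <- 5L - rev(vfull[hArm2])
    hx <- .gcHelix(4L)
    junk <- .sampleBgUnif(ivLen - 15L)
    intron <- c(sample.int(4L, 2L, replace = TRUE), HArm1, hx$arm1, junk,
                hx$arm2, .nonPairing(HArm1[4L]))
    stopifnot(length(intron) == ivLen)
    list(vfull = vfull, intron = intron, offset = cpos)
}

.sampleBgUnif <- function(n) if (n > 0L) sample.int(4L, n, replace = TRUE) else integer(0)

#' Sample a promoter instance from a motif
#'
#' Draws one base per column from the motif's probability matrix; used by
#' the generator to plant promoter occurrences with realistic per-position
#' variability.
#'
#' @param motif a [PromoterMotif-class].
#' @return integer-coded sequence of length `motif@width`.
#' @export
sampleMotifInstance <- function(motif) {
    vapply(seq_len(motif@width), function(cc)
        sample.int(4L, 1L, prob = motif@prob[, cc]), integer(1))
}

## ---- feature blocks -----------------------------------------------------

## Each builder returns list(block = int vector, truth = data.frame (block-
## relative coords), promoters = data.frame (block-relative)).

.truthRow <- function(class, id, isotype, anticodon, junction = NA,
                      stem = NA, intervening = NA, intronLen = NA,
                      orientation = NA,
                      fiveStart = NA, fiveEnd = NA, fiveStrand = NA,
                      threeStart = NA, threeEnd = NA, threeStrand = NA,
                      matureSeq = NA, product = NA) {
    data.frame(class = class, id = id, isotype = isotype,
               anticodon = anticodon, junction = junction, stem = stem,
               intervening = intervening, intronLen = intronLen,
               orientation = orientation, fiveStart = fiveStart,
               fiveEnd = fiveEnd, fiveStrand = fiveStrand,
               threeStart = threeStart, threeEnd = threeEnd,
               threeStrand = threeStrand, matureSeq = matureSeq,
               product = product, stringsAsFactors = FALSE)
}

.promRow <- function(id, class, start, end, strand, offset) {
    data.frame(id = id, class = class, start = start, end = end,
               strand = strand, offset = offset, stringsAsFactors = FALSE)
}

#' Plant a standard (optionally intron-containing) tRNA gene block
#'
#' @param anticodon DNA anticodon.
#' @param id feature id.
#' @param gcBias stem G/C fraction.
#' @param intronLen 0 for an intronless gene, otherwise the canonical
#'   intron length (>= 15, inserted between Sprinzl 37 and 38 with a BHB at
#'   its boundaries).
#' @param motif promoter motif to sample the planted promoter from.
#' @param promOffsetRange magnitude range the promoter offset is drawn
#'   from (default the normal band 30-49 nt upstream of the mature 5' end).
#' @return list(block, truth, promoters) with block-relative coordinates.
#' @export
plantStandard <- function(anticodon, id = "trna1", gcBias = 0.6,
                          intronLen = 0L, motif = promoterTemplate(),
                          promOffsetRange = c(30L, 49L)) {
    t <- makeTrnaSequence(anticodon, gcBias = gcBias)
    layout <- .cloverleafLayout(t$structure@d, t$structure@dloop,
                                t$structure@varlen, t$structure@cca)
    body <- t$int
    if (intronLen > 0L) {
        mi <- .makeIntron(t$int, layout, as.integer(intronLen))
        body <- c(mi$vfull[1:mi$offset], mi$intron,
                  mi$vfull[(mi$offset + 1L):layout$len])
        t$int <- mi$vfull
    }
    mag <- sample(promOffsetRange[1]:promOffsetRange[2], 1L)
    g <- mag - 16L
    prom <- sampleMotifInstance(motif)
    block <- c(prom, .sampleBgUnif(g), body)
    gs <- 16L + g + 1L
    list(block = block,
         truth = .truthRow("standard", id, anticodonToIsotype(anticodon),
                           anticodon, intronLen = intronLen,
                           fiveStart = gs, fiveEnd = gs + length(body) - 1L,
                           fiveStrand = "+", matureSeq = intToDna(t$int)),
         promoters = .promRow(id, "tRNA", 1L, 16L, "+", -mag))
}

#' Plant a split (trans-spliced) tRNA gene block
#'
#' Cuts a designed tRNA at the junction, builds a canonical hBHBh' at the
#' splice sites with a G/C-rich trans-pairing stem of the requested length
#' between the 5'-half trailer and the 3'-half leader, and lays the parts
#' out in one of three genomic arrangements with promoters upstream of
#' both halves.
#'
#' @param anticodon DNA anticodon.
#' @param junction Sprinzl cut position `a` (cut between a and a+1).
#' @param stem trans-pairing stem length in bp.
#' @param orientation `"same_strand"` (adjacent, cis span `cisSpan`),
#'   `"convergent"` (adjacent, 3' half on the opposite strand) or
#'   `"distant"` (same strand, separated by `separation` nt).
#' @param id feature id.
#' @param gcBias stem G/C fraction of the tRNA body.
#' @param cisSpan exon1-end to exon2-start distance for the same-strand
#'   arrangement (default 121 nt, i.e. an apparent long intron).
#' @param separation exon gap for the distant arrangement (default 4500).
#' @param motif promoter motif for planted promoters.
#' @return list(block, truth, promoters).
#' @export
plantSplit <- function(anticodon, junction = 37L, stem = 14L,
                       orientation = c("same_strand", "convergent", "distant"),
                       id = "split1", gcBias = 0.6, cisSpan = 121L,
                       separation = 4500L, motif = promoterTemplate()) {
    orientation <- match.arg(orientation)
    a <- as.integer(junction)
    t <- makeTrnaSequence(anticodon, gcBias = gcBias)
    layout <- .cloverleafLayout(t$structure@d, t$structure@dloop,
                                t$structure@varlen, t$structure@cca)
    cpos <- match(as.character(a), layout$sprinzl)
    if (is.na(cpos)) stop("junction not representable")
    fr <- NULL
    for (uu in list(c(2L, 2L), c(1L, 2L), c(2L, 1L), c(1L, 1L))) {
        cand <- .forceJunction(t$int, layout, cpos, uu[1], uu[2], stem)
        if (is.null(cand)) next
        st2 <- foldCloverleaf(intToDna(cand$vfull))
        if (!is.null(st2) && st2@score >= 20) { fr <- cand; break }
    }
    if (is.null(fr)) stop("no feasible BHB geometry at junction ", a)
    vfull <- fr$vfull
    five <- c(vfull[1:cpos], fr$trailer)
    fiveExonLen <- cpos
    three <- c(fr$leader, vfull[(cpos + 1L):layout$len])
    threeExonLen <- layout$len - cpos
    leaderLen <- length(fr$leader)
    prom5 <- sampleMotifInstance(motif); prom3 <- sampleMotifInstance(motif)
    mag5 <- sample(30:49, 1L); g5 <- mag5 - 16L
    g3 <- 30L
    mk <- function(gapMid) {
        ## [prom5][g5][five exon + trailer][gapMid][prom3][g3][leader + 3' exon]
        block <- c(prom5, .sampleBgUnif(g5), five, .sampleBgUnif(gapMid),
                   prom3, .sampleBgUnif(g3), three)
        fs <- 16L + g5 + 1L
        ts <- fs + length(five) + gapMid + 16L + g3 + leaderLen
        list(block = block, fs = fs, ts = ts,
             prom3Start = fs + length(five) + gapMid + 1L)
    }
    jlab <- paste0(a, "/", a + 1L)
    iso <- anticodonToIsotype(anticodon)
    if (orientation %in% c("same_strand", "distant")) {
        span <- if (orientation == "same_strand") cisSpan else separation
        gapMid <- span - length(fr$trailer) - 16L - g3 - leaderLen
        if (gapMid < 5L) stop("cisSpan/separation too small for the stem")
        m <- mk(gapMid)
        truth <- .truthRow("split", id, iso, anticodon, junction = jlab,
                           stem = stem, orientation = orientation,
                           fiveStart = m$fs, fiveEnd = m$fs + fiveExonLen - 1L,
                           fiveStrand = "+", threeStart = m$ts,
                           threeEnd = m$ts + threeExonLen - 1L,
                           threeStrand = "+", matureSeq = intToDna(vfull))
        proms <- rbind(
            .promRow(paste0(id, "_5h"), "tRNA", 1L, 16L, "+", -mag5),
            .promRow(paste0(id, "_3h"), "tRNA", m$prom3Start,
                     m$prom3Start + 15L, "+", -(16L + g3 + leaderLen)))
        return(list(block = m$block, truth = truth, promoters = proms))
    }
    ## convergent: 3'-half cassette reverse-complemented downstream
    cassette <- c(prom3, .sampleBgUnif(g3), three)
    gapMid <- 40L
    head <- c(prom5, .sampleBgUnif(g5), five)
    block <- c(head, .sampleBgUnif(gapMid), revCompInt(cassette))
    fs <- 16L + g5 + 1L
    cassStart <- length(head) + gapMid + 1L
    ## exon2 inside cassette (cassette coords): after prom3+g3+leader
    exon2CasStart <- 16L + g3 + leaderLen + 1L
    exon2CasEnd <- exon2CasStart + threeExonLen - 1L
    ## map to block coords after reverse complement
    casLen <- length(cassette)
    ts <- cassStart + (casLen - exon2CasEnd)
    te <- cassStart + (casLen - exon2CasStart)
    promCasStart <- 1L; promCasEnd <- 16L
    ps <- cassStart + (casLen - promCasEnd)
    pe <- cassStart + (casLen - promCasStart)
    truth <- .truthRow("split", id, iso, anticodon, junction = jlab,
                       stem = stem, orientation = "convergent",
                       fiveStart = fs, fiveEnd = fs + fiveExonLen - 1L,
                       fiveStrand = "+", threeStart = ts, threeEnd = te,
                       threeStrand = "-", matureSeq = intToDna(vfull))
    proms <- rbind(
        .promRow(paste0(id, "_5h"), "tRNA", 1L, 16L, "+", -mag5),
        .promRow(paste0(id, "_3h"), "tRNA", ps, pe, "-",
                 -(16L + g3 + leaderLen)))
    list(block = block, truth = truth, promoters = proms)
}

#' Plant a circularly permuted tRNA gene block
#'
#' Lays out the 3' part (Sprinzl j+1..76) upstream of the 5' part (1..j)
#' separated by `intervening` nucleotides, with a canonical hBHBh' formed
#' across the precursor termini (leader before the 3' part, trailer after
#' the 5' part) and a single promoter upstream of the whole transcript at
#' an outlier spacing from the mature 5' end.
#'
#' @param anticodon DNA anticodon.
#' @param junction T-loop Sprinzl cut position j (default 59, i.e. 59/60).
#' @param intervening length of the sequence between the parts (>= 0).
#' @param intronLen 0, or a canonical intron (>= 15 nt) inside the 5' part.
#' @param id feature id.
#' @param gcBias stem G/C fraction.
#' @param motif promoter motif.
#' @param promOffsetRange magnitude range for the promoter offset from the
#'   mature 5' end (default 68-80, around the spacings observed for
#'   permuted genes and clearly beyond the 30-49 nt normal band).
#' @return list(block, truth, promoters).
#' @export
plantPermuted <- function(anticodon, junction = 59L, intervening = 7L,
                          intronLen = 0L, id = "perm1", gcBias = 0.6,
                          motif = promoterTemplate(),
                          promOffsetRange = c(68L, 80L)) {
    j <- as.integer(junction)
    if (j < 54L || j > 59L) stop("permuted junction must lie in the T loop")
    iv <- as.integer(intervening)
    t <- makeTrnaSequence(anticodon, gcBias = gcBias)
    layout <- .cloverleafLayout(t$structure@d, t$structure@dloop,
                                t$structure@varlen, t$structure@cca)
    cpos <- match(as.character(j), layout$sprinzl)
    fr <- NULL
    for (uu in list(c(2L, 2L), c(1L, 2L), c(2L, 1L), c(1L, 1L))) {
        cand <- .forceJunction(t$int, layout, cpos, uu[1], uu[2], stem = 6L)
        if (is.null(cand)) next
        st2 <- foldCloverleaf(intToDna(cand$vfull))
        if (!is.null(st2) && st2@score >= 20) { fr <- cand; break }
    }
    if (is.null(fr)) stop("no feasible BHB geometry at junction ", j)
    vfull <- fr$vfull
    fiveExon <- vfull[1:cpos]
    if (intronLen > 0L) {
        mi <- .makeIntron(vfull, layout, as.integer(intronLen))
        vfull <- mi$vfull
        fiveExon <- c(vfull[1:mi$offset], mi$intron,
                      vfull[(mi$offset + 1L):cpos])
    }
    threeExon <- vfull[(cpos + 1L):layout$len]
    leaderLen <- length(fr$leader)
    len3 <- length(threeExon)
    prom <- sampleMotifInstance(motif)
    tgtLo <- max(promOffsetRange[1], 16L + leaderLen + len3 + iv + 2L)
    tgt <- sample(tgtLo:max(promOffsetRange[2], tgtLo), 1L)
    g1 <- tgt - 16L - leaderLen - len3 - iv
    block <- c(prom, .sampleBgUnif(g1), fr$leader, threeExon,
               .sampleBgUnif(iv), fiveExon, fr$trailer)
    ts <- 16L + g1 + leaderLen + 1L
    fs <- ts + len3 + iv
    truth <- .truthRow("permuted", id, anticodonToIsotype(anticodon, imet = TRUE),
                       anticodon, junction = paste0(j, "/", j + 1L),
                       intervening = iv, intronLen = intronLen,
                       orientation = "same_strand",
                       fiveStart = fs, fiveEnd = fs + length(fiveExon) - 1L,
                       fiveStrand = "+", threeStart = ts,
                       threeEnd = ts + len3 - 1L, threeStrand = "+",
                       matureSeq = intToDna(vfull))
    list(block = block, truth = truth,
         promoters = .promRow(id, "tRNA", 1L, 16L, "+", -tgt))
}

## decoy protein-coding gene block (for promoter training)
.plantCds <- function(id, motif, known = TRUE, operon = FALSE) {
    len <- sample(300:900, 1L)
    products <- c("DNA-directed RNA polymerase subunit B",
                  "30S ribosomal protein S12", "elongation factor 1-alpha",
                  "ATP synthase subunit A", "glutamine synthetase",
                  "cell division protein FtsZ", "reverse gyrase",
                  "thermosome subunit alpha")
    if (known) {
        mag <- sample(30:49, 1L)
        prom <- sampleMotifInstance(motif)
        block <- c(prom, .sampleBgUnif(mag - 16L), .sampleBgUnif(len))
        gs <- mag + 1L
        product <- sample(products, 1L)
        promoters <- .promRow(id, "CDS", 1L, 16L, "+", -mag)
    } else {
        block <- .sampleBgUnif(len)
        gs <- 1L
        product <- "hypothetical protein"
        promoters <- NULL
    }
    truth <- .truthRow("cds", id, NA, NA, fiveStart = gs,
                       fiveEnd = gs + len - 1L, fiveStrand = "+",
                       product = product)
    if (operon) {
        gap <- sample(20:60, 1L)
        len2 <- sample(300:600, 1L)
        s2 <- length(block) + gap + 1L
        block <- c(block, .sampleBgUnif(gap), .sampleBgUnif(len2))
        truth <- rbind(truth,
            .truthRow("cds", paste0(id, "b"), NA, NA, fiveStart = s2,
                      fiveEnd = s2 + len2 - 1L, fiveStrand = "+",
                      product = sample(products, 1L)))
    }
    list(block = block, truth = truth, promoters = promoters)
}

## ---- genome assembly ----------------------------------------------------

#' Configuration for the synthetic-genome generator
#'
#' Defaults emulate the statistical structure of the discovery setting:
#' a 1-Mb genome carrying 20 standard tRNA genes, 2 split tRNA pairs
#' (junctions 37/38 and 30/31 with 14- and 13-bp trans-pairing stems,
#' cycling through same-strand-adjacent, convergent and distant
#' arrangements) and 1 permuted gene (junction 59/60, intervening length
#' drawn from 1-7 nt), plus annotated decoy protein-coding genes whose
#' planted promoters train the motif stage. Promoters sit 30-49 nt
#' upstream of mature tRNA 5' ends; permuted-gene promoters 60-80 nt.
#'
#' @param genomeLength total genome length.
#' @param nStandard,nSplit,nPermuted,nCds feature counts.
#' @param gcBias tRNA stem G/C fraction.
#' @param bg background model (`NULL` = uniform, G+C 0.5).
#' @param minSpacing minimum background gap between feature blocks.
#' @param splitJunctions,splitStems recycled per split feature.
#' @param splitOrientations recycled per split feature.
#' @param permutedJunction T-loop junction for permuted genes.
#' @param permutedIntron canonical intron length inside permuted genes
#'   (0 = none).
#' @param seed integer seed.
#' @return a list with class `plantConfig`.
#' @export
plantConfig <- function(genomeLength = 1e6, nStandard = 20L, nSplit = 2L,
                        nPermuted = 1L, nCds = 40L, gcBias = 0.6,
                        bg = NULL, minSpacing = 500L,
                        splitJunctions = c(37L, 30L),
                        splitStems = c(14L, 13L),
                        splitOrientations = c("same_strand", "convergent",
                                              "distant"),
                        permutedJunction = 59L, permutedIntron = 0L,
                        seed = 1L) {
    structure(list(genomeLength = as.integer(genomeLength),
                   nStandard = as.integer(nStandard),
                   nSplit = as.integer(nSplit),
                   nPermuted = as.integer(nPermuted),
                   nCds = as.integer(nCds), gcBias = gcBias,
                   bg = if (is.null(bg)) uniformBackground(0.5) else bg,
                   minSpacing = as.integer(minSpacing),
                   splitJunctions = as.integer(splitJunctions),
                   splitStems = as.integer(splitStems),
                   splitOrientations = splitOrientations,
                   permutedJunction = as.integer(permutedJunction),
                   permutedIntron = as.integer(permutedIntron),
                   seed = as.integer(seed)),
              class = "plantConfig")
}

.flipBlock <- function(x) {
    n <- length(x$block)
    x$block <- revCompInt(x$block)
    flip <- function(s, e) list(start = n - e + 1L, end = n - s + 1L)
    fstr <- function(s) ifelse(is.na(s), s, ifelse(s == "+", "-", "+"))
    tr <- x$truth
    for (cols in list(c("fiveStart", "fiveEnd"), c("threeStart", "threeEnd"))) {
        ok <- !is.na(tr[[cols[1]]])
        if (any(ok)) {
            f <- flip(tr[[cols[1]]][ok], tr[[cols[2]]][ok])
            tr[[cols[1]]][ok] <- f$start
            tr[[cols[2]]][ok] <- f$end
        }
    }
    tr$fiveStrand <- fstr(tr$fiveStrand)
    tr$threeStrand <- fstr(tr$threeStrand)
    x$truth <- tr
    if (!is.null(x$promoters) && nrow(x$promoters)) {
        f <- flip(x$promoters$start, x$promoters$end)
        x$promoters$start <- f$start
        x$promoters$end <- f$end
        x$promoters$strand <- fstr(x$promoters$strand)
    }
    x
}

#' Generate a synthetic annotated genome with planted tRNA features
#'
#' Builds every configured feature block (standard, split and permuted
#' tRNA genes with promoters; decoy protein-coding genes for promoter
#' training), places the blocks in random order and random strand on a
#' background sampled from the configured Markov model, and returns the
#' genome with machine-readable ground truth. Deterministic per seed.
#'
#' @param config a [plantConfig()] list.
#' @return list with `genome` (named `DNAStringSet`), `truth` (data.frame
#'   of planted features, absolute 1-based coordinates), `promoters`
#'   (data.frame of planted promoter instances), `annotations` (`GRanges`
#'   of the decoy protein-coding genes, suitable for promoter training)
#'   and `config`.
#' @export
generateGenome <- function(config = plantConfig()) {
    set.seed(config$seed)
    ## tRNA-locus promoters are planted close to consensus (the discovery
    ## setting rests on "strong promoters matching the promoter
    ## consensus"); decoy-CDS training promoters carry more noise.
    trnaMotif <- promoterTemplate(strength = 0.95)
    motif <- promoterTemplate(strength = 0.85)
    acs <- sub(".*\\(([A-Z]+)\\)", "\\1", chartr("U", "T", archaealAnticodons()))
    blocks <- list()
    k <- 0L
    for (i in seq_len(config$nStandard)) {
        k <- k + 1L
        blocks[[k]] <- plantStandard(acs[(i - 1L) %% length(acs) + 1L],
                                     id = sprintf("std%02d", i),
                                     gcBias = config$gcBias, motif = trnaMotif)
    }
    for (i in seq_len(config$nSplit)) {
        k <- k + 1L
        blocks[[k]] <- plantSplit(
            anticodon = c("GTC", "CTT")[(i - 1L) %% 2L + 1L],
            junction = config$splitJunctions[(i - 1L) %%
                                             length(config$splitJunctions) + 1L],
            stem = config$splitStems[(i - 1L) %% length(config$splitStems) + 1L],
            orientation = config$splitOrientations[(i - 1L) %%
                                                   length(config$splitOrientations) + 1L],
            id = sprintf("split%02d", i), gcBias = config$gcBias,
            motif = trnaMotif)
    }
    for (i in seq_len(config$nPermuted)) {
        k <- k + 1L
        blocks[[k]] <- plantPermuted(
            anticodon = c("CAT", "GTA")[(i - 1L) %% 2L + 1L],
            junction = config$permutedJunction,
            intervening = sample(1:7, 1L),
            intronLen = config$permutedIntron,
            id = sprintf("perm%02d", i), gcBias = config$gcBias,
            motif = trnaMotif)
    }
    for (i in seq_len(config$nCds)) {
        k <- k + 1L
        blocks[[k]] <- .plantCds(sprintf("cds%02d", i), motif,
                                 known = (i %% 4L != 0L),
                                 operon = (i %% 3L == 0L))
    }
    ## random order and strand
    ord <- sample.int(length(blocks))
    blocks <- blocks[ord]
    flip <- runif(length(blocks)) < 0.5
    for (i in which(flip)) blocks[[i]] <- .flipBlock(blocks[[i]])
    lens <- vapply(blocks, function(b) length(b$block), integer(1))
    nb <- length(blocks)
    extra <- config$genomeLength - sum(lens) - (nb + 1L) * config$minSpacing
    if (extra < 0L)
        stop("infeasible packing: features exceed the genome length")
    props <- runif(nb + 1L)
    gaps <- config$minSpacing + floor(props / sum(props) * extra)
    gaps[nb + 1L] <- config$genomeLength - sum(lens) - sum(gaps[seq_len(nb)])
    pieces <- vector("list", 2L * nb + 1L)
    offsets <- integer(nb)
    pos <- 0L
    for (i in seq_len(nb)) {
        pieces[[2L * i - 1L]] <- .sampleBg(config$bg, gaps[i])
        pos <- pos + gaps[i]
        offsets[i] <- pos
        pieces[[2L * i]] <- blocks[[i]]$block
        pos <- pos + lens[i]
    }
    pieces[[2L * nb + 1L]] <- .sampleBg(config$bg, gaps[nb + 1L])
    genomeInt <- unlist(pieces)
    stopifnot(length(genomeInt) == config$genomeLength)
    truth <- do.call(rbind, lapply(seq_len(nb), function(i) {
        tr <- blocks[[i]]$truth
        for (cc in c("fiveStart", "fiveEnd", "threeStart", "threeEnd"))
            tr[[cc]] <- tr[[cc]] + offsets[i]
        tr
    }))
    if (is.null(truth))
        truth <- .truthRow("x", "x", NA, NA)[0, , drop = FALSE]
    proms <- do.call(rbind, lapply(seq_len(nb), function(i) {
        pr <- blocks[[i]]$promoters
        if (is.null(pr) || nrow(pr) == 0L) return(NULL)
        pr$start <- pr$start + offsets[i]
        pr$end <- pr$end + offsets[i]
        pr
    }))
    genome <- Biostrings::DNAStringSet(intToDna(genomeInt))
    names(genome) <- "synthetic"
    cds <- truth[truth$class == "cds", , drop = FALSE]
    ann <- GenomicRanges::GRanges(
        seqnames = rep("synthetic", nrow(cds)),
        ranges = IRanges::IRanges(cds$fiveStart, cds$fiveEnd),
        strand = cds$fiveStrand)
    S4Vectors::mcols(ann)$type <- rep("CDS", nrow(cds))
    S4Vectors::mcols(ann)$ID <- cds$id
    S4Vectors::mcols(ann)$product <- cds$product
    list(genome = genome, truth = truth, promoters = proms,
         annotations = ann, config = config)
}

#' Write generator outputs to disk
#'
#' Writes the genome as wrapped FASTA, the ground truth as GFF3 and JSON,
#' and the planted promoters as TSV.
#'
#' @param sim result of [generateGenome()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeSyntheticGenome <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    writeGenomeFasta(sim$genome, fa)
    tsv <- file.path(dir, "truth.tsv")
    write.table(sim$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    js <- file.path(dir, "truth.json")
    jsonlite::write_json(sim$truth, js, dataframe = "rows", na = "null")
    pr <- file.path(dir, "promoters.tsv")
    write.table(sim$promoters, pr, sep = "\t", quote = FALSE, row.names = FALSE)
    gff <- file.path(dir, "annotations.gff3")
    .writeGff3(sim$annotations, gff)
    invisible(c(fa, tsv, js, pr, gff))
}
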