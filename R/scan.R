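## Whole-genome tRNA scanner.
##
## Detection is anchored on the most conserved block of the molecule, the
## T-loop (G53-T54-T55-C56-R57-A58 ... C61), which also forms the core of
## the internal RNA polymerase III-style B-box promoter. Anchors passing
## the profile are expanded by enumerating cloverleaf arm-length
## combinations (the 3' end of the molecule sits at a fixed offset from the
## anchor), scoring each and keeping assignments above the bit cutoff.
## Anchors with a paired T arm but no full-length fold trigger a search for
## a displaced acceptor 5' strand (canonical intron at Sprinzl 37/38) and,
## failing that, are emitted as candidate 3' tRNA halves. Anchors whose
## T-loop block is intact but whose T stem cannot pair locally are tested
## as candidate 5' halves of permuted genes (structure complete only up to
## the T loop).

## match counts of the 7-column T-loop block at every position; position p
## is the genomic index of Sprinzl 53.
.anchorScores <- function(b) {
    n <- length(b)
    if (n < 30L) return(integer(0))
    idx <- seq_len(n - 8L)
    m <- (b[idx] == 3L) +                     # G53
        (b[idx + 1L] == 4L) +                 # T54
        (b[idx + 2L] == 4L) +                 # T55
        (b[idx + 3L] == 2L) +                 # C56
        (b[idx + 4L] == 1L | b[idx + 4L] == 3L) +  # R57
        (b[idx + 5L] == 1L) +                 # A58
        (b[idx + 8L] == 2L)                   # C61
    m
}

## T-stem pairing check at anchor p (Sprinzl 53). Returns mismatch count
## and pair score for the 5 T-stem pairs, for a given cca flag.
.tArmAt <- function(b, p, cca) {
    c3 <- if (cca) 3L else 0L
    endc <- p + 20L + c3
    e5 <- (24:20) + c3
    e3 <- (8:12) + c3
    i <- endc - e5
    j <- endc - e3
    ok <- i >= 1L & j <= length(b)
    mm <- 5L
    sc <- -10
    if (all(ok)) {
        vi <- b[i]; vj <- b[j]
        vi[is.na(vi)] <- 5L; vj[is.na(vj)] <- 5L
        cls <- .PAIR$cls[cbind(vi, vj)]
        mm <- sum(cls == 0L)
        sc <- sum(.PAIR$score[cbind(vi, vj)])
    }
    list(mm = mm, score = sc)
}

## candidate variable-loop lengths at anchor p: those where U33/C32 land
## correctly (falls back to the full range when none do).
.vCandidates <- function(b, p) {
    vs <- 3:21
    p33 <- p - 15L - vs
    p32 <- p - 16L - vs
    ok <- p32 >= 1L & b[pmax(p33, 1L)] == 4L & b[pmax(p32, 1L)] == 2L
    ok[is.na(ok)] <- FALSE
    if (any(ok)) vs[ok] else vs
}

## Evaluate all arm combinations for a full gene ending at endc (view
## coordinates). Returns the best valid assignment or NULL.
.evalGeneAt <- function(b, endc, cca, vCand, consFloor = 12) {
    best <- NULL
    c3 <- if (cca) 3L else 0L
    acc3 <- b[(endc - 7L - c3):(endc - 1L - c3)]      # Sprinzl 66..72
    for (d in 3:4) for (dl in 4:12) for (v in vCand) {
        L <- 52L + 2L * d + dl + v + if (cca) 3L else 0L
        s <- endc - L + 1L
        if (s < 1L) next
        ## cheap precheck: acceptor stem with at most one non-pairing
        cls <- .PAIR$cls[(rev(acc3) - 1L) * 5L + b[s:(s + 6L)]]
        if (sum(cls == 0L) > 1L) next
        layout <- .cloverleafLayout(d, dl, v, cca)
        sc <- .scoreLayout(b[s:endc], layout)
        if (!.stemsValid(sc$mm) || sc$cons < consFloor) next
        if (is.null(best) || sc$score > best$score ||
            (sc$score == best$score && sc$wc > best$wc) ||
            (sc$score == best$score && sc$wc == best$wc && sc$gc > best$gc)) {
            best <- list(score = sc$score, wc = sc$wc, gc = sc$gc,
                         d = d, dl = dl, v = v, cca = cca, start = s, L = L)
        }
    }
    best
}

## Search for an intron-displaced gene: acceptor 5' strand found upstream,
## insert between Sprinzl 37 and 38. Returns best candidate or NULL.
.evalIntronGeneAt <- function(b, endc, cca, config) {
    c3 <- if (cca) 3L else 0L
    acc3 <- b[(endc - 7L - c3):(endc - 1L - c3)]      # Sprinzl 66..72
    if (anyNA(acc3)) return(NULL)
    sMin <- max(1L, endc - (110L + config@intronMax))
    sMax <- endc - (55L + config@intronMin)
    if (sMax < sMin) return(NULL)
    ss <- sMin:sMax
    pc <- integer(length(ss))
    for (k in 0:6) {
        vb <- b[ss + k]
        vb[is.na(vb)] <- 5L
        pc <- pc + as.integer(.PAIR$cls[cbind(vb, acc3[7L - k])] %in% 1:2)
    }
    cand <- ss[pc >= 6L]
    if (length(cand) == 0L) return(NULL)
    best <- NULL
    for (s in cand) {
        Ltot <- endc - s + 1L
        for (d in 3:4) for (dl in 4:12) {
            len5 <- 21L + 2L * d + dl                  # Sprinzl 1..37
            ## D stem lies entirely in the 5' exon: precheck cheaply
            kd <- seq_len(d)
            cls <- .PAIR$cls[(b[s + (10L + d + dl + d - kd) - 1L] - 1L) * 5L +
                             b[s + (9L + kd) - 1L]]
            if (sum(cls == 0L | cls == 3L) > 1L) next
            for (v in 3:21) {
                L <- 52L + 2L * d + dl + v + c3
                iv <- Ltot - L
                if (iv < config@intronMin || iv > config@intronMax) next
                len3 <- L - len5
                spl <- c(b[s:(s + len5 - 1L)], b[(endc - len3 + 1L):endc])
                layout <- .cloverleafLayout(d, dl, v, cca)
                sc <- .scoreLayout(spl, layout)
                if (!.stemsValid(sc$mm) || sc$cons < config@consFloor) next
                if (is.null(best) || sc$score > best$score) {
                    best <- list(score = sc$score, d = d, dl = dl, v = v,
                                 cca = cca, start = s, L = L, iv = iv,
                                 len5 = len5, len3 = len3)
                }
            }
        }
    }
    if (is.null(best)) return(NULL)
    ## require a BHB at the intron boundaries (splice sites at 37/38)
    cut1 <- best$start + best$len5 - 1L
    e2 <- endc - best$len3 + 1L
    ctx1 <- .safeSlice(b, cut1 - 14L, cut1 + 15L)
    ctx2 <- .safeSlice(b, e2 - 16L, e2 + 14L)
    bhb <- findBhb(intToDna(ctx1$v), ctx1$site(cut1), intToDna(ctx2$v),
                   ctx2$site(e2 - 1L))
    if (nrow(bhb) == 0L) return(NULL)
    best$bhbClass <- bhb$strictness[1L]
    best
}

## slice with bounds clamping; $site(i) converts an absolute position to
## "residues before the cut after position i" within the slice.
.safeSlice <- function(b, from, to) {
    from <- max(1L, from); to <- min(length(b), to)
    v <- b[from:to]
    v[is.na(v)] <- 5L
    list(v = v, from = from, site = function(i) i - from + 1L)
}

## Evaluate a candidate permuted-gene 5' part (Sprinzl 1..59) anchored at
## p, optionally with a canonical intron of length iv at 37/38.
.evalFivePartCombo <- function(b, p, d, dl, v, iv) {
    idx53 <- 32L + 2L * d + dl + v
    len5i <- 21L + 2L * d + dl                    # Sprinzl 1..37
    s <- p - idx53 + 1L - iv
    if (s < 1L) return(NULL)
    endp <- p + 6L                                # Sprinzl 59
    if (endp > length(b)) return(NULL)
    ## cheap arithmetic precheck: both local stems must pair perfectly
    sAc5 <- 11L + 2L * d + dl; sAc3 <- 23L + 2L * d + dl
    k <- 1:5
    gi <- s + (sAc5 + k - 1L) - 1L
    gj <- s + iv + (sAc3 + 5L - k) - 1L
    cls <- .PAIR$cls[cbind(b[gi], b[gj])]
    if (any(cls == 0L | cls == 3L)) return(NULL)
    kd <- seq_len(d)
    gi <- s + (9L + kd) - 1L
    gj <- s + (10L + d + dl + d - kd) - 1L
    cls <- .PAIR$cls[cbind(b[gi], b[gj])]
    if (any(cls == 0L | cls == 3L)) return(NULL)
    layout <- .cloverleafLayout(d, dl, v, FALSE)
    part <- if (iv > 0L) {
        c(b[s:(s + len5i - 1L)], b[(s + len5i + iv):endp])
    } else b[s:endp]
    part[is.na(part)] <- 5L
    nidx <- length(part)
    keep <- layout$pairs[, 1L] <= nidx & layout$pairs[, 2L] <= nidx
    stems <- layout$stems[keep]
    pr <- layout$pairs[keep, , drop = FALSE]
    cls <- .PAIR$cls[cbind(part[pr[, 1L]], part[pr[, 2L]])]
    psc <- .PAIR$score[cbind(part[pr[, 1L]], part[pr[, 2L]])]
    ## candidate 5' parts must pair both local stems perfectly: with the T
    ## stem unavailable this is the only strong structural evidence
    if (any(cls[stems %in% c("d", "ac")] == 0L)) return(NULL)
    ck <- layout$cons$idx <= nidx
    cb <- part[layout$cons$idx[ck]]
    exp <- layout$cons$base[ck]
    hit <- cb == exp | (exp == 0L & (cb == 1L | cb == 3L))
    csc <- sum(ifelse(hit, layout$cons$w[ck], -layout$cons$w[ck] / 2))
    score <- sum(psc[stems %in% c("d", "ac")]) + csc
    list(score = score, d = d, dl = dl, v = v, start = s, end = endp, iv = iv)
}

.evalFivePartAt <- function(b, p, iv = 0L) {
    best <- NULL
    for (d in 3:4) for (dl in 4:12) for (v in 3:21) {
        cand <- .evalFivePartCombo(b, p, d, dl, v, iv)
        if (!is.null(cand) && (is.null(best) || cand$score > best$score))
            best <- cand
    }
    best
}

## find a displaced acceptor/D-arm block (canonical intron inside the 5'
## part): search upstream for the anticodon 5' stem pairing acstem3.
.evalFivePartIntron <- function(b, p, config) {
    ## candidate (v, iv) pairs are bounded by requiring C32/U33 to land
    ## correctly once the 5'-of-intron block is displaced by iv
    ivs <- config@intronMin:config@intronMax
    best <- NULL
    for (v in 3:21) {
        p33 <- p - 15L - v - ivs
        p32 <- p33 - 1L
        ok <- p32 >= 1L & b[pmax(p33, 1L)] == 4L & b[pmax(p32, 1L)] == 2L
        ok[is.na(ok)] <- FALSE
        for (iv in ivs[ok]) {
            for (d in 3:4) for (dl in 4:12) {
                cand <- .evalFivePartCombo(b, p, d, dl, v, iv)
                if (!is.null(cand) && (is.null(best) || cand$score > best$score))
                    best <- cand
            }
        }
    }
    best
}

.scanStrand <- function(b, config) {
    n <- length(b)
    b5 <- b; b5[is.na(b5)] <- 5L
    ## T-loop block without the C61 column (absent from permuted 5' parts)
    m <- .anchorScores(b5)
    idx <- seq_len(max(0L, n - 8L))
    m6 <- m - as.integer(b5[idx + 8L] == 2L)
    anchors <- which(m >= 6L | m6 == 6L)
    anchors <- anchors[anchors > 60L & anchors + 30L <= n]
    genes <- list()
    frag3 <- list()
    frag5 <- list()
    fivePartBits <- config@cutoffBits + 6     # see vignette: above what
    ## free arm-length selection achieves on background sequence
    for (p in anchors) {
        tcc <- list(`FALSE` = .tArmAt(b5, p, FALSE), `TRUE` = .tArmAt(b5, p, TRUE))
        tValid <- tcc$`TRUE`$mm <= 1L || tcc$`FALSE`$mm <= 1L
        if (tValid && m[p] >= 6L) {
            vCand <- .vCandidates(b5, p)
            best <- NULL
            for (cca in c(TRUE, FALSE)) {
                if (tcc[[as.character(cca)]]$mm > 1L) next
                endc <- p + 20L + if (cca) 3L else 0L
                if (endc > n) next
                cand <- .evalGeneAt(b5, endc, cca, vCand, config@consFloor)
                if (!is.null(cand) && (is.null(best) || cand$score > best$score))
                    best <- cand
            }
            if (!is.null(best) && best$score < config@cutoffBits &&
                !identical(vCand, 3:21)) {
                ## fallback: unpruned enumeration before giving up
                for (cca in c(TRUE, FALSE)) {
                    if (tcc[[as.character(cca)]]$mm > 1L) next
                    endc <- p + 20L + if (cca) 3L else 0L
                    if (endc > n) next
                    cand <- .evalGeneAt(b5, endc, cca, 3:21, config@consFloor)
                    if (!is.null(cand) && cand$score > best$score) best <- cand
                }
            }
            if (!is.null(best) && best$score >= config@cutoffBits) {
                genes[[length(genes) + 1L]] <-
                    .geneRecord(b5, best, p, intron = NULL)
                next
            }
            ## intron-displaced full gene
            ibest <- NULL
            for (cca in c(TRUE, FALSE)) {
                if (tcc[[as.character(cca)]]$mm > 1L) next
                endc <- p + 20L + if (cca) 3L else 0L
                if (endc > n) next
                cand <- .evalIntronGeneAt(b5, endc, cca, config)
                if (!is.null(cand) && (is.null(ibest) || cand$score > ibest$score))
                    ibest <- cand
            }
            if (!is.null(ibest) && ibest$score >= config@cutoffBits) {
                genes[[length(genes) + 1L]] <- .geneRecord(b5, ibest, p,
                                                           intron = ibest)
                next
            }
        }
        ## no gene at this anchor: candidate 3' half
        if (m[p] == 7L && tValid) {
            cca <- tcc$`TRUE`$mm <= tcc$`FALSE`$mm
            tsc <- tcc[[as.character(cca)]]
            endc <- p + 20L + if (cca) 3L else 0L
            if (endc <= n && tsc$mm == 0L) {
                partial <- tsc$score + 5  # T stem + conserved block
                if (partial >= config@fragmentBits)
                    frag3[[length(frag3) + 1L]] <- data.frame(
                        kind = "three_prime", start = max(1L, endc - 34L),
                        end = endc, score = partial, cca = cca,
                        d = NA_integer_, dl = NA_integer_, v = NA_integer_,
                        intronLen = 0L, stringsAsFactors = FALSE)
            }
        }
        ## candidate permuted 5' part (structure complete up to the T loop)
        if (m6[p] == 6L) {
            cand <- .evalFivePartAt(b5, p)
            if (is.null(cand) || cand$score < fivePartBits)
                cand <- .evalFivePartIntron(b5, p, config)
            if (!is.null(cand) && cand$score >= fivePartBits)
                frag5[[length(frag5) + 1L]] <- data.frame(
                    kind = "five_prime", start = cand$start, end = cand$end,
                    score = cand$score, cca = NA,
                    d = cand$d, dl = cand$dl, v = cand$v,
                    intronLen = cand$iv, stringsAsFactors = FALSE)
        }
    }
    list(genes = genes, frag3 = frag3, frag5 = frag5)
}

.geneRecord <- function(b, best, p, intron = NULL) {
    endc <- best$start + best$L - 1L + if (is.null(intron)) 0L else intron$iv
    if (!is.null(intron)) {
        mature <- c(b[best$start:(best$start + intron$len5 - 1L)],
                    b[(endc - intron$len3 + 1L):endc])
    } else {
        mature <- b[best$start:endc]
    }
    d <- best$d; dl <- best$dl
    idx34 <- 18L + 2L * d + dl
    ac <- intToDna(mature[idx34:(idx34 + 2L)])
    data.frame(start = best$start, end = endc, score = best$score,
               d = d, dl = dl, v = best$v, cca = best$cca,
               anticodon = ac, isotype = anticodonToIsotype(ac),
               matureSeq = intToDna(mature),
               intronLen = if (is.null(intron)) 0L else intron$iv,
               intronOffset = if (is.null(intron)) NA_integer_ else intron$len5,
               intronSprinzl = if (is.null(intron)) NA_character_ else "37/38",
               bhbClass = if (is.null(intron)) NA_character_ else intron$bhbClass,
               stringsAsFactors = FALSE)
}

.flipCoords <- function(df, n) {
    if (nrow(df) == 0L) return(df)
    s <- df$start; e <- df$end
    df$start <- n - e + 1L
    df$end <- n - s + 1L
    df
}

#' Scan a genome for tRNA genes and tRNA gene fragments
#'
#' Both strands are scanned with a T-loop/B-box anchor pre-filter followed
#' by cloverleaf constraint folding; canonical introns (between Sprinzl 37
#' and 38, length within the configured range, bounded by a BHB) are
#' detected by allowing a displaced acceptor/D-arm block. Overlapping hits
#' are resolved to the best score. Anchors with a supported T arm but no
#' qualifying gene are emitted as candidate 3' halves; anchors whose T-loop
#' block is intact but cannot pair a downstream T stem are evaluated as
#' candidate permuted 5' parts (structure complete up to the T loop, with
#' or without a canonical intron). Fragment scores are partial-structure
#' scores and lie below the gene cutoff by construction.
#'
#' @param genome a `DNAString`, character string, or named `DNAStringSet`
#'   of length 1.
#' @param config a [RunConfig-class] (default [runConfig()]).
#' @param seqid sequence name used in the returned ranges.
#' @return list with elements `genes` and `fragments`, both `GRanges` with
#'   metadata columns (isotype, anticodon, score, arm lengths, mature
#'   sequence and intron annotation for genes; kind, score, structural
#'   guesses for fragments).
#' @export
scanGenome <- function(genome, config = runConfig(), seqid = NULL) {
    if (is(genome, "DNAStringSet")) {
        if (is.null(seqid)) seqid <- names(genome)[1]
        genome <- genome[[1]]
    }
    if (is.null(seqid)) seqid <- "genome"
    chr <- as.character(genome)
    bPlus <- dnaToInt(chr)
    n <- length(bPlus)
    bMinus <- revCompInt(bPlus)
    resP <- .scanStrand(bPlus, config)
    resM <- .scanStrand(bMinus, config)
    bindRows <- function(lst) if (length(lst)) do.call(rbind, lst) else NULL
    gP <- bindRows(resP$genes); gM <- bindRows(resM$genes)
    if (!is.null(gM)) gM <- .flipCoords(gM, n)
    genes <- rbind(
        if (!is.null(gP)) cbind(gP, strand = "+", stringsAsFactors = FALSE),
        if (!is.null(gM)) cbind(gM, strand = "-", stringsAsFactors = FALSE))
    fP <- bindRows(c(resP$frag3, resP$frag5))
    fM <- bindRows(c(resM$frag3, resM$frag5))
    if (!is.null(fM)) fM <- .flipCoords(fM, n)
    frags <- rbind(
        if (!is.null(fP)) cbind(fP, strand = "+", stringsAsFactors = FALSE),
        if (!is.null(fM)) cbind(fM, strand = "-", stringsAsFactors = FALSE))
    ## overlap resolution: keep best-scoring, deterministic order
    if (!is.null(genes) && nrow(genes) > 1L) {
        genes <- genes[order(-genes$score, genes$start), , drop = FALSE]
        keep <- rep(TRUE, nrow(genes))
        for (i in seq_len(nrow(genes))) {
            if (!keep[i]) next
            if (i < nrow(genes)) for (j in (i + 1L):nrow(genes)) {
                if (keep[j] && genes$start[j] <= genes$end[i] &&
                    genes$end[j] >= genes$start[i]) keep[j] <- FALSE
            }
        }
        genes <- genes[keep, , drop = FALSE]
        genes <- genes[order(genes$start), , drop = FALSE]
    }
    ## drop fragments overlapping called genes
    if (!is.null(frags) && nrow(frags) > 0L && !is.null(genes) && nrow(genes) > 0L) {
        keep <- vapply(seq_len(nrow(frags)), function(i) {
            !any(frags$start[i] <= genes$end & frags$end[i] >= genes$start)
        }, TRUE)
        frags <- frags[keep, , drop = FALSE]
    }
    .asGeneRanges(genes, frags, seqid)
}

.asGeneRanges <- function(genes, frags, seqid) {
    toGR <- function(df, cols) {
        if (is.null(df) || nrow(df) == 0L) {
            gr <- GenomicRanges::GRanges()
            return(gr)
        }
        gr <- GenomicRanges::GRanges(
            seqnames = seqid,
            ranges = IRanges::IRanges(start = df$start, end = df$end),
            strand = df$strand)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[, cols, drop = FALSE])
        gr
    }
    list(genes = toGR(genes, c("score", "d", "dl", "v", "cca", "anticodon",
                               "isotype", "matureSeq", "intronLen",
                               "intronOffset", "intronSprinzl", "bhbClass")),
         fragments = toGR(frags, c("kind", "score", "cca", "d", "dl", "v",
                                   "intronLen")))
}
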