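## Circularly permuted tRNA detection. Triggered by promoter-spacing
## outliers: a promoter displaced well upstream of a candidate 5' part
## suggests that the 3' part of the molecule (T stem 3' strand, acceptor
## 3' strand, discriminator, CCA) lies between the promoter and the
## mature 5' end, transcribed as one precursor whose termini form a BHB.

## Re-examine a promoter-spacing-outlier gene as a candidate permuted 5'
## part: a permuted precursor can fold into a spurious low-quality
## cloverleaf spanning the intervening sequence, so the original gene call
## is re-evaluated at its own T-loop anchor under the 5'-part model.
.fivePartFromGene <- function(gene, fragId, views, config) {
    mc <- S4Vectors::mcols(gene)
    strand <- as.character(GenomicRanges::strand(gene))[1]
    sigma <- if (strand == "-") "m" else "p"
    b <- views[[sigma]]
    gv <- .genomicToView(strand, GenomicRanges::start(gene)[1],
                         GenomicRanges::end(gene)[1], views$n)
    idx53 <- 32L + 2L * mc$d + mc$dl + mc$v
    p <- gv[1] + idx53 - 1L
    cand <- .evalFivePartAt(b, p)
    if (is.null(cand) || cand$score < config@cutoffBits + 6)
        cand <- .evalFivePartIntron(b, p, config)
    if (is.null(cand) || cand$score < config@cutoffBits + 6) return(NULL)
    gg <- .viewToGenomic(strand, cand$start, cand$end, views$n)
    gr <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gene))[1],
                                 IRanges::IRanges(gg[1], gg[2]), strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        kind = "five_prime", score = cand$score, cca = NA,
        d = cand$d, dl = cand$dl, v = cand$v, intronLen = cand$iv,
        fragId = fragId)
    gr
}

#' Detect circularly permuted tRNA genes
#'
#' For every 5'-part fragment whose promoter offset is flagged as a
#' spacing outlier, the region between the promoter and the fragment's
#' mature start is searched for a matching 3' part. T-loop junctions are
#' enumerated (Sprinzl 57/58 to 59/60); a candidate is reported when the
#' joined mature sequence folds above the bit cutoff and a canonical
#' hBHBh' forms across the precursor termini. Canonical introns detected
#' inside the 5' part are carried through and reported.
#'
#' @param fragments `GRanges` of fragments from [scanGenome()] (only
#'   `five_prime` rows are used).
#' @param outliers `data.frame` with `geneId`, `offset`, `outlier` as
#'   produced by [spacingOutliers()]; `geneId` must match
#'   `names(fragments)` or `fragments$fragId`.
#' @param genome genome sequence.
#' @param config a [RunConfig-class].
#' @return `DataFrame` of permuted candidates (isotype, anticodon,
#'   junction, intervening length, canonical-intron flag, joined score,
#'   BHB class, promoter offset, part loci).
#' @export
detectPermuted <- function(fragments, outliers, genome,
                           config = runConfig()) {
    views <- .genomeViews(genome)
    mc <- S4Vectors::mcols(fragments)
    ids <- if (!is.null(mc$fragId)) mc$fragId else if (!is.null(names(fragments)))
        names(fragments) else paste0("frag", seq_along(fragments))
    rows <- list()
    fl <- which(mc$kind == "five_prime")
    for (i in fl) {
        hit <- outliers[outliers$geneId == ids[i], , drop = FALSE]
        if (nrow(hit) == 0L || !isTRUE(hit$outlier[1])) next
        sigma <- if (as.character(GenomicRanges::strand(fragments))[i] == "-")
            "m" else "p"
        vw <- views[[sigma]]
        gv <- .genomicToView(if (sigma == "p") "+" else "-",
                             GenomicRanges::start(fragments)[i],
                             GenomicRanges::end(fragments)[i], views$n)
        vs <- gv[1]
        d <- mc$d[i]; dl <- mc$dl[i]; v <- mc$v[i]
        iv <- mc$intronLen[i]
        if (is.na(d)) next
        promEnd <- vs + hit$offset[1] + config@motifWidth - 1L
        len5i <- 21L + 2L * d + dl                  # Sprinzl 1..37
        best <- NULL
        for (j in 57:59) {
            idxj <- .cloverleafLayout(d, dl, v, FALSE)
            lenj <- match(as.character(j), idxj$sprinzl)
            if (is.na(lenj)) next
            fiveMature <- if (iv > 0L) {
                c(vw[vs:(vs + len5i - 1L)],
                  vw[(vs + len5i + iv):(vs + lenj - 1L + iv)])
            } else vw[vs:(vs + lenj - 1L)]
            cut1 <- vs + lenj - 1L + iv
            for (cca in c(TRUE, FALSE)) {
                L <- 52L + 2L * d + dl + v + if (cca) 3L else 0L
                len3 <- L - lenj
                layout <- .cloverleafLayout(d, dl, v, cca)
                pLo <- max(1L, promEnd - 5L)
                pHi <- vs - len3
                if (pHi < pLo) next
                for (p in pLo:pHi) {
                    joined <- c(fiveMature, vw[p:(p + len3 - 1L)])
                    sc <- .scoreLayout(joined, layout)
                    if (!.stemsValid(sc$mm)) next
                    if (sc$score < config@cutoffBits) next
                    ## ties (junction residue unpaired and unconserved) go
                    ## to the larger junction: ambiguous residues are
                    ## assigned to the mature gene, not the intervening
                    ## sequence
                    if (!is.null(best) && (sc$score < best$score ||
                        (sc$score == best$score && j <= best$j))) next
                    best <- list(score = sc$score, j = j, cca = cca, p = p,
                                 len3 = len3, lenj = lenj, cut1 = cut1,
                                 joined = intToDna(joined), layout = layout)
                }
            }
        }
        if (is.null(best)) next
        ## BHB across the precursor termini
        n <- length(vw)
        ctx1 <- vw[max(1L, best$cut1 - 14L):min(n, best$cut1 + 15L)]
        site1 <- best$cut1 - max(1L, best$cut1 - 14L) + 1L
        ctx2 <- vw[max(1L, best$p - 15L):min(n, best$p + 14L)]
        site2 <- best$p - max(1L, best$p - 15L)
        bhb <- findBhb(intToDna(ctx1), site1, intToDna(ctx2), site2)
        if (!.hasCanonicalBhb(bhb)) next
        fg <- .viewToGenomic(if (sigma == "p") "+" else "-",
                             vs, best$cut1, views$n)
        tg <- .viewToGenomic(if (sigma == "p") "+" else "-",
                             best$p, best$p + best$len3 - 1L, views$n)
        strand <- if (sigma == "p") "+" else "-"
        idx34 <- 18L + 2L * d + dl
        ac <- substr(best$joined, idx34, idx34 + 2L)
        rows[[length(rows) + 1L]] <- data.frame(
            isotype = anticodonToIsotype(ac, imet = identical(ac, "CAT")),
            anticodon = ac,
            junction = paste0(best$j, "/", best$j + 1L),
            intervening = as.integer(vs - (best$p + best$len3)),
            intronPresent = iv > 0L,
            intronLen = as.integer(iv),
            intronSprinzl = if (iv > 0L) "37/38" else NA_character_,
            joinedScore = best$score, bhbClass = "canonical_hBHBh",
            promoterOffset = hit$offset[1],
            fiveStart = fg[1], fiveEnd = fg[2],
            threeStart = tg[1], threeEnd = tg[2], strand = strand,
            joinedSeq = best$joined, stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) {
        return(S4Vectors::DataFrame(data.frame(
            isotype = character(0), anticodon = character(0),
            junction = character(0), intervening = integer(0),
            intronPresent = logical(0), intronLen = integer(0),
            intronSprinzl = character(0), joinedScore = numeric(0),
            bhbClass = character(0), promoterOffset = integer(0),
            fiveStart = integer(0), fiveEnd = integer(0),
            threeStart = integer(0), threeEnd = integer(0),
            strand = character(0), joinedSeq = character(0),
            stringsAsFactors = FALSE)))
    }
    S4Vectors::DataFrame(do.call(rbind, rows))
}
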