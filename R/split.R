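## Split (trans-spliced) tRNA assembly and validation.

## strand-space views of a genome: integer-coded plus strand, its reverse
## complement, and coordinate mapping helpers.
.genomeViews <- function(genome) {
    if (is(genome, "DNAStringSet")) genome <- genome[[1]]
    chr <- as.character(genome)
    bp <- dnaToInt(chr)
    bp[is.na(bp)] <- 5L
    list(p = bp, m = revCompInt(bp), n = length(bp), chr = chr)
}

.viewToGenomic <- function(strand, s, e, n) {
    if (strand == "+") c(s, e) else c(n - e + 1L, n - s + 1L)
}

.genomicToView <- function(strand, gs, ge, n) {
    if (strand == "+") c(gs, ge) else c(n - ge + 1L, n - gs + 1L)
}

#' Join two tRNA half fragments at a splice junction
#'
#' Concatenates the mature parts of a 5' and a 3' fragment; the inverse of
#' [cutTrna()]. The fragment Sprinzl spans must abut exactly at the
#' junction.
#'
#' @param five,three fragment lists with fields `kind`, `seq`,
#'   `sprinzlFrom`, `sprinzlTo` (as produced by [cutTrna()]).
#' @param junction optional Sprinzl cut position `a` (or `"a/b"`); defaults
#'   to the 5' fragment's last covered position.
#' @return the joined nucleotide string.
#' @export
joinSplit <- function(five, three, junction = NULL) {
    if (!identical(five$kind, "five_prime") ||
        !identical(three$kind, "three_prime"))
        stop("assembly error: need one five_prime and one three_prime fragment")
    a <- if (is.null(junction)) suppressWarnings(as.integer(five$sprinzlTo))
         else if (is.character(junction)) as.integer(sub("/.*", "", junction))
         else as.integer(junction)
    fTo <- suppressWarnings(as.integer(five$sprinzlTo))
    tFrom <- suppressWarnings(as.integer(three$sprinzlFrom))
    if (is.na(fTo) || is.na(tFrom) || fTo != a || tFrom != a + 1L)
        stop("assembly error: fragment spans leave a gap or overlap at the junction")
    paste0(five$seq, three$seq)
}

#' Genomic span of a candidate cis intron between two half loci
#'
#' When a split locus could instead be transcribed as one read-through
#' precursor, the distance between the 3' end of the 5' exon and the 5'
#' start of the 3' exon is the length of the implied intron. Returns NA
#' (not applicable) when the fragments lie on different strands or in the
#' wrong order for a single transcript.
#'
#' @param five,three length-1 `GRanges` (or lists with `start`, `end`,
#'   `strand`) of the 5' and 3' exon loci.
#' @return integer span in nt, or `NA_integer_`.
#' @export
cisIntronSpan <- function(five, three) {
    loc <- function(x) {
        if (is(x, "GRanges"))
            list(start = GenomicRanges::start(x)[1],
                 end = GenomicRanges::end(x)[1],
                 strand = as.character(GenomicRanges::strand(x))[1])
        else x
    }
    f <- loc(five); t3 <- loc(three)
    if (!identical(f$strand, t3$strand)) return(NA_integer_)
    if (f$strand == "+") {
        if (t3$start <= f$end) return(NA_integer_)
        as.integer(t3$start - f$end - 1L)
    } else {
        if (f$start <= t3$end) return(NA_integer_)
        as.integer(f$start - t3$end - 1L)
    }
}

#' Classify tRNA introns and validate their splice-junction structure
#'
#' Inserts between Sprinzl 37 and 38 are canonical; anywhere else,
#' noncanonical. Each intron is validated by [findBhb()] at its
#' boundaries.
#'
#' @param gene either a length-1 `GRanges` from [scanGenome()] (with
#'   intron metadata columns) together with `genome`, or a list with
#'   fields `precursor` (nucleotide string), `exon1Len`, `intronLen` and
#'   `sprinzl` (e.g. `"32/33"`).
#' @param genome the genome sequence (required for `GRanges` input).
#' @return data.frame with columns `sprinzl`, `length`, `class`,
#'   `bhbClass` (NA when no BHB forms); zero rows for intronless genes.
#' @export
classifyIntron <- function(gene, genome = NULL) {
    empty <- data.frame(sprinzl = character(0), length = integer(0),
                        class = character(0), bhbClass = character(0),
                        stringsAsFactors = FALSE)
    if (is(gene, "GRanges")) {
        mc <- S4Vectors::mcols(gene)
        if (length(gene) != 1L) stop("one gene at a time")
        if (is.na(mc$intronLen) || mc$intronLen == 0L) return(empty)
        if (is.null(genome)) stop("genome required to validate the BHB")
        pre <- extractInterval(
            if (is(genome, "DNAStringSet")) genome else
                setNames(Biostrings::DNAStringSet(list(genome)),
                         as.character(GenomicRanges::seqnames(gene))[1]),
            gene)
        gene <- list(precursor = pre, exon1Len = mc$intronOffset,
                     intronLen = mc$intronLen, sprinzl = mc$intronSprinzl)
    }
    if (is.na(gene$intronLen) || gene$intronLen == 0L) return(empty)
    v <- dnaToInt(gene$precursor)
    v[is.na(v)] <- 5L
    cut1 <- gene$exon1Len
    e2 <- cut1 + gene$intronLen + 1L
    s1 <- max(1L, cut1 - 14L)
    ctx1 <- v[s1:min(length(v), cut1 + 15L)]
    s2 <- max(1L, e2 - 16L)
    ctx2 <- v[s2:min(length(v), e2 + 13L)]
    bhb <- tryCatch(findBhb(intToDna(ctx1), cut1 - s1 + 1L,
                            intToDna(ctx2), e2 - s2),
                    error = function(e) NULL)
    data.frame(sprinzl = gene$sprinzl, length = gene$intronLen,
               class = if (identical(gene$sprinzl, "37/38")) "canonical"
                       else "noncanonical",
               bhbClass = if (!is.null(bhb) && nrow(bhb)) bhb$strictness[1]
                          else NA_character_,
               stringsAsFactors = FALSE)
}

## evaluate one candidate split join; returns best row or NULL
.evalSplitJoin <- function(views, sigma, tau, veSigma, armStartTau,
                           arm2EndSigma, stemLen, config) {
    vT <- views[[tau]]; vS <- views[[sigma]]
    best <- NULL
    for (u2 in 1:2) {
        exon2Start <- arm2EndSigma + u2 + 1L
        len3 <- veSigma - exon2Start + 1L
        if (len3 < 15L || len3 > 95L) next
        for (u1 in 1:2) {
            e1 <- armStartTau - 8L + u1
            if (e1 < 60L) next
            for (cca in c(TRUE, FALSE)) for (d in 3:4) for (dl in 4:12)
                for (v in 3:21) {
                L <- 52L + 2L * d + dl + v + if (cca) 3L else 0L
                len5 <- L - len3
                if (len5 < 8L || len5 >= L) next
                layout <- .cloverleafLayout(d, dl, v, cca)
                aLab <- suppressWarnings(as.integer(layout$sprinzl[len5]))
                bLab <- suppressWarnings(as.integer(layout$sprinzl[len5 + 1L]))
                if (is.na(aLab) || is.na(bLab) || bLab != aLab + 1L) next
                if (aLab < config@junctionMin ||
                    aLab > min(config@junctionMax, 59L)) next
                s1 <- e1 - len5 + 1L
                if (s1 < 1L) next
                joined <- c(vT[s1:e1], vS[exon2Start:veSigma])
                sc <- .scoreLayout(joined, layout)
                if (!.stemsValid(sc$mm)) next
                if (sc$score < config@cutoffBits) next
                ## exact ties (junction residue unpaired and unconserved)
                ## go to the larger junction, assigning the ambiguous
                ## residue to the 5' exon rather than the junction context
                if (!is.null(best) && (sc$score < best$score ||
                    (sc$score == best$score && aLab <= best$junction))) next
                best <- list(score = sc$score, junction = aLab,
                             u1 = u1, u2 = u2, s1 = s1, e1 = e1,
                             exon2Start = exon2Start, len5 = len5,
                             len3 = len3, joined = intToDna(joined),
                             layout = layout)
            }
        }
    }
    if (is.null(best)) return(NULL)
    ## BHB validation at the chosen junction
    n1 <- length(vT)
    ctx1 <- vT[max(1L, best$e1 - 14L):min(n1, best$e1 + 15L)]
    site1 <- best$e1 - max(1L, best$e1 - 14L) + 1L
    n2 <- length(vS)
    ctx2 <- vS[max(1L, best$exon2Start - 15L):min(n2, best$exon2Start + 14L)]
    site2 <- best$exon2Start - max(1L, best$exon2Start - 15L)
    bhb <- findBhb(intToDna(ctx1), site1, intToDna(ctx2), site2)
    if (!.hasCanonicalBhb(bhb)) return(NULL)
    best$bhbClass <- "canonical_hBHBh"
    best$stemLen <- stemLen
    best
}

#' Search for trans-pairing partners of orphan 3' tRNA halves
#'
#' For each orphan 3'-half fragment, seeds (12-mers) from the 40-90 nt
#' region upstream of its mature start are matched in reverse complement
#' against both genome strands; each seed hit is extended to the maximal
#' trans-pairing duplex and, when the stem reaches the configured minimum,
#' a 5'-half placement is reconstructed from the duplex geometry. Splice
#' junctions are enumerated over the configured Sprinzl range by arm-length
#' combination; candidates are kept when the joined sequence folds above
#' the bit cutoff and a canonical hBHBh' forms at the junction.
#'
#' @param fragments `GRanges` of fragments from [scanGenome()] (only
#'   `three_prime` rows are used).
#' @param genome genome sequence (`DNAString`, character, or
#'   `DNAStringSet`).
#' @param config a [RunConfig-class].
#' @return `DataFrame` of split candidates (isotype, anticodon, junction,
#'   trans-stem length, BHB class, joined score, orientation, separation,
#'   half loci, joined sequence).
#' @export
searchSplitPartners <- function(fragments, genome, config = runConfig()) {
    views <- .genomeViews(genome)
    dnas <- list(p = Biostrings::DNAString(intToDna(views$p)),
                 m = Biostrings::DNAString(intToDna(views$m)))
    orphans <- fragments[S4Vectors::mcols(fragments)$kind == "three_prime"]
    rows <- list()
    for (i in seq_along(orphans)) {
        sigma <- if (as.character(GenomicRanges::strand(orphans))[i] == "-")
            "m" else "p"
        gv <- .genomicToView(if (sigma == "p") "+" else "-",
                             GenomicRanges::start(orphans)[i],
                             GenomicRanges::end(orphans)[i], views$n)
        ve <- gv[2]
        w2s <- max(1L, ve - 110L); w2e <- ve - 17L
        if (w2e - w2s < 20L) next
        W2 <- views[[sigma]][w2s:w2e]
        W2seq <- intToDna(W2)
        kmers <- unique(substring(W2seq, 1:(nchar(W2seq) - 11L),
                                  12:nchar(W2seq)))
        kmers <- kmers[!grepl("N", kmers)]
        if (length(kmers) == 0L) next
        pd <- Biostrings::PDict(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(kmers)))
        best <- NULL
        for (tau in c("p", "m")) {
            mt <- Biostrings::matchPDict(pd, dnas[[tau]])
            starts <- sort(unique(unlist(lapply(mt, BiocGenerics::start))))
            if (length(starts) == 0L) next
            ## merge hits closer than 25 nt into candidate regions
            grp <- cumsum(c(TRUE, diff(starts) > 25L))
            for (g in unique(grp)) {
                q0 <- min(starts[grp == g]); q1 <- max(starts[grp == g]) + 11L
                rs <- max(1L, q0 - 30L); re <- min(views$n, q1 + 30L)
                ## skip the orphan's own neighbourhood (same strand space)
                if (tau == sigma && re >= w2s - 50L && rs <= ve + 10L) next
                ext <- maxDuplex(intToDna(views[[tau]][rs:re]), W2seq)
                if (ext$len < config@minTransStem) next
                armStart <- rs + ext$aStart - 1L
                arm2End <- w2s + ext$bEnd - 1L
                cand <- .evalSplitJoin(views, sigma, tau, ve, armStart,
                                       arm2End, ext$len, config)
                if (!is.null(cand) && (is.null(best) || cand$score > best$score)) {
                    cand$tau <- tau
                    best <- cand
                }
            }
        }
        if (is.null(best)) next
        fg <- .viewToGenomic(if (best$tau == "p") "+" else "-",
                             best$s1, best$e1, views$n)
        tg <- .viewToGenomic(if (sigma == "p") "+" else "-",
                             best$exon2Start, ve, views$n)
        fStrand <- if (best$tau == "p") "+" else "-"
        tStrand <- if (sigma == "p") "+" else "-"
        sep <- max(0L, max(fg[1], tg[1]) - min(fg[2], tg[2]) - 1L)
        orient <- if (fStrand == tStrand) "same_strand"
        else if ((fStrand == "+" && fg[1] < tg[1]) ||
                 (fStrand == "-" && tg[1] < fg[1])) "convergent" else "divergent"
        idx34 <- 18L + 2L * best$layout$d + best$layout$dl
        ac <- substr(best$joined, idx34, idx34 + 2L)
        rows[[length(rows) + 1L]] <- data.frame(
            isotype = anticodonToIsotype(ac), anticodon = ac,
            junction = paste0(best$junction, "/", best$junction + 1L),
            stemLen = best$stemLen, bhbClass = best$bhbClass,
            joinedScore = best$score, orientation = orient,
            separation = sep, fiveStart = fg[1], fiveEnd = fg[2],
            fiveStrand = fStrand, threeStart = tg[1], threeEnd = tg[2],
            threeStrand = tStrand, joinedSeq = best$joined,
            source = "orphan_search", stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) return(S4Vectors::DataFrame(.emptySplitDf()))
    df <- do.call(rbind, rows)
    ## deduplicate identical candidates found from several orphan anchors
    key <- paste(df$fiveStart, df$threeStart, df$junction)
    df <- df[!duplicated(key), , drop = FALSE]
    S4Vectors::DataFrame(df)
}

.emptySplitDf <- function() {
    data.frame(isotype = character(0), anticodon = character(0),
               junction = character(0), stemLen = integer(0),
               bhbClass = character(0), joinedScore = numeric(0),
               orientation = character(0), separation = integer(0),
               fiveStart = integer(0), fiveEnd = integer(0),
               fiveStrand = character(0), threeStart = integer(0),
               threeEnd = integer(0), threeStrand = character(0),
               joinedSeq = character(0), source = character(0),
               stringsAsFactors = FALSE)
}

## Re-classify an intron-containing gene as a split candidate when a
## quality promoter lies inside the intron on the gene strand (the 3'
## half then has its own transcription unit).
.splitFromIntronGene <- function(gene, genome, motif, null, pThr, config) {
    mc <- S4Vectors::mcols(gene)
    if (is.na(mc$intronLen) || mc$intronLen < 60L) return(NULL)
    genomeSet <- if (is(genome, "DNAStringSet")) genome else
        setNames(Biostrings::DNAStringSet(list(genome)),
                 as.character(GenomicRanges::seqnames(gene))[1])
    pre <- extractInterval(genomeSet, gene)
    intronSeq <- substr(pre, mc$intronOffset + 1L,
                        mc$intronOffset + mc$intronLen)
    hit <- .bestHits(motif, intronSeq)
    if (is.na(hit$score[1])) return(NULL)
    pv <- pvalueFromNull(null, hit$score[1])
    if (pv > pThr) return(NULL)
    strand <- as.character(GenomicRanges::strand(gene))[1]
    gs <- GenomicRanges::start(gene)[1]; ge <- GenomicRanges::end(gene)[1]
    exon1Len <- mc$intronOffset
    exon2Len <- ge - gs + 1L - exon1Len - mc$intronLen
    if (strand == "+") {
        f <- c(gs, gs + exon1Len - 1L)
        t3 <- c(ge - exon2Len + 1L, ge)
    } else {
        f <- c(ge - exon1Len + 1L, ge)
        t3 <- c(gs, gs + exon2Len - 1L)
    }
    stem <- maxDuplex(substr(intronSeq, 1L, min(30L, nchar(intronSeq))),
                      substr(intronSeq, max(1L, nchar(intronSeq) - 29L),
                             nchar(intronSeq)))$len
    data.frame(isotype = mc$isotype, anticodon = mc$anticodon,
               junction = mc$intronSprinzl, stemLen = stem,
               bhbClass = mc$bhbClass, joinedScore = mc$score,
               orientation = "same_strand",
               separation = as.integer(mc$intronLen),
               fiveStart = f[1], fiveEnd = f[2], fiveStrand = strand,
               threeStart = t3[1], threeEnd = t3[2], threeStrand = strand,
               joinedSeq = mc$matureSeq, source = "intron_promoter",
               stringsAsFactors = FALSE)
}
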