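## Constraint-based cloverleaf model.
##
## A mature tRNA is modeled as a fixed succession of segments with bounded
## lengths:
##   acceptor 5' strand (7) | 8,9 | D stem (d = 3-4) | D loop (4-12) |
##   D stem' | 26 | anticodon stem (5) | anticodon loop (7) | anticodon
##   stem' | variable loop (3-21) | T stem (5) | T loop (7) | T stem' |
##   acceptor 3' strand (7) | discriminator | optional CCA
## Total length = 52 + 2d + dloop + var (+3 with CCA); the canonical
## 76-nt tRNA is d=4, dloop=8, var=5 with CCA.

## conserved-position profile: Sprinzl label, expected base (0 = purine),
## and weight; a match adds +w, a mismatch -w/2.
.CONSERVED <- data.frame(
    label = c("8", "14", "18", "19", "21", "26", "32", "33", "37",
              "53", "54", "55", "56", "57", "58", "60", "61",
              "74", "75", "76"),
    base = c(4L, 1L, 3L, 3L, 1L, 3L, 2L, 4L, 1L,
             3L, 4L, 4L, 2L, 0L, 1L, 2L, 2L,
             2L, 2L, 1L),
    w = c(0.8, 0.8, 1.0, 1.0, 0.8, 0.5, 0.5, 1.2, 0.5,
          1.2, 1.5, 1.5, 1.5, 0.6, 1.2, 0.4, 0.8,
          0.7, 0.7, 0.6),
    stringsAsFactors = FALSE)

.layoutEnv <- new.env(parent = emptyenv())

.sprinzlDloop <- function(dl) {
    core <- c("14", "15", "16", "17", "18", "19", "20", "21")
    if (dl < 8L) {
        drop <- c("17", "16", "15", "20")[seq_len(8L - dl)]
        core[!core %in% drop]
    } else if (dl > 8L) {
        ins17 <- paste0("17", letters)[seq_len(min(dl - 8L, 2L))]
        ins20 <- if (dl > 10L) paste0("20", letters)[seq_len(dl - 10L)] else character(0)
        c("14", "15", "16", "17", ins17, "18", "19", "20", ins20, "21")
    } else core
}

.sprinzlVar <- function(v) {
    core <- c("44", "45", "46", "47", "48")
    if (v < 5L) {
        drop <- c("47", "46")[seq_len(5L - v)]
        core[!core %in% drop]
    } else if (v > 5L) {
        c("44", "45", "46", "47", paste0("47", letters)[seq_len(v - 5L)], "48")
    } else core
}

#' Cloverleaf layout for given arm lengths
#'
#' Internal builder of the index bookkeeping (segment starts, pair list,
#' Sprinzl labels, conserved-position indices) for one arm-length
#' combination; results are memoized.
#'
#' @keywords internal
.cloverleafLayout <- function(d, dl, v, cca) {
    key <- ((d - 3L) * 9L + (dl - 4L)) * 19L + (v - 3L) + 1L +
        if (cca) 342L else 0L
    cache <- .layoutEnv$cache
    if (is.null(cache)) {
        cache <- vector("list", 684L)
        .layoutEnv$cache <- cache
    }
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    d <- as.integer(d); dl <- as.integer(dl); v <- as.integer(v)
    sAcc5 <- 1L; sLink <- 8L; sD5 <- 10L
    sDloop <- sD5 + d; sD3 <- sDloop + dl; s26 <- sD3 + d
    sAc5 <- s26 + 1L; sAcl <- sAc5 + 5L; sAc3 <- sAcl + 7L
    sVar <- sAc3 + 5L; sT5 <- sVar + v; sTl <- sT5 + 5L; sT3 <- sTl + 7L
    sAcc3 <- sT3 + 5L; sDisc <- sAcc3 + 7L
    len <- sDisc + if (cca) 3L else 0L
    pairs <- rbind(
        cbind(1:7, sAcc3 + 7L - (1:7)),
        cbind(sD5 + seq_len(d) - 1L, sD3 + d - seq_len(d)),
        cbind(sAc5 + 0:4, sAc3 + 5L - (1:5)),
        cbind(sT5 + 0:4, sT3 + 5L - (1:5)))
    sprinzl <- c(as.character(1:9),
                 as.character(seq(10L, length.out = d)),
                 .sprinzlDloop(dl),
                 as.character(seq(26L - d, 25L)),
                 as.character(26:43),
                 .sprinzlVar(v),
                 as.character(49:73),
                 if (cca) as.character(74:76) else character(0))
    stopifnot(length(sprinzl) == len)
    consIdx <- match(.CONSERVED$label, sprinzl)
    keep <- !is.na(consIdx)
    cons <- list(idx = consIdx[keep], base = .CONSERVED$base[keep],
                 w = .CONSERVED$w[keep])
    stems <- rep(c("acc", "d", "ac", "t"), c(7L, d, 5L, 5L))
    stemIdx <- list(acc = 1:7, d = 7L + seq_len(d),
                    ac = 7L + d + 1:5, t = 12L + d + 1:5)
    layout <- list(d = d, dl = dl, v = v, cca = cca, len = len,
                   pairs = pairs, stems = stems, stemIdx = stemIdx,
                   sprinzl = sprinzl, cons = cons,
                   seg = c(acc5 = sAcc5, link = sLink, d5 = sD5,
                           dloop = sDloop, d3 = sD3, p26 = s26, ac5 = sAc5,
                           acl = sAcl, ac3 = sAc3, var = sVar, t5 = sT5,
                           tl = sTl, t3 = sT3, acc3 = sAcc3, disc = sDisc))
    .layoutEnv$cache[[key]] <- layout
    layout
}

## All (d, dloop, var, cca) combinations compatible with a total length.
.combosForLength <- function(len) {
    out <- list()
    for (cca in c(FALSE, TRUE)) for (d in 3:4) for (dl in 4:12) {
        v <- len - 52L - 2L * d - dl - if (cca) 3L else 0L
        if (v >= 3L && v <= 21L)
            out[[length(out) + 1L]] <- list(d = d, dl = dl, v = v, cca = cca)
    }
    out
}

#' Score an integer-coded sequence against a cloverleaf layout
#'
#' @return list with total bit score, WC/GC pair counts, and per-stem
#'   mismatch counts.
#' @keywords internal
.scoreLayout <- function(v, layout) {
    v[is.na(v)] <- 5L
    i <- v[layout$pairs[, 1L]]
    j <- v[layout$pairs[, 2L]]
    lin <- (j - 1L) * 5L + i
    cls <- .PAIR$cls[lin]
    psc <- .PAIR$score[lin]
    cb <- v[layout$cons$idx]
    exp <- layout$cons$base
    hit <- cb == exp | (exp == 0L & (cb == 1L | cb == 3L))
    csc <- sum(layout$cons$w * (1.5 * hit - 0.5))
    mm0 <- cls == 0L
    mm <- c(sum(mm0[layout$stemIdx$acc]), sum(mm0[layout$stemIdx$d]),
            sum(mm0[layout$stemIdx$ac]), sum(mm0[layout$stemIdx$t]))
    list(score = sum(psc) + csc, cons = csc,
         wc = sum(cls == 2L), gc = sum(cls == 2L & (i == 2L | i == 3L)),
         mm = mm)
}

## stems accept at most one non-pairing position each, and at most two
## across the whole cloverleaf (real tRNA stems are essentially fully
## paired once G.U wobble is allowed)
.stemsValid <- function(mm) all(mm <= 1L) && sum(mm) <= 2L

#' Fold a sequence into a cloverleaf structure
#'
#' Enumerates every arm-boundary assignment compatible with the sequence
#' length, scores each (base-pair log-odds plus conserved-position terms)
#' and returns the best assignment in which all four stems are supported
#' (at most one non-pairing position per stem), or `NULL` when no
#' assignment qualifies. Ties are broken deterministically: most
#' Watson-Crick pairs, then most G-C pairs, then the enumeration order of
#' the arm lengths.
#'
#' @param seq mature-range nucleotide string (55-110 nt).
#' @return a [CloverleafStructure-class] with the fold's bit score, or
#'   `NULL`.
#' @examples
#' s <- makeTrnaSequence("GTC", seed = 1)
#' foldCloverleaf(s$seq)
#' @export
foldCloverleaf <- function(seq) {
    seq <- as.character(seq)
    len <- nchar(seq)
    if (len < 55L || len > 110L) stop("sequence length must be 55-110 nt")
    v <- dnaToInt(seq)
    best <- NULL
    bestKey <- c(-Inf, -Inf, -Inf)
    for (cmb in .combosForLength(len)) {
        layout <- .cloverleafLayout(cmb$d, cmb$dl, cmb$v, cmb$cca)
        sc <- .scoreLayout(v, layout)
        if (!.stemsValid(sc$mm)) next
        key <- c(sc$score, sc$wc, sc$gc)
        if (is.null(best) || key[1] > bestKey[1] ||
            (key[1] == bestKey[1] && (key[2] > bestKey[2] ||
             (key[2] == bestKey[2] && key[3] > bestKey[3])))) {
            best <- c(cmb, list(score = sc$score))
            bestKey <- key
        }
    }
    if (is.null(best)) return(NULL)
    layout <- .cloverleafLayout(best$d, best$dl, best$v, best$cca)
    new("CloverleafStructure", d = layout$d, dloop = layout$dl,
        varlen = layout$v, cca = layout$cca, len = layout$len,
        pairs = layout$pairs, sprinzl = layout$sprinzl,
        score = best$score)
}

#' Score a sequence under a given cloverleaf structure
#'
#' The score is the sum of stem pairing log-odds terms (G-C 2.0, A-T 1.5,
#' G-U 0.8, non-pairing -2.0 bits) and conserved-position terms (U8, A14,
#' G18/G19, A21, U33, the T-loop G53-U54-U55-C56-R57-A58 block, C60/C61 and
#' a genomically encoded CCA bonus). It is monotone non-decreasing in the
#' number of Watson-Crick pairs, all else equal.
#'
#' @param seq nucleotide string.
#' @param structure a [CloverleafStructure-class] folded from `seq`.
#' @return bit score (numeric).
#' @export
scoreTrna <- function(seq, structure) {
    seq <- as.character(seq)
    if (nchar(seq) != structure@len)
        stop("structure was not produced from this sequence (length mismatch)")
    layout <- .cloverleafLayout(structure@d, structure@dloop,
                                structure@varlen, structure@cca)
    .scoreLayout(dnaToInt(seq), layout)$score
}

#' Sprinzl numbering of a cloverleaf structure
#'
#' Maps each residue of the structure to its canonical tRNA (Sprinzl)
#' position: the anticodon is always 34-36, the T loop 54-60, the acceptor
#' 3' strand 66-72 and the discriminator 73; D-loop and variable-loop
#' insertions receive letter-suffixed labels (17a, 20a, 47a, ...).
#'
#' @param structure a [CloverleafStructure-class].
#' @return character vector of Sprinzl labels, one per residue.
#' @export
sprinzlNumber <- function(structure) structure@sprinzl

#' Sequence index of a Sprinzl position
#'
#' @param structure a [CloverleafStructure-class].
#' @param label Sprinzl label(s) as character or integer.
#' @return integer index (NA when the position is absent from the
#'   structure).
#' @export
posOfSprinzl <- function(structure, label) {
    match(as.character(label), structure@sprinzl)
}

#' Isotype of an anticodon
#'
#' Decodes the anticodon by the standard genetic code (three-letter amino
#' acid codes; CAT may represent elongator Met or initiator Met, selected by
#' `imet`).
#'
#' @param anticodon 3-mer DNA anticodon (e.g. `"GTC"`).
#' @param imet treat anticodon CAT as initiator methionine (`"iMet"`).
#' @return three-letter isotype string.
#' @examples
#' anticodonToIsotype("GTC")   # Asp
#' @export
anticodonToIsotype <- function(anticodon, imet = FALSE) {
    anticodon <- toupper(chartr("U", "T", anticodon))
    if (imet && anticodon == "CAT") return("iMet")
    codon <- revComp(anticodon)
    aa <- Biostrings::GENETIC_CODE[[codon]]
    if (is.null(aa) || aa == "*") return("Sup")
    unname(Biostrings::AMINO_ACID_CODE[aa])
}

#' Expected archaeal anticodon inventory
#'
#' The default decoding set used by [inventoryCheck()]: 46 anticodons
#' following standard archaeal wobble sparing rules (no A34 anticodons),
#' one initiator Met in addition to elongator Met, and two isoleucine
#' isoacceptors (the AUA-decoding tRNA is carried as Ile(UAU) here; in
#' many archaea it is encoded with a modified C34 instead). The set is
#' configurable through the `expected` argument of [inventoryCheck()].
#'
#' @return character vector of 46 entries formatted `"Isotype(ANT)"` with
#'   RNA-style anticodons.
#' @export
archaealAnticodons <- function() {
    sets <- list(
        Ala = c("UGC", "GGC", "CGC"), Arg = c("UCU", "CCU", "UCG", "CCG", "GCG"),
        Asn = "GUU", Asp = "GUC", Cys = "GCA", Gln = c("UUG", "CUG"),
        Glu = c("UUC", "CUC"), Gly = c("UCC", "CCC", "GCC"), His = "GUG",
        Ile = c("GAU", "UAU"), Leu = c("UAA", "CAA", "UAG", "CAG", "GAG"),
        Lys = c("UUU", "CUU"), Met = "CAU", iMet = "CAU", Phe = "GAA",
        Pro = c("UGG", "CGG", "GGG"), Ser = c("UGA", "CGA", "GGA", "GCU"),
        Thr = c("UGU", "CGU", "GGU"), Trp = "CCA", Tyr = "GUA",
        Val = c("UAC", "CAC", "GAC"))
    unlist(lapply(names(sets), function(iso)
        paste0(iso, "(", sets[[iso]], ")")), use.names = FALSE)
}

#' Report missing anticodons in a gene set
#'
#' Compares the isotype/anticodon inventory of a detected gene set against
#' the expected decoding set; a missing anticodon flags a possibly
#' fragmented (split or permuted) gene.
#'
#' @param genes a `GRanges` of tRNA genes with `isotype` and `anticodon`
#'   metadata columns (as returned by [scanGenome()]), or a character
#'   vector already formatted `"Isotype(ANT)"`.
#' @param expected the expected set (default [archaealAnticodons()]).
#' @return character vector of missing entries (empty when complete).
#' @export
inventoryCheck <- function(genes, expected = archaealAnticodons()) {
    if (is.character(genes)) {
        have <- genes
    } else {
        ac <- chartr("T", "U", S4Vectors::mcols(genes)$anticodon)
        have <- paste0(S4Vectors::mcols(genes)$isotype, "(", ac, ")")
        ## a single-copy CAU gene may serve as initiator Met
        if ("Met(CAU)" %in% have && !"iMet(CAU)" %in% have &&
            sum(have == "Met(CAU)") > 1L)
            have <- c(have, "iMet(CAU)")
    }
    setdiff(expected, have)
}
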