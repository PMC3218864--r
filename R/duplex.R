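#' Longest contiguous antiparallel duplex between two sequences
#'
#' Finds the longest run of consecutive base pairs formed between `a`
#' (read 5'->3') and `b` (read 3'->5'), i.e. the longest perfect
#' antiparallel helix the two strands can form. G.U wobble pairs count
#' unless `wcOnly = TRUE`. Used to measure the trans-pairing stem that
#' holds split pre-tRNA halves together.
#'
#' @param a,b nucleotide strings.
#' @param wcOnly require Watson-Crick pairs only.
#' @return list with `len` (stem length in bp) and the 1-based coordinates
#'   of the duplex: `aStart`/`aEnd` on `a` and `bStart`/`bEnd` on `b`
#'   (position `aStart + t` pairs with `bEnd - t`).
#' @examples
#' maxDuplex("GGGGCCCCAAAAA", "TTTGGGGCCCC")$len
#' @export
maxDuplex <- function(a, b, wcOnly = FALSE) {
    va <- dnaToInt(as.character(a)); vb <- dnaToInt(as.character(b))
    if (length(va) == 0L || length(vb) == 0L) stop("empty input")
    va[is.na(va)] <- 5L; vb[is.na(vb)] <- 5L
    okCls <- if (wcOnly) 2L else c(1L, 2L)
    n <- length(va); m <- length(vb)
    prev <- integer(m)
    best <- 0L; bi <- 0L; bj <- 0L
    for (i in seq_len(n)) {
        cur <- integer(m)
        cls <- .PAIR$cls[cbind(va[i], vb)]
        hit <- cls %in% okCls
        if (any(hit)) {
            js <- which(hit)
            ext <- ifelse(js < m, prev[pmin(js + 1L, m)], 0L)
            ext[js == m] <- 0L
            cur[js] <- ext + 1L
            mx <- max(cur[js])
            if (mx > best) {
                best <- mx
                jbest <- js[which.max(cur[js])]
                bi <- i; bj <- jbest
            }
        }
        prev <- cur
    }
    if (best == 0L)
        return(list(len = 0L, aStart = NA_integer_, aEnd = NA_integer_,
                    bStart = NA_integer_, bEnd = NA_integer_))
    list(len = best,
         aStart = bi - best + 1L, aEnd = bi,
         bStart = bj, bEnd = bj + best - 1L)
}

## Enumerate BHB structures. Geometry (antiparallel duplex with two offset
## bulges, splice sites strictly inside the bulges):
##
##   strand1 5'- [h arm] [bulge1 * b1len] [H arm] [h' arm] -3'
##   strand2 5'- [h' arm] [bulge2 * b2len] [H arm] [h arm] -3'
##
## h pairs h, H pairs H (the central helix), h' pairs h'. site1 is the cut
## after `site1` residues of ctx1 (inside bulge1); site2 the cut after
## `site2` residues of ctx2 (inside bulge2).
.bhbEnumerate <- function(v1, c1, v2, c2, bulgeRange, centralRange, minFlank) {
    n1 <- length(v1); n2 <- length(v2)
    out <- list()
    for (b1 in bulgeRange) for (u1 in seq_len(b1 - 1L)) {
        bs1 <- c1 - u1 + 1L
        if (bs1 < 1L || bs1 + b1 - 1L > n1) next
        for (b2 in bulgeRange) for (u2 in seq_len(b2 - 1L)) {
            bs2 <- c2 - u2 + 1L
            if (bs2 < 1L || bs2 + b2 - 1L > n2) next
            for (H in centralRange) {
                h1s <- bs1 + b1          # central arm on strand1
                h2s <- bs2 + b2          # central arm on strand2
                if (h1s + H - 1L > n1 || h2s + H - 1L > n2) next
                ok <- TRUE
                cs <- 0
                for (t in seq_len(H)) {
                    p <- .PAIR$cls[v1[h1s + t - 1L], v2[h2s + H - t]]
                    if (p == 0L || p == 3L) { ok <- FALSE; break }
                    cs <- cs + .PAIR$score[v1[h1s + t - 1L], v2[h2s + H - t]]
                }
                if (!ok) next
                ## flank h: upstream of bulge1 vs downstream of central on 2
                f1 <- 0L; fs1 <- 0
                repeat {
                    i <- bs1 - 1L - f1
                    j <- h2s + H + f1
                    if (i < 1L || j > n2) break
                    p <- .PAIR$cls[v1[i], v2[j]]
                    if (p == 0L || p == 3L) break
                    fs1 <- fs1 + .PAIR$score[v1[i], v2[j]]
                    f1 <- f1 + 1L
                    if (f1 >= 8L) break
                }
                if (f1 < minFlank) next
                ## flank h': downstream of central on 1 vs upstream of bulge2
                f2 <- 0L; fs2 <- 0
                repeat {
                    i <- h1s + H + f2
                    j <- bs2 - 1L - f2
                    if (i > n1 || j < 1L) break
                    p <- .PAIR$cls[v1[i], v2[j]]
                    if (p == 0L || p == 3L) break
                    fs2 <- fs2 + .PAIR$score[v1[i], v2[j]]
                    f2 <- f2 + 1L
                    if (f2 >= 8L) break
                }
                if (f2 < minFlank) next
                canonical <- (b1 == 3L && b2 == 3L && H == 4L)
                out[[length(out) + 1L]] <- data.frame(
                    strictness = if (canonical) "canonical_hBHBh" else "relaxed",
                    bulge1 = b1, bulge2 = b2, central = H,
                    u1 = u1, u2 = u2, flank1 = f1, flank2 = f2,
                    score = cs + fs1 + fs2, stringsAsFactors = FALSE)
            }
        }
    }
    out
}

#' Find bulge-helix-bulge splice-junction structures
#'
#' Enumerates helix / 3-nt bulge / 4-bp central helix / 3-nt bulge / helix
#' (hBHBh') arrangements across two splice-site contexts, with both splice
#' sites strictly inside the bulges and flanking helices of at least
#' `minFlank` base pairs (G.U allowed throughout). Canonical matches
#' (exactly 3-nt bulges and a 4-bp central helix) are ranked above relaxed
#' matches (bulges 2-4 nt, central helix 3-5 bp).
#'
#' @param ctx1 sequence context around the first splice site (the strand
#'   cut after its exon, e.g. 5' exon end plus trailer).
#' @param site1 number of `ctx1` residues 5' of the splice site.
#' @param ctx2 context around the second splice site (leader plus exon
#'   start).
#' @param site2 number of `ctx2` residues 5' of the splice site.
#' @param minFlank minimum flanking-helix length in bp.
#' @param relaxed also report relaxed (non-canonical) geometries.
#' @return data.frame of matches (strictness, bulge/central/flank sizes,
#'   splice-site placements `u1`/`u2` within the bulges, pairing score),
#'   canonical first, then by score; zero rows when no BHB forms.
#' @export
findBhb <- function(ctx1, site1, ctx2, site2, minFlank = 3L, relaxed = TRUE) {
    v1 <- dnaToInt(as.character(ctx1)); v2 <- dnaToInt(as.character(ctx2))
    v1[is.na(v1)] <- 5L; v2[is.na(v2)] <- 5L
    if (length(v1) < 15L || length(v2) < 15L)
        stop("contexts must include >= 15 nt around each splice site")
    res <- .bhbEnumerate(v1, site1, v2, site2,
                         bulgeRange = if (relaxed) 2:4 else 3L,
                         centralRange = if (relaxed) 3:5 else 4L,
                         minFlank = as.integer(minFlank))
    if (length(res) == 0L)
        return(data.frame(strictness = character(0), bulge1 = integer(0),
                          bulge2 = integer(0), central = integer(0),
                          u1 = integer(0), u2 = integer(0),
                          flank1 = integer(0), flank2 = integer(0),
                          score = numeric(0), stringsAsFactors = FALSE))
    df <- do.call(rbind, res)
    df <- df[order(df$strictness != "canonical_hBHBh", -df$score), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' @keywords internal
.hasCanonicalBhb <- function(bhb) {
    nrow(bhb) > 0L && any(bhb$strictness == "canonical_hBHBh")
}
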