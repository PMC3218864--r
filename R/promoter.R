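## Archaeal promoter identification: 16-mer motif (TFB response element
## A-run + TATA box) learned by EM from upstream windows of operon-leading
## known genes, scanned over 150-nt upstream regions, with empirical
## P-values from virtual genomes sampled from a Markov background.

## ---- training-set selection --------------------------------------------

#' Select upstream training windows for promoter discovery
#'
#' Keeps genes that (i) lead a potential operon - no same-strand gene ends
#' within `config@operonGap` nucleotides upstream - and (ii) have an
#' informative product annotation (products containing "putative" or
#' "hypothetical" are excluded). For each kept gene the window of
#' `config@trainUpstream` nucleotides immediately upstream (strand-aware)
#' is extracted; windows truncated by a contig edge are flagged.
#'
#' @param annotations `GRanges` of gene annotations with a `product`
#'   metadata column (e.g. from [readAnnotations()]).
#' @param genome named `DNAStringSet` (or single `DNAString`).
#' @param config a [RunConfig-class].
#' @return `data.frame` with columns `geneId`, `window`, `truncated`.
#' @export
selectTrainingGenes <- function(annotations, genome, config = runConfig()) {
    ann <- annotations[!is.na(S4Vectors::mcols(annotations)$product)]
    if (length(ann) == 0L) stop("annotations carry no product descriptions")
    prod <- as.character(S4Vectors::mcols(ann)$product)
    known <- !grepl("putative|hypothetical", prod, ignore.case = TRUE)
    ids <- S4Vectors::mcols(ann)$ID
    if (is.null(ids)) ids <- paste0("gene", seq_along(ann))
    keep <- logical(length(ann))
    st <- GenomicRanges::start(ann); en <- GenomicRanges::end(ann)
    sdr <- as.character(GenomicRanges::strand(ann))
    sq <- as.character(GenomicRanges::seqnames(ann))
    for (i in seq_along(ann)) {
        if (!known[i]) next
        same <- which(sq == sq[i] & sdr == sdr[i] & seq_along(ann) != i)
        if (sdr[i] == "+") {
            up <- same[en[same] < st[i]]
            gap <- if (length(up)) st[i] - max(en[same[en[same] < st[i]]]) - 1L else Inf
        } else {
            dn <- same[st[same] > en[i]]
            gap <- if (length(dn)) min(st[same[st[same] > en[i]]]) - en[i] - 1L else Inf
        }
        keep[i] <- gap >= config@operonGap
    }
    sel <- which(keep)
    if (length(sel) == 0L)
        return(data.frame(geneId = character(0), window = character(0),
                          truncated = logical(0), stringsAsFactors = FALSE))
    win <- upstreamWindows(ann[sel], genome, width = config@trainUpstream)
    data.frame(geneId = as.character(ids[sel]), window = win$seq,
               truncated = win$truncated, stringsAsFactors = FALSE)
}

#' Strand-aware upstream windows of genomic features
#'
#' @param gr feature `GRanges`.
#' @param genome named `DNAStringSet` or `DNAString`.
#' @param width window width in nt.
#' @return list with `seq` (character, 5'->3' on the feature strand, ending
#'   immediately before the feature start) and `truncated` (logical).
#' @export
upstreamWindows <- function(gr, genome, width) {
    if (is(genome, "DNAString"))
        genome <- setNames(Biostrings::DNAStringSet(list(genome)),
                           as.character(GenomicRanges::seqnames(gr))[1])
    n <- length(gr)
    seqs <- character(n); trunc <- logical(n)
    for (i in seq_len(n)) {
        sid <- as.character(GenomicRanges::seqnames(gr))[i]
        glen <- length(genome[[sid]])
        if (as.character(GenomicRanges::strand(gr))[i] == "-") {
            s <- GenomicRanges::end(gr)[i] + 1L
            e <- min(glen, GenomicRanges::end(gr)[i] + width)
            trunc[i] <- e - s + 1L < width
            if (e < s) { seqs[i] <- ""; next }
            iv <- GenomicRanges::GRanges(sid, IRanges::IRanges(s, e), "-")
        } else {
            e <- GenomicRanges::start(gr)[i] - 1L
            s <- max(1L, GenomicRanges::start(gr)[i] - width)
            trunc[i] <- e - s + 1L < width
            if (e < s) { seqs[i] <- ""; next }
            iv <- GenomicRanges::GRanges(sid, IRanges::IRanges(s, e), "+")
        }
        seqs[i] <- extractInterval(genome, iv)
    }
    list(seq = seqs, truncated = trunc)
}

## ---- EM motif discovery -------------------------------------------------

## windows as padded integer matrix; pad code 5 kills those positions.
.windowMatrix <- function(windows) {
    vs <- lapply(windows, dnaToInt)
    L <- max(lengths(vs))
    mat <- matrix(5L, length(vs), L)
    for (i in seq_along(vs)) {
        v <- vs[[i]]
        v[is.na(v)] <- 5L
        if (length(v)) mat[i, seq_along(v)] <- v
    }
    mat
}

## position log-likelihood-ratio matrix: n x (L - w + 1)
.positionScores <- function(mat, lodds) {
    w <- ncol(lodds)
    L <- ncol(mat)
    m <- L - w + 1L
    S <- matrix(0, nrow(mat), m)
    lo <- rbind(lodds, rep(-1e9, w))   # row 5: pad
    for (cc in seq_len(w)) {
        S <- S + matrix(lo[cbind(as.vector(mat[, cc:(cc + m - 1L)]),
                                 cc)], nrow(mat), m)
    }
    S
}

.emZoops <- function(mat, width, bg, gamma0 = 0.7, maxIter = 100L,
                     pseudo = 0.1, theta0 = NULL) {
    n <- nrow(mat); L <- ncol(mat)
    m <- L - width + 1L
    mi <- apply(mat, 1L, function(r) {
        lastReal <- max(c(0L, which(r != 5L)))
        max(0L, min(m, lastReal - width + 1L))
    })
    if (is.null(theta0)) {
        ## random initialization from one window occurrence
        i0 <- sample.int(n, 1L)
        z0 <- sample.int(max(1L, mi[i0]), 1L)
        theta <- matrix(0.1 / 3, 4L, width)
        for (cc in seq_len(width)) {
            b <- mat[i0, z0 + cc - 1L]
            if (b <= 4L) theta[b, cc] <- 0.9 else theta[, cc] <- 0.25
            theta[, cc] <- theta[, cc] / sum(theta[, cc])
        }
    } else {
        theta <- theta0
    }
    gamma <- gamma0
    prevLL <- -Inf
    for (iter in seq_len(maxIter)) {
        lodds <- log(theta / bg)
        S <- .positionScores(mat, lodds)
        ## guard columns beyond mi
        for (i in which(mi < m)) if (mi[i] < m)
            S[i, seq.int(mi[i] + 1L, m)] <- -1e9
        Smax <- apply(S, 1L, max)
        Smax[!is.finite(Smax)] <- 0
        W <- exp(S - Smax)
        rs <- rowSums(W)
        ri <- ifelse(mi > 0L, gamma / pmax(mi, 1L) * rs * exp(Smax), 0)
        post <- ri / ((1 - gamma) + ri)
        post[!is.finite(post)] <- 1
        LL <- sum(log((1 - gamma) + ri))
        ## M step
        Z <- W / pmax(rs, 1e-300) * post
        newTheta <- matrix(pseudo, 4L, width)
        for (cc in seq_len(width)) {
            sub <- mat[, cc:(cc + m - 1L), drop = FALSE]
            for (b in 1:4) newTheta[b, cc] <- newTheta[b, cc] +
                    sum(Z[sub == b])
        }
        theta <- sweep(newTheta, 2L, colSums(newTheta), "/")
        gamma <- min(0.95, max(0.05, mean(post)))
        if (is.finite(LL) && abs(LL - prevLL) < 1e-8) { prevLL <- LL; break }
        prevLL <- LL
    }
    list(theta = theta, gamma = gamma, loglik = prevLL)
}

#' Discover a promoter motif by EM
#'
#' Fits a zero-or-one-occurrence-per-sequence (ZOOPS) motif model to the
#' training windows by expectation-maximization, taking the best of
#' `restarts` seeded random initializations. Deterministic for a fixed
#' seed. With degenerate (e.g. all-identical) input the EM still converges;
#' the resulting motif is usable but flagged via its information content.
#'
#' @param windows character vector of training windows (typically 90-nt
#'   upstream regions).
#' @param width motif width (default 16).
#' @param restarts number of random restarts (default 20).
#' @param seed integer seed.
#' @param pseudo pseudocount added per PWM cell in the M step.
#' @return a [PromoterMotif-class].
#' @export
discoverMotif <- function(windows, width = 16L, restarts = 20L, seed = 1L,
                          pseudo = 0.1) {
    windows <- windows[nchar(windows) >= width]
    if (length(windows) == 0L) stop("no training window reaches motif width")
    if (length(windows) < 20L)
        warning("fewer than 20 training windows; motif estimate may be noisy")
    mat <- .windowMatrix(windows)
    cnt <- table(factor(mat[mat <= 4L], levels = 1:4))
    bg <- as.numeric(cnt + 1) / sum(cnt + 4)
    best <- NULL
    for (r in seq_len(restarts)) {
        set.seed(as.integer(seed) + r)
        fit <- .emZoops(mat, as.integer(width), bg, pseudo = pseudo)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    ## shift refinement: seeded EM can converge to a variant of the true
    ## motif displaced by a column or two; re-run EM from shifted versions
    ## of the best solution and keep the highest-likelihood one
    for (sh in c(-3:-1, 1:3)) {
        w <- as.integer(width)
        th <- matrix(bg, 4L, w)
        src <- seq_len(w) - sh
        keep <- src >= 1L & src <= w
        th[, keep] <- best$theta[, src[keep]]
        fit <- .emZoops(mat, w, bg, pseudo = pseudo, theta0 = th)
        if (fit$loglik > best$loglik + 1e-6) best <- fit
    }
    prob <- best$theta
    rownames(prob) <- BASES
    lodds <- log2(prob / bg)
    new("PromoterMotif", width = as.integer(width), prob = prob,
        logOdds = lodds, bg = bg, nseq = length(windows))
}

#' Packaged default promoter motif
#'
#' PWM built from the package's archaeal core-promoter template (a short
#' adenosine run - the TFB response element - followed by a TATA-like box).
#' Used when no annotations are available to train a genome-specific motif,
#' and as the template the synthetic-genome generator plants promoter
#' instances from.
#'
#' @param strength probability mass on the consensus base in the core
#'   (A-run + TATA) columns; flanking columns are weakly informative
#'   (half-way between `strength` and uniform), reflecting the base
#'   preferences around archaeal BRE/TATA elements.
#' @return a [PromoterMotif-class] of width 16.
#' @export
promoterTemplate <- function(strength = 0.85) {
    cons <- c("G", "C", "A", "A", "A", "T", "T", "T", "A", "T", "A", "T",
              "A", "G", "A", "G")
    core <- 3:13
    prob <- matrix(0.25, 4L, 16L, dimnames = list(BASES, NULL))
    for (cc in seq_along(cons)) {
        s <- if (cc %in% core) strength else 0.75
        prob[, cc] <- (1 - s) / 3
        prob[cons[cc], cc] <- s
    }
    bg <- rep(0.25, 4)
    new("PromoterMotif", width = 16L, prob = prob,
        logOdds = log2(prob / bg), bg = bg, nseq = 0L)
}

## ---- scanning -----------------------------------------------------------

## best motif placement in each window; returns offset relative to the
## feature 5' end (window is assumed to end immediately before the feature)
.bestHits <- function(motif, windows) {
    w <- motif@width
    out <- data.frame(offset = rep(NA_integer_, length(windows)),
                      score = rep(NA_real_, length(windows)))
    ok <- nchar(windows) >= w
    if (!any(ok)) return(out)
    mat <- .windowMatrix(windows[ok])
    S <- .positionScores(mat, motif@logOdds)
    Lw <- nchar(windows[ok])
    m <- ncol(S)
    for (k in seq_len(nrow(S))) {
        mk <- Lw[k] - w + 1L
        sc <- S[k, seq_len(mk)]
        z <- which.max(sc)               # leftmost (most upstream) on ties
        out$offset[which(ok)[k]] <- (z - 1L) - Lw[k]
        out$score[which(ok)[k]] <- sc[z]
    }
    out
}

#' Scan upstream regions for promoter hits
#'
#' Scores every placement of the motif in each upstream window on the
#' gene's strand and reports the best-scoring placement per gene; ties go
#' to the most upstream placement. Offsets are the motif start relative to
#' the feature 5' end (negative upstream; an offset of -16 puts a 16-mer
#' motif immediately adjacent to the start). Windows shorter than the
#' motif are skipped with NA results.
#'
#' @param motif a [PromoterMotif-class].
#' @param regions `data.frame` with columns `geneId` and `window` (the
#'   upstream sequence, 5'->3' on the gene strand, ending just before the
#'   gene).
#' @return `data.frame` with `geneId`, `offset`, `score`.
#' @export
scanUpstream <- function(motif, regions) {
    hits <- .bestHits(motif, regions$window)
    data.frame(geneId = regions$geneId, offset = hits$offset,
               score = hits$score, stringsAsFactors = FALSE)
}

#' Build an empirical null distribution of promoter scores
#'
#' Samples `n` virtual genomes of the given length from the Markov
#' background, applies the same windowed scanning protocol used for real
#' upstream regions (150-nt windows, best placement per window) and
#' collects the best-hit scores. Deterministic for a fixed seed.
#'
#' @param motif a [PromoterMotif-class].
#' @param bg a [MarkovBackground-class].
#' @param genomeLength length of each virtual genome.
#' @param n number of virtual genomes (default 10).
#' @param seed integer seed.
#' @param windowWidth scanning window width (default 150).
#' @return a [NullDistribution-class].
#' @export
buildNull <- function(motif, bg, genomeLength, n = 10L, seed = 1L,
                      windowWidth = 150L) {
    if (n < 1L) stop("n must be >= 1")
    w <- motif@width
    lo <- rbind(motif@logOdds, rep(-1e9, w))
    all <- list()
    for (g in seq_len(n)) {
        vg <- sampleVirtualGenome(bg, genomeLength, seed = seed + g,
                                  as = "character")
        v <- dnaToInt(vg)
        v[is.na(v)] <- 5L
        m <- length(v) - w + 1L
        S <- numeric(m)
        for (cc in seq_len(w)) S <- S + lo[cbind(v[cc:(cc + m - 1L)], cc)]
        K <- (length(v) %/% windowWidth)
        starts <- (seq_len(K) - 1L) * windowWidth + 1L
        lastValid <- pmin(starts + windowWidth - w, m)
        best <- vapply(seq_len(K), function(r)
            max(S[starts[r]:lastValid[r]]), numeric(1))
        all[[g]] <- best
    }
    new("NullDistribution", scores = sort(unlist(all)),
        nGenomes = as.integer(n), seed = as.integer(seed))
}

#' Empirical P-values from a null distribution
#'
#' P(s) = (r + 1) / (n + 1) where r is the number of null scores at or
#' above s; monotone non-increasing in the score.
#'
#' @param null a [NullDistribution-class].
#' @param scores numeric scores.
#' @return numeric P-values in (0, 1].
#' @export
pvalueFromNull <- function(null, scores) {
    ns <- null@scores
    n <- length(ns)
    r <- n - findInterval(scores, ns, left.open = FALSE)
    exact <- vapply(scores, function(s) sum(ns >= s), numeric(1))
    (exact + 1) / (n + 1)
}

#' Filter promoter hits by expected position and training-derived threshold
#'
#' Keeps hits whose offset lies inside the expected-position window and
#' whose empirical P-value does not exceed the largest (worst) P-value
#' among the training-gene promoters - i.e. the threshold is set by the
#' lowest-scoring known gene. Training-gene hits themselves always
#' satisfy the threshold rule.
#'
#' @param hits `data.frame` from [scanUpstream()] (geneId, offset, score).
#' @param null a [NullDistribution-class].
#' @param trainingScores numeric vector of training-gene promoter scores.
#' @param positionWindow numeric length-2 vector, inclusive offset window
#'   (e.g. `c(-100, -16)`).
#' @return the filtered `data.frame` with a `pvalue` column appended.
#' @export
filterHits <- function(hits, null, trainingScores,
                       positionWindow = c(-100, -16)) {
    if (length(trainingScores) == 0L || all(is.na(trainingScores)))
        stop("no training-gene promoter scores; cannot derive threshold")
    thr <- max(pvalueFromNull(null, trainingScores[!is.na(trainingScores)]))
    hits$pvalue <- pvalueFromNull(null, hits$score)
    keep <- !is.na(hits$offset) &
        hits$offset >= positionWindow[1] & hits$offset <= positionWindow[2] &
        hits$pvalue <= thr
    out <- hits[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Flag promoter-to-gene spacing outliers
#'
#' Summarizes the empirical distribution of promoter offsets across tRNA
#' loci and flags offsets whose magnitude exceeds both the Tukey fence
#' (Q3 + 1.5 IQR of offset magnitudes) and the configured normal band
#' (`bandMax`). Outliers are the trigger for the permuted-gene search: a
#' promoter displaced well beyond the normal 5'-leader band suggests extra
#' sequence (a 3' half plus intervening sequence) between the promoter and
#' the mature 5' end. With fewer than `minHits` hits outlier calling is
#' disabled with a warning.
#'
#' @param trnaHits `data.frame` with `geneId` and `offset` (negative
#'   upstream).
#' @param bandMax upper edge of the normal spacing band (nt; default 49).
#' @param minHits minimum number of hits for outlier calling (default 10).
#' @param reference optional logical vector (same length as `trnaHits`)
#'   marking the rows the spacing distribution is estimated from (e.g.
#'   confidently called genes); all rows are still tested against the
#'   resulting fence.
#' @param slack upper cap on how far the Tukey fence may exceed `bandMax`
#'   (default 16, one motif width): with few hits the sample quartiles are
#'   noisy and an uncapped fence can swallow genuine outliers.
#' @return the input with an added logical `outlier` column.
#' @export
spacingOutliers <- function(trnaHits, bandMax = 49, minHits = 10L,
                            reference = NULL, slack = 16L) {
    out <- trnaHits
    out$outlier <- logical(nrow(out))
    if (is.null(reference)) reference <- rep(TRUE, nrow(out))
    ok <- !is.na(out$offset)
    ref <- ok & reference
    if (sum(ref) < minHits) {
        warning("fewer than ", minHits,
                " promoter hits; spacing outlier calling disabled")
        return(out)
    }
    mag <- -out$offset[ref]
    q <- quantile(mag, c(0.25, 0.75), names = FALSE, type = 7)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    thr <- max(bandMax, min(fence, bandMax + slack))
    out$outlier[ok] <- -out$offset[ok] > thr
    out
}
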