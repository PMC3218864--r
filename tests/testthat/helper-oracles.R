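## Independent reference implementations used to cross-check the package.

.B <- c("A", "C", "G", "T")

randSeq <- function(n, gc = 0.5) {
    paste(sample(.B, n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

## naive base-by-base reverse complement
oracleRevComp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

## can two bases pair (WC or G.U)?
oraclePairable <- function(x, y) {
    paste0(x, y) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
}

## longest antiparallel duplex by scanning diagonals of the pairing matrix
oracleMaxDuplex <- function(a, b) {
    va <- strsplit(a, "")[[1]]
    vb <- strsplit(b, "")[[1]]
    M <- outer(va, vb, oraclePairable)
    ## duplex runs lie along anti-diagonals read as diagonals of M[, rev]
    Mr <- M[, rev(seq_len(ncol(M))), drop = FALSE]
    best <- 0L
    n <- nrow(Mr); m <- ncol(Mr)
    for (d in (-(n - 1L)):(m - 1L)) {
        i <- seq_len(n)
        j <- i + d
        ok <- j >= 1L & j <= m
        if (!any(ok)) next
        diagv <- Mr[cbind(i[ok], j[ok])]
        r <- rle(diagv)
        hit <- r$lengths[r$values]
        if (length(hit)) best <- max(best, max(hit))
    }
    best
}

## Needleman-Wunsch with unit costs; returns substitution count of one
## optimal alignment (match 0, mismatch 1, gap 1.5 so substitutions are
## preferred over indel pairs, as in the package alignment parameters)
oracleSubstitutions <- function(a, b) {
    va <- strsplit(a, "")[[1]]
    vb <- strsplit(b, "")[[1]]
    n <- length(va); m <- length(vb)
    D <- matrix(0, n + 1L, m + 1L)
    D[, 1L] <- (0:n) * 1.5
    D[1L, ] <- (0:m) * 1.5
    for (i in seq_len(n)) for (j in seq_len(m)) {
        D[i + 1L, j + 1L] <- min(D[i, j] + (va[i] != vb[j]),
                                 D[i, j + 1L] + 1.5,
                                 D[i + 1L, j] + 1.5)
    }
    ## traceback counting substitutions
    i <- n; j <- m; subs <- 0L
    while (i > 0L && j > 0L) {
        if (abs(D[i + 1L, j + 1L] - (D[i, j] + (va[i] != vb[j]))) < 1e-9) {
            subs <- subs + (va[i] != vb[j])
            i <- i - 1L; j <- j - 1L
        } else if (abs(D[i + 1L, j + 1L] - (D[i, j + 1L] + 1.5)) < 1e-9) {
            i <- i - 1L
        } else {
            j <- j - 1L
        }
    }
    as.integer(subs)
}

## exhaustive BHB enumeration written from the geometry definition:
## strand1 = h-arm | bulge1 | H-arm | h'-arm, strand2 = h'-arm | bulge2 |
## H-arm | h-arm; splice sites strictly inside the bulges.
oracleBhb <- function(ctx1, site1, ctx2, site2, minFlank = 3L) {
    v1 <- strsplit(ctx1, "")[[1]]
    v2 <- strsplit(ctx2, "")[[1]]
    res <- list()
    for (b1 in 2:4) for (b2 in 2:4) for (H in 3:5) {
        for (u1 in 1:(b1 - 1L)) for (u2 in 1:(b2 - 1L)) {
            bs1 <- site1 - u1 + 1L
            bs2 <- site2 - u2 + 1L
            if (bs1 < 1L || bs1 + b1 - 1L > length(v1)) next
            if (bs2 < 1L || bs2 + b2 - 1L > length(v2)) next
            h1 <- bs1 + b1; h2 <- bs2 + b2
            if (h1 + H - 1L > length(v1) || h2 + H - 1L > length(v2)) next
            central <- all(vapply(seq_len(H), function(t)
                oraclePairable(v1[h1 + t - 1L], v2[h2 + H - t]), TRUE))
            if (!central) next
            f1 <- 0L
            while (f1 < 8L && bs1 - 1L - f1 >= 1L &&
                   h2 + H + f1 <= length(v2) &&
                   oraclePairable(v1[bs1 - 1L - f1], v2[h2 + H + f1]))
                f1 <- f1 + 1L
            if (f1 < minFlank) next
            f2 <- 0L
            while (f2 < 8L && h1 + H + f2 <= length(v1) &&
                   bs2 - 1L - f2 >= 1L &&
                   oraclePairable(v1[h1 + H + f2], v2[bs2 - 1L - f2]))
                f2 <- f2 + 1L
            if (f2 < minFlank) next
            res[[length(res) + 1L]] <- data.frame(
                strictness = if (b1 == 3L && b2 == 3L && H == 4L)
                    "canonical_hBHBh" else "relaxed",
                bulge1 = b1, bulge2 = b2, central = H, u1 = u1, u2 = u2,
                flank1 = f1, flank2 = f2, stringsAsFactors = FALSE)
        }
    }
    if (length(res) == 0L)
        return(data.frame(strictness = character(0), bulge1 = integer(0),
                          bulge2 = integer(0), central = integer(0),
                          u1 = integer(0), u2 = integer(0),
                          flank1 = integer(0), flank2 = integer(0)))
    do.call(rbind, res)
}

## canonical sorted key of a BHB match table for set comparison
bhbKey <- function(df) {
    k <- sprintf("%s_%d_%d_%d_%d_%d_%d_%d", df$strictness, df$bulge1,
                 df$bulge2, df$central, df$u1, df$u2, df$flank1, df$flank2)
    sort(k)
}

## line-by-line FASTA parser
oracleReadFasta <- function(path) {
    lines <- readLines(path)
    ids <- character(0); seqs <- character(0); cur <- ""
    for (ln in lines) {
        if (startsWith(ln, ">")) {
            if (length(ids)) seqs <- c(seqs, cur)
            ids <- c(ids, sub("\\s.*$", "", sub("^>", "", ln)))
            cur <- ""
        } else cur <- paste0(cur, ln)
    }
    seqs <- c(seqs, cur)
    setNames(toupper(chartr("u", "T", chartr("U", "T", seqs))), ids)
}
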