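#' Train a k-th order Markov background model
#'
#' Conditional distributions P(next base | preceding k-mer) are estimated
#' from (order+1)-mer counts with a pseudocount of 0.25 per context cell so
#' that no context has a zero-probability continuation, even in small
#' genomes. Positions whose (order+1)-mer contains an N are excluded from
#' training.
#'
#' @param seq a `DNAString`/`DNAStringSet` element or character string.
#' @param order chain order (default 5, retaining the 6-mer composition of
#'   the training genome).
#' @param pseudocount added to every context cell before normalization.
#' @param id label recorded as the training-sequence id.
#' @return a [MarkovBackground-class] object.
#' @examples
#' bg <- trainMarkov("ACGTACGTACGTAC", order = 1)
#' markovProb(bg)
#' @export
trainMarkov <- function(seq, order = 5L, pseudocount = 0.25, id = "genome") {
    if (order < 0L) stop("order must be >= 0")
    order <- as.integer(order)
    if (!is(seq, "DNAString")) seq <- Biostrings::DNAString(as.character(seq))
    if (length(seq) <= 4^(order + 1))
        warning("training sequence shorter than 4^(order+1); ",
                "estimates will lean on the pseudocount")
    counts <- Biostrings::oligonucleotideFrequency(seq, width = order + 1L)
    ## counts come ordered with the last base fastest: reshape to contexts x 4
    mat <- matrix(as.numeric(counts), ncol = 4L, byrow = TRUE)
    mat <- mat + pseudocount
    prob <- mat / rowSums(mat)
    ctx <- rowSums(mat)
    new("MarkovBackground", order = order, prob = prob,
        contextFreq = ctx / sum(ctx), trainedOn = id)
}

#' Sample a virtual genome from a Markov background
#'
#' Generates a sequence of the requested length; the initial context is
#' drawn from the empirical context distribution of the training genome and
#' subsequent bases follow the conditional distributions. Deterministic for
#' a fixed seed. Sampled sequences never contain N.
#'
#' @param bg a [MarkovBackground-class].
#' @param length output length (> order).
#' @param seed integer seed.
#' @param as character: `"DNAString"` (default) or `"character"`.
#' @return the sampled sequence.
#' @export
sampleVirtualGenome <- function(bg, length, seed, as = c("DNAString", "character")) {
    as <- match.arg(as)
    k <- bg@order
    if (length <= k) stop("length must exceed the Markov order")
    set.seed(as.integer(seed))
    if (k > 0L) {
        ctxCode <- sample.int(nrow(bg@prob), 1L, prob = bg@contextFreq) - 1L
        init <- integer(k)
        for (i in k:1) {
            init[i] <- ctxCode %% 4L + 1L
            ctxCode <- ctxCode %/% 4L
        }
    } else {
        init <- integer(0)
    }
    cum <- t(apply(bg@prob, 1L, cumsum))
    if (nrow(bg@prob) == 1L) cum <- matrix(cumsum(bg@prob[1L, ]), nrow = 1L)
    v <- .sampleMarkovCpp(cum, init, as.integer(length))
    s <- intToDna(v)
    if (as == "character") s else Biostrings::DNAString(s)
}

#' Count substitutions between two near-identical sequences
#'
#' Globally aligns the two sequences (Needleman-Wunsch via
#' [Biostrings::pairwiseAlignment()], unit-like costs) and counts the
#' substituted positions; indels are not counted as substitutions but are
#' reported alongside.
#'
#' @param a,b nucleotide strings of near-equal length.
#' @return integer substitution count, with attribute `indels` giving the
#'   total number of inserted/deleted bases in the alignment.
#' @examples
#' countSubstitutions("ACGT", "ACGA")
#' @export
countSubstitutions <- function(a, b) {
    a <- as.character(a); b <- as.character(b)
    if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(b),
        type = "global", substitutionMatrix = mat,
        gapOpening = 2, gapExtension = 1)
    subs <- Biostrings::nmismatch(aln)
    pa <- as.character(Biostrings::alignedPattern(aln))
    ps <- as.character(Biostrings::alignedSubject(aln))
    indels <- sum(strsplit(pa, "")[[1]] == "-") + sum(strsplit(ps, "")[[1]] == "-")
    structure(as.integer(subs), indels = as.integer(indels))
}
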