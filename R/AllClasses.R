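## Central S4 classes. Gene, fragment and candidate sets are ordinary
## GRanges/DataFrame objects with metadata columns; the classes below hold
## model state that benefits from validity checking.

#' MarkovBackground: k-th order Markov model of genomic composition
#'
#' Conditional distributions of the next base given the preceding `order`
#' bases, estimated from (order+1)-mer counts with a pseudocount. Used both
#' to generate virtual genomes for empirical promoter-score null
#' distributions and as the background of the synthetic-genome generator.
#'
#' @slot order integer, chain order (>= 0; the pipeline default is 5).
#' @slot prob 4^order x 4 matrix of conditional probabilities; rows are
#'   contexts (base-4 code of the preceding k-mer), columns A,C,G,T.
#' @slot contextFreq empirical distribution over contexts, used to draw the
#'   initial context when sampling.
#' @slot trainedOn id of the training sequence.
#' @export
setClass("MarkovBackground",
    representation(order = "integer", prob = "matrix",
                   contextFreq = "numeric", trainedOn = "character"),
    validity = function(object) {
        if (object@order < 0L) return("order must be >= 0")
        if (nrow(object@prob) != 4L^object@order || ncol(object@prob) != 4L)
            return("prob must be a 4^order x 4 matrix")
        if (any(abs(rowSums(object@prob) - 1) > 1e-9))
            return("conditional distributions must sum to 1 within 1e-9")
        if (abs(sum(object@contextFreq) - 1) > 1e-9)
            return("contextFreq must sum to 1")
        TRUE
    })

#' CloverleafStructure: arm-boundary assignment of a tRNA cloverleaf
#'
#' The constraint model fixes stem sizes (acceptor 7 bp, anticodon and T
#' stems 5 bp) and lets the D stem (3-4 bp), D loop (4-12 nt) and variable
#' loop (3-21 nt) vary; the anticodon and T loops are always 7 nt. Sprinzl
#' labels are derived from the assignment, with letter suffixes for D-loop /
#' variable-loop insertions.
#'
#' @slot d D-stem length in bp (3 or 4).
#' @slot dloop D-loop length in nt (4-12).
#' @slot varlen variable-loop length in nt (3-21).
#' @slot cca logical, genomically encoded 3'-terminal CCA present.
#' @slot len total length of the mature sequence the structure describes.
#' @slot pairs two-column integer matrix of paired positions (5' index, 3'
#'   index), acceptor stem first, then D, anticodon and T stems.
#' @slot sprinzl character vector of Sprinzl labels, one per residue.
#' @slot score bit score of the sequence the structure was folded from
#'   (NA when constructed without a sequence).
#' @export
setClass("CloverleafStructure",
    representation(d = "integer", dloop = "integer", varlen = "integer",
                   cca = "logical", len = "integer", pairs = "matrix",
                   sprinzl = "character", score = "numeric"),
    validity = function(object) {
        if (!object@d %in% 3:4) return("d must be 3 or 4")
        if (object@dloop < 4L || object@dloop > 12L) return("dloop must be 4-12")
        if (object@varlen < 3L || object@varlen > 21L) return("varlen must be 3-21")
        if (length(object@sprinzl) != object@len)
            return("sprinzl labels must cover every residue")
        TRUE
    })

#' PromoterMotif: position weight matrix of the core promoter
#'
#' A probability matrix over A,C,G,T per column together with its log-odds
#' form against a 0-order background. The default width of 16 accommodates
#' the archaeal TFB response element (a short A-run) plus the TATA box.
#'
#' @slot width motif width (>= 8).
#' @slot prob 4 x width probability matrix (columns sum to 1).
#' @slot logOdds 4 x width log2-odds matrix vs `bg`.
#' @slot bg background base frequencies (A,C,G,T).
#' @slot nseq number of training windows the motif was estimated from.
#' @export
setClass("PromoterMotif",
    representation(width = "integer", prob = "matrix", logOdds = "matrix",
                   bg = "numeric", nseq = "integer"),
    validity = function(object) {
        if (object@width < 8L) return("width must be >= 8")
        if (ncol(object@prob) != object@width || nrow(object@prob) != 4L)
            return("prob must be 4 x width")
        if (any(abs(colSums(object@prob) - 1) > 1e-6))
            return("each PWM column must sum to 1")
        TRUE
    })

#' NullDistribution: empirical null of promoter scan scores
#'
#' Best-hit scores collected by applying the upstream-window scanning
#' protocol to virtual genomes sampled from a Markov background. Empirical
#' P-values use (r+1)/(n+1) smoothing, where r is the number of null scores
#' at or above the observed score.
#'
#' @slot scores sorted numeric vector of null best-hit scores.
#' @slot nGenomes number of virtual genomes scanned.
#' @slot seed RNG seed the virtual genomes were generated from.
#' @export
setClass("NullDistribution",
    representation(scores = "numeric", nGenomes = "integer", seed = "integer"),
    validity = function(object) {
        if (length(object@scores) == 0L) return("null distribution is empty")
        if (is.unsorted(object@scores)) return("scores must be sorted")
        TRUE
    })

#' RunConfig: tunable parameters of the discovery pipeline
#'
#' Defaults follow the published protocol where one exists: 20-bit reporting
#' cutoff, fifth-order Markov background, ten virtual genomes, 16-mer
#' promoter motif trained on 90-nt upstream windows of operon-leading known
#' genes (>= 100 nt same-strand intergenic gap), 150-nt upstream scan
#' windows, splice-junction enumeration between Sprinzl 8 and 60, 10-bp
#' minimum trans-pairing stem, tRNA intron lengths 11-129 nt, and a normal
#' promoter spacing band of 30-49 nt.
#'
#' @slot cutoffBits reporting cutoff for tRNA gene/candidate scores (bits).
#' @slot markovOrder order of the genomic background model.
#' @slot nVirtualGenomes virtual genomes used for the score null.
#' @slot motifWidth promoter motif width.
#' @slot trainUpstream upstream window for motif training (nt).
#' @slot scanUpstream upstream window scanned for promoters (nt).
#' @slot operonGap minimum same-strand intergenic gap for an operon leader.
#' @slot junctionMin,junctionMax Sprinzl range enumerated for splice junctions.
#' @slot minTransStem minimum trans-pairing stem length (bp).
#' @slot intronMin,intronMax accepted tRNA intron length range (nt).
#' @slot bandMin,bandMax normal promoter offset band (nt upstream).
#' @slot fragmentBits minimum partial score for reporting tRNA fragments.
#' @slot consFloor minimum conserved-position score (bits) for a reported
#'   gene: the conserved core (U8, A14, G18/G19, U33, T-loop block, ...)
#'   is the identity signal that separates tRNAs from structural decoys.
#' @slot seed base RNG seed.
#' @export
setClass("RunConfig",
    representation(cutoffBits = "numeric", markovOrder = "integer",
                   nVirtualGenomes = "integer", motifWidth = "integer",
                   trainUpstream = "integer", scanUpstream = "integer",
                   operonGap = "integer", junctionMin = "integer",
                   junctionMax = "integer", minTransStem = "integer",
                   intronMin = "integer", intronMax = "integer",
                   bandMin = "integer", bandMax = "integer",
                   fragmentBits = "numeric", consFloor = "numeric",
                   seed = "integer"),
    validity = function(object) {
        if (object@junctionMin < 1L || object@junctionMax > 60L ||
            object@junctionMin >= object@junctionMax)
            return("junction range must lie within 1..60")
        if (object@intronMin > object@intronMax)
            return("intron length range is inverted")
        TRUE
    })

#' DiscoveryReport: per-genome result of the discovery pipeline
#'
#' @slot genomeId id of the analyzed sequence.
#' @slot genes `GRanges` of detected tRNA genes (isotype, anticodon, score,
#'   intron annotation in the metadata columns).
#' @slot fragments `GRanges` of sub-cutoff tRNA halves.
#' @slot missingAnticodons anticodons of the expected decoding set without a
#'   detected gene.
#' @slot promoters `DataFrame` of promoter hits (gene, offset, score,
#'   P-value, percentile, outlier flag).
#' @slot splitCandidates `DataFrame` of validated split (trans-spliced)
#'   tRNA candidates.
#' @slot permutedCandidates `DataFrame` of validated permuted tRNA
#'   candidates.
#' @slot config the `RunConfig` used.
#' @slot provenance list of seeds/counts recorded per stage.
#' @export
setClass("DiscoveryReport",
    representation(genomeId = "character", genes = "GRanges",
                   fragments = "GRanges", missingAnticodons = "character",
                   promoters = "DataFrame", splitCandidates = "DataFrame",
                   permutedCandidates = "DataFrame", config = "RunConfig",
                   provenance = "list"))

## ---- constructors -------------------------------------------------------

#' Construct a RunConfig
#'
#' @param ... named values overriding the defaults documented in
#'   [RunConfig-class].
#' @return a `RunConfig` object.
#' @examples
#' cfg <- runConfig(cutoffBits = 25)
#' @export
runConfig <- function(...) {
    defaults <- list(cutoffBits = 20, markovOrder = 5L, nVirtualGenomes = 10L,
                     motifWidth = 16L, trainUpstream = 90L, scanUpstream = 150L,
                     operonGap = 100L, junctionMin = 8L, junctionMax = 60L,
                     minTransStem = 10L, intronMin = 11L, intronMax = 129L,
                     bandMin = 30L, bandMax = 49L, fragmentBits = 8,
                     consFloor = 12, seed = 1L)
    over <- list(...)
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) stop("unknown RunConfig fields: ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
    intSlots <- vapply(defaults, is.numeric, TRUE) &
        !names(defaults) %in% c("cutoffBits", "fragmentBits", "consFloor")
    defaults[intSlots] <- lapply(defaults[intSlots], as.integer)
    do.call(new, c(list("RunConfig"), defaults))
}

## ---- show methods -------------------------------------------------------

setMethod("show", "MarkovBackground", function(object) {
    cat("MarkovBackground of order", object@order,
        "trained on", object@trainedOn, "\n")
    gc <- sum(colSums(object@prob[, 2:3, drop = FALSE] * object@contextFreq))
    cat("  contexts:", nrow(object@prob),
        sprintf("| stationary G+C ~ %.2f\n", gc))
})

setMethod("show", "CloverleafStructure", function(object) {
    cat(sprintf(
        "CloverleafStructure: %d nt | D stem %d bp, D loop %d nt, var loop %d nt%s%s\n",
        object@len, object@d, object@dloop, object@varlen,
        if (object@cca) ", 3'-CCA" else "",
        if (is.na(object@score)) "" else sprintf(" | %.1f bits", object@score)))
})

setMethod("show", "PromoterMotif", function(object) {
    cat("PromoterMotif: width", object@width, "| consensus",
        motifConsensus(object), "| trained on", object@nseq, "windows\n")
})

setMethod("show", "NullDistribution", function(object) {
    cat("NullDistribution:", length(object@scores), "best-hit scores from",
        object@nGenomes, "virtual genomes (seed", paste0(object@seed, ")"), "\n")
})

setMethod("show", "RunConfig", function(object) {
    cat("RunConfig:",
        sprintf("cutoff %.0f bits | Markov order %d | %d virtual genomes",
                object@cutoffBits, object@markovOrder, object@nVirtualGenomes),
        sprintf("| motif %d-mer | junctions %d-%d | min stem %d bp\n",
                object@motifWidth, object@junctionMin, object@junctionMax,
                object@minTransStem))
})

setMethod("show", "DiscoveryReport", function(object) {
    cat("DiscoveryReport for", object@genomeId, "\n")
    cat("  tRNA genes:          ", length(object@genes), "\n")
    cat("  tRNA fragments:      ", length(object@fragments), "\n")
    cat("  missing anticodons:  ", length(object@missingAnticodons), "\n")
    cat("  promoter hits:       ", nrow(object@promoters), "\n")
    cat("  split candidates:    ", nrow(object@splitCandidates), "\n")
    cat("  permuted candidates: ", nrow(object@permutedCandidates), "\n")
})

## ---- accessors ----------------------------------------------------------

#' @describeIn MarkovBackground-class chain order
#' @param bg a `MarkovBackground`.
#' @export
markovOrder <- function(bg) bg@order

#' @describeIn MarkovBackground-class conditional probability matrix
#' @export
markovProb <- function(bg) bg@prob

#' @describeIn PromoterMotif-class log-odds scoring matrix
#' @param motif a `PromoterMotif`.
#' @export
motifLogOdds <- function(motif) motif@logOdds

#' @describeIn PromoterMotif-class probability matrix
#' @export
motifProb <- function(motif) motif@prob

#' @describeIn PromoterMotif-class majority-base consensus string
#' @export
motifConsensus <- function(motif) {
    paste(BASES[apply(motif@prob, 2, which.max)], collapse = "")
}

#' @describeIn PromoterMotif-class total information content (bits)
#' @export
motifInformation <- function(motif) {
    p <- motif@prob
    sum(p * log2(pmax(p, 1e-12) / motif@bg))
}

#' @describeIn NullDistribution-class sorted null scores
#' @param null a `NullDistribution`.
#' @export
nullScores <- function(null) null@scores

#' @describeIn CloverleafStructure-class Sprinzl labels per residue
#' @param x a `CloverleafStructure`.
#' @export
sprinzlLabels <- function(x) x@sprinzl

#' @describeIn CloverleafStructure-class paired positions (5', 3') matrix
#' @export
structurePairs <- function(x) x@pairs

#' @describeIn CloverleafStructure-class bit score of the folded sequence
#' @export
structureScore <- function(x) x@score

#' @describeIn DiscoveryReport-class detected tRNA genes
#' @param report a `DiscoveryReport`.
#' @export
reportGenes <- function(report) report@genes

#' @describeIn DiscoveryReport-class detected tRNA fragments
#' @export
reportFragments <- function(report) report@fragments

#' @describeIn DiscoveryReport-class promoter hit table
#' @export
reportPromoters <- function(report) report@promoters

#' @describeIn DiscoveryReport-class split tRNA candidate table
#' @export
reportSplits <- function(report) report@splitCandidates

#' @describeIn DiscoveryReport-class permuted tRNA candidate table
#' @export
reportPermuted <- function(report) report@permutedCandidates

#' @describeIn DiscoveryReport-class missing anticodons
#' @export
reportMissingAnticodons <- function(report) report@missingAnticodons
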