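## Integer-coded DNA helpers shared by the scanners. Bases are coded
## A=1, C=2, G=3, T=4; code 5 is a scoring pad that never pairs.

BASES <- c("A", "C", "G", "T")

## Watson-Crick + wobble pairing tables, indexed [base1, base2].
## Class: 2 = WC, 1 = G.U wobble, 0 = mismatch, 3 = pad (ignored).
.makePairTables <- function() {
    cls <- matrix(0L, 5, 5)
    cls[1, 4] <- cls[4, 1] <- 2L            # A:T
    cls[2, 3] <- cls[3, 2] <- 2L            # C:G
    cls[3, 4] <- cls[4, 3] <- 1L            # G:T wobble
    cls[5, ] <- 3L
    cls[, 5] <- 3L
    sc <- matrix(-2.0, 5, 5)
    sc[1, 4] <- sc[4, 1] <- 1.5
    sc[2, 3] <- sc[3, 2] <- 2.0
    sc[3, 4] <- sc[4, 3] <- 0.8
    sc[5, ] <- 0
    sc[, 5] <- 0
    list(cls = cls, score = sc)
}
.PAIR <- .makePairTables()

#' Convert a DNA string to integer codes
#'
#' @param x character scalar, `DNAString`, or `DNAStringSet` of length 1.
#' @return integer vector with A=1, C=2, G=3, T=4 (anything else becomes NA).
#' @keywords internal
dnaToInt <- function(x) {
    if (!is.character(x)) x <- as.character(x)
    match(strsplit(toupper(x), "", fixed = TRUE)[[1]], BASES)
}

#' @keywords internal
intToDna <- function(v) paste(BASES[v], collapse = "")

#' Reverse complement of an integer-coded sequence
#' @keywords internal
revCompInt <- function(v) rev(5L - v)

#' Reverse complement of a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character scalar over A,C,G,T,N.
#' @return character scalar.
#' @export
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## TRUE where two integer-coded bases can pair (WC or G.U)
.canPair <- function(a, b) .PAIR$cls[cbind(a, b)] > 0L & .PAIR$cls[cbind(a, b)] < 3L

#' Read genome sequences from a FASTA file
#'
#' Records are normalized to uppercase and RNA-style U residues are mapped to
#' T, so downstream code works on a DNA alphabet. Empty records or records
#' with missing headers raise an error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by record id (first word of the
#'   header line).
#' @export
readGenomeFasta <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stop("no FASTA records in ", path)
    chr <- toupper(as.character(raw))
    chr <- chartr("U", "T", chr)
    ids <- sub("\\s.*$", "", names(raw))
    for (i in seq_along(chr)) {
        if (is.na(ids[i]) || !nzchar(ids[i]))
            stop("FASTA record ", i, " in ", path, " has an empty header")
        if (!nzchar(chr[i]))
            stop("FASTA record '", ids[i], "' in ", path, " is empty")
        if (grepl("[^ACGTN]", chr[i]))
            stop("FASTA record '", ids[i], "' contains non-ACGTN residues")
    }
    out <- Biostrings::DNAStringSet(chr)
    names(out) <- ids
    out
}

#' Write genome sequences to a FASTA file
#'
#' @param seqs a named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return `path`, invisibly. Sequence lines are wrapped at 60 columns.
#' @export
writeGenomeFasta <- function(seqs, path) {
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path, width = 60L)
    invisible(path)
}

#' Extract sequence for genomic intervals
#'
#' Coordinates follow the Bioconductor convention (1-based, inclusive, as in
#' `GRanges`); minus-strand intervals return the reverse complement of the
#' plus-strand slice. On a circular sequence an interval may wrap past the
#' end when `circular = TRUE`.
#'
#' @param genome a [Biostrings::DNAStringSet] (named) or single `DNAString`.
#' @param gr a [GenomicRanges::GRanges] of intervals to extract.
#' @param circular treat sequences as circular (allow wraparound).
#' @return character vector of extracted sequences, one per interval.
#' @export
extractInterval <- function(genome, gr, circular = FALSE) {
    if (is(genome, "DNAString")) {
        genome <- Biostrings::DNAStringSet(list(x = genome))
        names(genome) <- as.character(GenomicRanges::seqnames(gr))[1]
    }
    out <- character(length(gr))
    for (i in seq_along(gr)) {
        sid <- as.character(GenomicRanges::seqnames(gr))[i]
        if (!sid %in% names(genome)) stop("unknown seqid: ", sid)
        seq <- genome[[sid]]
        n <- length(seq)
        s <- GenomicRanges::start(gr)[i]
        e <- GenomicRanges::end(gr)[i]
        if (s < 1L || s > e) stop("invalid interval [", s, ",", e, "]")
        if (e > n) {
            if (!circular) stop("interval [", s, ",", e,
                                "] out of bounds for '", sid, "' (length ", n, ")")
            body <- paste0(as.character(Biostrings::subseq(seq, s, n)),
                           as.character(Biostrings::subseq(seq, 1L, e - n)))
        } else {
            body <- as.character(Biostrings::subseq(seq, s, e))
        }
        if (as.character(GenomicRanges::strand(gr))[i] == "-") body <- revComp(body)
        out[i] <- body
    }
    out
}

#' Read gene annotations from a GFF3 file
#'
#' @param path path to a GFF3 file.
#' @return a `GRanges` with at least `type` and, where present, `ID`,
#'   `product` and `gene` metadata columns.
#' @export
readAnnotations <- function(path) {
    if (!file.exists(path)) stop("GFF3 file not found: ", path)
    rtracklayer::import(path, format = "gff3")
}

#' URL of a RefSeq nucleotide record
#'
#' Documented fetch helper only: builds the NCBI efetch URL for a RefSeq
#' accession so the cited genomes can be retrieved where network access is
#' available. No download is performed by this package.
#'
#' @param accession RefSeq accession, e.g. `"NC_000854"`.
#' @return character URL returning the sequence in FASTA format.
#' @export
refseqUrl <- function(accession) {
    paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
           "?db=nuccore&rettype=fasta&retmode=text&id=", accession)
}
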