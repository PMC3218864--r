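## Discovery pipeline: scan -> inventory -> promoters -> split/permuted.

.writeGff3 <- function(gr, path) {
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

.grBare <- function(gr) {
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                           IRanges::IRanges(GenomicRanges::start(gr),
                                            GenomicRanges::end(gr)),
                           GenomicRanges::strand(gr))
}

.trnaUpstreamRegions <- function(genes, fragments, genome, width) {
    all <- c(.grBare(genes), .grBare(fragments))
    ids <- c(if (length(genes)) paste0("gene", seq_along(genes)),
             if (length(fragments)) paste0("frag", seq_along(fragments)))
    if (length(all) == 0L)
        return(data.frame(geneId = character(0), window = character(0),
                          stringsAsFactors = FALSE))
    win <- upstreamWindows(all, genome, width)
    data.frame(geneId = ids, window = win$seq, stringsAsFactors = FALSE)
}

#' Run the full discovery pipeline on one genome
#'
#' Stages: (1) structural tRNA scan of both strands (genes, canonical
#' introns, candidate halves); (2) decoding-set inventory; (3) promoter
#' identification - motif training on operon-leading known genes when
#' annotations are available (otherwise the packaged template motif,
#' flagged in the provenance), PSSM scan of 150-nt upstream regions of all
#' annotated genes and tRNA loci, empirical P-values from virtual genomes,
#' spacing-outlier analysis; (4) split-tRNA discovery via orphan-half
#' trans-pairing search and via promoters found inside long introns;
#' (5) permuted-tRNA discovery at promoter-spacing outliers. Deterministic
#' for a fixed config seed.
#'
#' @param genome path to a FASTA file, or a named `DNAStringSet`.
#' @param annotations optional path to a GFF3 file or a `GRanges` with
#'   `product` metadata (used for promoter training).
#' @param config a [RunConfig-class].
#' @param outDir optional output directory; when given, GFF3/TSV/JSON
#'   reports are written.
#' @return a [DiscoveryReport-class].
#' @export
runDiscovery <- function(genome, annotations = NULL, config = runConfig(),
                         outDir = NULL) {
    if (is.character(genome)) genome <- readGenomeFasta(genome)
    if (!is(genome, "DNAStringSet")) {
        genome <- Biostrings::DNAStringSet(list(as(genome, "DNAString")))
        names(genome) <- "genome"
    }
    seqid <- names(genome)[1]
    gseq <- genome[[1]]
    if (is.character(annotations)) annotations <- readAnnotations(annotations)
    provenance <- list(seed = config@seed, genomeLength = length(gseq))

    ## stage 1: structural scan
    scan <- scanGenome(gseq, config, seqid = seqid)
    genes <- scan$genes; fragments <- scan$fragments
    provenance$nGenes <- length(genes)
    provenance$nFragments <- length(fragments)

    ## stage 2: inventory
    missing <- if (length(genes)) inventoryCheck(genes) else archaealAnticodons()

    ## stage 3: promoters
    trained <- FALSE
    trainScores <- numeric(0)
    if (!is.null(annotations) &&
        !is.null(S4Vectors::mcols(annotations)$product)) {
        training <- selectTrainingGenes(annotations, genome, config)
        if (nrow(training) >= 5L) {
            motif <- suppressWarnings(
                discoverMotif(training$window, width = config@motifWidth,
                              restarts = 20L, seed = config@seed))
            trained <- TRUE
            sel <- match(training$geneId,
                         as.character(S4Vectors::mcols(annotations)$ID))
            tw <- upstreamWindows(annotations[sel[!is.na(sel)]], genome,
                                  config@scanUpstream)
            th <- .bestHits(motif, tw$seq)
            trainScores <- th$score[!is.na(th$score)]
        }
    }
    if (!trained) motif <- promoterTemplate()
    provenance$motifTrained <- trained
    bg <- trainMarkov(gseq, order = config@markovOrder, id = seqid)
    null <- buildNull(motif, bg, genomeLength = length(gseq),
                      n = config@nVirtualGenomes, seed = config@seed,
                      windowWidth = config@scanUpstream)
    pThr <- if (length(trainScores))
        max(pvalueFromNull(null, trainScores)) else 0.05
    provenance$promoterPvalueThreshold <- pThr

    regions <- .trnaUpstreamRegions(genes, fragments, genome,
                                    config@scanUpstream)
    hits <- scanUpstream(motif, regions)
    hits$pvalue <- ifelse(is.na(hits$score), NA_real_,
                          pvalueFromNull(null, hits$score))
    allScores <- hits$score[!is.na(hits$score)]
    hits$percentile <- vapply(hits$score, function(s)
        if (is.na(s) || !length(allScores)) NA_real_
        else mean(allScores <= s), numeric(1))
    quality <- hits
    quality$offset[!is.na(quality$pvalue) & quality$pvalue > pThr] <- NA
    out <- suppressWarnings(
        spacingOutliers(quality, bandMax = config@bandMax,
                        reference = grepl("^gene", quality$geneId),
                        slack = config@motifWidth))
    hits$outlier <- out$outlier

    ## stage 4: splits
    splits <- searchSplitPartners(fragments, gseq, config)
    intronSplits <- list()
    for (i in seq_along(genes)) {
        cand <- .splitFromIntronGene(genes[i], genome, motif, null, pThr,
                                     config)
        if (!is.null(cand)) intronSplits[[length(intronSplits) + 1L]] <- cand
    }
    if (length(intronSplits)) {
        splits <- S4Vectors::DataFrame(
            rbind(as.data.frame(splits), do.call(rbind, intronSplits)))
    }
    provenance$nSplitCandidates <- nrow(splits)

    ## stage 5: permuted. Spacing-outlier genes are re-examined as
    ## candidate 5' parts: a permuted precursor can fold into a spurious
    ## low-quality full-gene call spanning its intervening sequence.
    frs <- fragments
    if (length(frs))
        S4Vectors::mcols(frs)$fragId <- paste0("frag", seq_along(frs))
    views <- .genomeViews(gseq)
    outGenes <- which(hits$outlier[grepl("^gene", hits$geneId)])
    for (k in outGenes) {
        extra <- .fivePartFromGene(genes[k], paste0("gene", k), views, config)
        if (!is.null(extra)) frs <- c(frs, extra)
    }
    permuted <- detectPermuted(frs, out, gseq, config)
    provenance$nPermutedCandidates <- nrow(permuted)
    ## genes superseded by a permuted candidate are re-assigned
    if (nrow(permuted) > 0L && length(genes) > 0L) {
        drop <- logical(length(genes))
        for (k in seq_len(nrow(permuted))) {
            drop <- drop | (GenomicRanges::start(genes) <= permuted$fiveEnd[k] &
                            GenomicRanges::end(genes) >= permuted$fiveStart[k])
        }
        if (any(drop)) {
            genes <- genes[!drop]
            missing <- if (length(genes)) inventoryCheck(genes)
                       else archaealAnticodons()
            provenance$nGenesReassigned <- sum(drop)
            provenance$nGenes <- length(genes)
        }
    }

    report <- new("DiscoveryReport", genomeId = seqid, genes = genes,
                  fragments = fragments, missingAnticodons = missing,
                  promoters = S4Vectors::DataFrame(hits),
                  splitCandidates = splits, permutedCandidates = permuted,
                  config = config, provenance = provenance)
    if (!is.null(outDir)) writeReport(report, outDir)
    report
}

#' Write a Table-1-style candidate report
#'
#' One row per split or permuted candidate, with the column set of the
#' published summary table (organism, isotype, anticodon, half 5' starts
#' with strand, precursor/mature sizes, ligation site, intron position)
#' followed by evidence columns (trans-stem length, BHB class, joined
#' score, orientation, separation, source). Precursor sizes are mature
#' size plus a fixed 15-nt leader/trailer window and are marked
#' approximate.
#'
#' @param report a [DiscoveryReport-class].
#' @param path optional output TSV path.
#' @return the table as a `data.frame`, invisibly when `path` is given.
#' @export
writeTable1 <- function(report, path = NULL) {
    fmtStart <- function(s, strand) sprintf("%d (%s)", s, strand)
    rows <- list()
    sp <- as.data.frame(report@splitCandidates)
    for (i in seq_len(nrow(sp))) {
        m5 <- sp$fiveEnd[i] - sp$fiveStart[i] + 1L
        m3 <- sp$threeEnd[i] - sp$threeStart[i] + 1L
        rows[[length(rows) + 1L]] <- data.frame(
            Organism = report@genomeId, Isotype = sp$isotype[i],
            Anticodon = chartr("T", "U", sp$anticodon[i]),
            FiveStart = fmtStart(sp$fiveStart[i], sp$fiveStrand[i]),
            FiveSizePre = sprintf("~%d", m5 + 15L), FiveSizeMature = m5,
            ThreeStart = fmtStart(sp$threeStart[i], sp$threeStrand[i]),
            ThreeSizePre = sprintf("~%d", m3 + 15L), ThreeSizeMature = m3,
            LigationSite = sp$junction[i], IntronPosition = "",
            StemLength = sp$stemLen[i], BhbClass = sp$bhbClass[i],
            JoinedScore = round(sp$joinedScore[i], 2),
            Orientation = sp$orientation[i], Separation = sp$separation[i],
            Source = sp$source[i], stringsAsFactors = FALSE)
    }
    pm <- as.data.frame(report@permutedCandidates)
    for (i in seq_len(nrow(pm))) {
        m5 <- pm$fiveEnd[i] - pm$fiveStart[i] + 1L
        m3 <- pm$threeEnd[i] - pm$threeStart[i] + 1L
        rows[[length(rows) + 1L]] <- data.frame(
            Organism = report@genomeId, Isotype = pm$isotype[i],
            Anticodon = chartr("T", "U", pm$anticodon[i]),
            FiveStart = fmtStart(pm$fiveStart[i], pm$strand[i]),
            FiveSizePre = sprintf("~%d", m5 + 15L), FiveSizeMature = m5,
            ThreeStart = fmtStart(pm$threeStart[i], pm$strand[i]),
            ThreeSizePre = sprintf("~%d", m3 + 15L), ThreeSizeMature = m3,
            LigationSite = pm$junction[i],
            IntronPosition = ifelse(is.na(pm$intronSprinzl[i]), "",
                                    pm$intronSprinzl[i]),
            StemLength = NA_integer_, BhbClass = pm$bhbClass[i],
            JoinedScore = round(pm$joinedScore[i], 2),
            Orientation = "permuted",
            Separation = pm$intervening[i], Source = "promoter_outlier",
            stringsAsFactors = FALSE)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else data.frame(
        Organism = character(0), Isotype = character(0),
        Anticodon = character(0), FiveStart = character(0),
        FiveSizePre = character(0), FiveSizeMature = integer(0),
        ThreeStart = character(0), ThreeSizePre = character(0),
        ThreeSizeMature = integer(0), LigationSite = character(0),
        IntronPosition = character(0), StemLength = integer(0),
        BhbClass = character(0), JoinedScore = numeric(0),
        Orientation = character(0), Separation = integer(0),
        Source = character(0), stringsAsFactors = FALSE)
    if (!is.null(path)) {
        write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(tab))
    }
    tab
}

#' Write all reports of a discovery run
#'
#' Writes tRNA genes and fragments as GFF3, the Table-1-style candidate
#' table and promoter hits as TSV, and the full report as JSON.
#'
#' @param report a [DiscoveryReport-class].
#' @param dir output directory (created if needed).
#' @return written paths, invisibly.
#' @export
writeReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    g <- report@genes
    S4Vectors::mcols(g)$type <- rep("tRNA", length(g))
    gff <- file.path(dir, "trna_genes.gff3")
    .writeGff3(g, gff)
    f <- report@fragments
    S4Vectors::mcols(f)$type <- rep("tRNA_fragment", length(f))
    gff2 <- file.path(dir, "trna_fragments.gff3")
    .writeGff3(f, gff2)
    paths <- c(paths, gff, gff2)
    t1 <- file.path(dir, "table1.tsv")
    writeTable1(report, t1)
    paths <- c(paths, t1)
    pr <- file.path(dir, "promoters.tsv")
    write.table(as.data.frame(report@promoters), pr, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, pr)
    js <- file.path(dir, "report.json")
    jsonlite::write_json(list(
        genomeId = report@genomeId,
        genes = as.data.frame(report@genes),
        fragments = as.data.frame(report@fragments),
        missingAnticodons = report@missingAnticodons,
        promoters = as.data.frame(report@promoters),
        splitCandidates = as.data.frame(report@splitCandidates),
        permutedCandidates = as.data.frame(report@permutedCandidates),
        provenance = report@provenance),
        js, dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA)
    paths <- c(paths, js)
    invisible(paths)
}
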