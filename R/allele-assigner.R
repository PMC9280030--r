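#' Extract SNP observations from aligned reads
#'
#' Walks each alignment's CIGAR and, for every interspecies SNP whose
#' reference position is consumed by an aligned (M/=/X) operation, emits
#' the read base observed there together with its vote: \code{CATTLE} if
#' it equals the cattle allele, \code{YAK} if the yak allele,
#' \code{OTHER} otherwise (sequencing error or N).  Positions under
#' deletions (D) or introns (N) yield no observation; insertions and
#' soft clips consume read only; hard-clipped bases are gone and simply
#' yield no observation.
#'
#' @param alignments A \code{GAlignments} from [readSamAlignments()].
#'   Only primary alignments are used.
#' @param snps A width-1 SNP \code{GRanges} with \code{cattle}/\code{yak}
#'   metadata columns.
#' @return A \code{DataFrame} with columns \code{readId}, \code{chrom},
#'   \code{pos}, \code{base}, \code{vote} (factor CATTLE/YAK/OTHER), one
#'   row per (read, covered SNP) pair.
#' @export
snpObservations <- function(alignments, snps) {
    stopifnot(is(alignments, "GAlignments"))
    alignments <- alignments[mcols(alignments)$isPrimary]
    emptyOut <- DataFrame(readId = character(0), chrom = character(0),
                          pos = integer(0), base = character(0),
                          vote = factor(character(0),
                                        levels = c("CATTLE", "YAK", "OTHER")))
    if (length(alignments) == 0L || length(snps) == 0L) return(emptyOut)
    cig <- cigar(alignments)
    refBlocks <- cigarRangesAlongReferenceSpace(
        cig, pos = start(alignments), ops = c("M", "=", "X"))
    qryBlocks <- cigarRangesAlongQuerySpace(
        cig, ops = c("M", "=", "X"))
    nb <- lengths(refBlocks)
    readOfBlock <- rep(seq_along(alignments), nb)
    refFlat <- unlist(refBlocks, use.names = FALSE)
    qryFlat <- unlist(qryBlocks, use.names = FALSE)
    blockGr <- GRanges(seqnames(alignments)[readOfBlock], refFlat)
    hits <- GenomicRanges::findOverlaps(snps, blockGr, ignore.strand = TRUE)
    if (length(hits) == 0L) return(emptyOut)
    snpIdx <- queryHits(hits)
    blkIdx <- subjectHits(hits)
    readIdx <- readOfBlock[blkIdx]
    offset <- start(snps)[snpIdx] - start(refFlat)[blkIdx]
    qpos <- start(qryFlat)[blkIdx] + offset
    base <- as.character(subseq(mcols(alignments)$seq[readIdx],
                                start = qpos, width = 1L))
    cattle <- mcols(snps)$cattle[snpIdx]
    yak <- mcols(snps)$yak[snpIdx]
    vote <- factor(ifelse(base == cattle, "CATTLE",
                   ifelse(base == yak, "YAK", "OTHER")),
                   levels = c("CATTLE", "YAK", "OTHER"))
    DataFrame(readId = mcols(alignments)$qname[readIdx],
              chrom = as.character(seqnames(snps))[snpIdx],
              pos = start(snps)[snpIdx],
              base = base,
              vote = vote)
}

#' Call parental origin of reads by the mode rule
#'
#' Tallies each read's SNP votes and applies the mode (majority) rule:
#' \code{CATTLE} if cattle votes outnumber yak votes, \code{YAK} for the
#' converse, \code{AMBIGUOUS} on a non-zero tie, and
#' \code{UNINFORMATIVE} when the read carries no informative vote at all.
#' \code{OTHER} votes (read base matching neither allele) are counted but
#' never decisive.  The result is invariant to observation order.
#'
#' @param observations A \code{DataFrame} from [snpObservations()].
#' @param readIds Optional character vector of read IDs to report even if
#'   they have no observations (these come out \code{UNINFORMATIVE});
#'   defaults to the reads present in \code{observations}.
#' @return A \code{DataFrame} with columns \code{readId}, \code{nCattle},
#'   \code{nYak}, \code{nOther}, \code{call} (factor
#'   CATTLE/YAK/AMBIGUOUS/UNINFORMATIVE).
#' @export
callReadOrigins <- function(observations, readIds = NULL) {
    if (is.null(readIds)) readIds <- unique(observations$readId)
    f <- factor(observations$readId, levels = readIds)
    tab <- table(f, observations$vote)
    nCattle <- as.integer(tab[, "CATTLE"])
    nYak <- as.integer(tab[, "YAK"])
    nOther <- as.integer(tab[, "OTHER"])
    call <- ifelse(nCattle > nYak, "CATTLE",
            ifelse(nYak > nCattle, "YAK",
            ifelse(nCattle > 0L, "AMBIGUOUS", "UNINFORMATIVE")))
    DataFrame(readId = readIds, nCattle = nCattle, nYak = nYak,
              nOther = nOther,
              call = factor(call, levels = c("CATTLE", "YAK", "AMBIGUOUS",
                                             "UNINFORMATIVE")))
}

#' Attach reads to genes by exonic overlap
#'
#' Full-length cDNA reads are spliced, so a read is attached to the gene
#' whose exons share the most aligned reference bases with it; ties are
#' broken by larger whole-span overlap, then by lexicographic gene ID
#' (deterministic).  Reads with zero exonic overlap get \code{NA}.
#'
#' @param alignments A \code{GAlignments}; only primary alignments are
#'   assigned (others get \code{NA}).
#' @param genes A \code{GRangesList} of exons per gene.
#' @return Character vector of gene IDs (or \code{NA}), one per
#'   alignment.
#' @export
assignReadsToGenes <- function(alignments, genes) {
    out <- rep(NA_character_, length(alignments))
    if (length(alignments) == 0L || length(genes) == 0L) return(out)
    use <- which(mcols(alignments)$isPrimary)
    if (length(use) == 0L) return(out)
    al <- alignments[use]
    refBlocks <- cigarRangesAlongReferenceSpace(
        cigar(al), pos = start(al), ops = c("M", "=", "X"))
    nb <- lengths(refBlocks)
    readOfBlock <- rep(seq_along(al), nb)
    refFlat <- unlist(refBlocks, use.names = FALSE)
    blockGr <- GRanges(seqnames(al)[readOfBlock], refFlat)

    exFlat <- unlist(genes, use.names = FALSE)
    geneOfExon <- rep(seq_along(genes), lengths(genes))
    hits <- GenomicRanges::findOverlaps(blockGr, exFlat, ignore.strand = TRUE)
    if (length(hits) == 0L) return(out)
    w <- width(IRanges::pintersect(
        IRanges::ranges(blockGr)[queryHits(hits)],
        IRanges::ranges(exFlat)[subjectHits(hits)]))
    readIdx <- readOfBlock[queryHits(hits)]
    geneIdx <- geneOfExon[subjectHits(hits)]
    key <- paste(readIdx, geneIdx)
    agg <- rowsum(w, key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    aggRead <- as.integer(vapply(parts, `[`, character(1), 1))
    aggGene <- as.integer(vapply(parts, `[`, character(1), 2))
    exonicOv <- as.numeric(agg[, 1])

    # tie-breaks: whole-span overlap, then lexicographic gene id
    span <- unlist(range(genes))
    readSpan <- GRanges(seqnames(al), IRanges(start(al), end(al)))
    sh <- GenomicRanges::findOverlaps(readSpan, span, ignore.strand = TRUE)
    sw <- width(IRanges::pintersect(
        IRanges::ranges(readSpan)[queryHits(sh)],
        IRanges::ranges(span)[subjectHits(sh)]))
    spanKey <- paste(queryHits(sh), subjectHits(sh))
    spanOv <- sw[match(paste(aggRead, aggGene), spanKey)]
    spanOv[is.na(spanOv)] <- 0

    geneIds <- names(genes)
    ord <- order(aggRead, -exonicOv, -spanOv, geneIds[aggGene])
    best <- !duplicated(aggRead[ord])
    out[use[aggRead[ord][best]]] <- geneIds[aggGene[ord][best]]
    out
}

#' Assign parental origin and gene to every primary alignment
#'
#' End-to-end per-read assignment: SNP observations via CIGAR walking,
#' mode-rule origin call, and exonic-overlap gene attachment.  Every
#' primary alignment yields exactly one row (possibly with \code{NA}
#' gene).  The number of non-primary alignments set aside is recorded in
#' \code{metadata(x)$skipped["nonPrimary"]}.
#'
#' @param alignments A \code{GAlignments} from [readSamAlignments()].
#' @param snps SNP \code{GRanges} (typically already homology-restricted).
#' @param genes \code{GRangesList} of exons per retained gene.
#' @return A \code{DataFrame} with columns \code{readId}, \code{geneId},
#'   \code{nCattle}, \code{nYak}, \code{nOther}, \code{call}.
#' @export
assignAlleles <- function(alignments, snps, genes) {
    primary <- mcols(alignments)$isPrimary
    al <- alignments[primary]
    obs <- snpObservations(al, snps)
    calls <- callReadOrigins(obs, readIds = mcols(al)$qname)
    geneId <- assignReadsToGenes(al, genes)
    out <- DataFrame(readId = calls$readId,
                     geneId = geneId[match(calls$readId, mcols(al)$qname)],
                     nCattle = calls$nCattle, nYak = calls$nYak,
                     nOther = calls$nOther, call = calls$call)
    metadata(out)$skipped <- c(nonPrimary = sum(!primary))
    out
}
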