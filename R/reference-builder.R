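#' Extract merged homologous blocks from a whole-genome alignment
#'
#' Filters PAF records (minimum block length, minimum mapping quality,
#' allowed chromosomes — typically the autosomes, since sex chromosomes
#' are excluded from allelic analysis) and merges the retained target
#' intervals per chromosome into disjoint homologous blocks on the
#' primary (cattle) reference.  Overlapping records are reconciled by
#' merging on primary coordinates; the mate (secondary-species)
#' coordinates of a merged block are taken from its dominant — longest —
#' contributing record.
#'
#' @param paf A PAF data frame from [readPaf()]; targets must be the
#'   primary reference.
#' @param minBlockLen Minimum alignment block length in bp (default 1000).
#' @param minMapq Minimum mapping quality (default 0; asm-preset
#'   whole-genome alignments carry mapq 60 or 0).
#' @param allowedChroms Character vector of primary chromosomes to keep
#'   (default: all chromosomes seen in the PAF).
#' @return A [HomologyMap-class].
#' @export
extractHomologyBlocks <- function(paf, minBlockLen = 1000L, minMapq = 0L,
                                  allowedChroms = NULL) {
    chromLengths <- tapply(paf$targetLen, paf$targetName, function(x) x[1])
    keep <- paf$blockLen >= minBlockLen & paf$mapq >= minMapq
    if (!is.null(allowedChroms))
        keep <- keep & paf$targetName %in% allowedChroms
    paf <- paf[keep, , drop = FALSE]
    if (nrow(paf) == 0L)
        stop("no homologous regions remain after filtering")
    sl <- chromLengths[names(chromLengths) %in% unique(paf$targetName)]
    gr <- GRanges(paf$targetName,
                  IRanges(paf$targetStart, paf$targetEnd),
                  seqlengths = structure(as.integer(sl), names = names(sl)))
    merged <- GenomicRanges::reduce(sort(gr))
    # dominant contributing record per merged block = the longest one
    ov <- GenomicRanges::findOverlaps(merged, gr)
    blen <- paf$blockLen[subjectHits(ov)]
    ord <- order(queryHits(ov), -blen)
    first <- !duplicated(queryHits(ov)[ord])
    dom <- subjectHits(ov)[ord][first]
    stopifnot(length(dom) == length(merged))
    mcols(merged)$mateChrom <- paf$queryName[dom]
    mcols(merged)$mateStart <- paf$queryStart[dom]
    mcols(merged)$mateEnd <- paf$queryEnd[dom]
    mcols(merged)$mateStrand <- paf$strand[dom]
    HomologyMap(merged)
}

#' Fraction of the genome covered by homologous blocks
#'
#' Total merged block length over total chromosome length — the statistic
#' behind "what share of the autosomes has a one-to-one counterpart in
#' the other species".
#'
#' @param map A [HomologyMap-class].
#' @return A fraction in \code{[0, 1]}.
#' @export
homologousFraction <- function(map) {
    sl <- GenomeInfoDb::seqlengths(map)
    if (any(sl <= 0L)) stop("chromosome lengths must be positive")
    sum(as.numeric(width(map))) / sum(as.numeric(sl))
}

#' Restrict SNP sites to homologous blocks
#'
#' Interspecies SNPs are only meaningful where the two genomes are
#' homologous; sites outside every block are dropped (order preserved).
#'
#' @param snps A SNP \code{GRanges} from [readVcfSnps()].
#' @param map A [HomologyMap-class].
#' @return The retained subset of \code{snps}.
#' @export
restrictSnps <- function(snps, map) {
    IRanges::subsetByOverlaps(snps, map, ignore.strand = TRUE)
}

#' N-mask SNP sites in a genome
#'
#' Replaces the base at every SNP position with \code{N} so that long
#' reads from either parental haplotype align without a reference-allele
#' advantage.  Sequence lengths are unchanged and the number of new
#' \code{N}s equals the number of masked sites.
#'
#' @param genome A \code{DNAStringSet}.
#' @param snps A width-1 SNP \code{GRanges}; every chromosome must be
#'   present in \code{genome} and every position in range.
#' @return The masked \code{DNAStringSet}.
#' @export
maskSnps <- function(genome, snps) {
    chroms <- as.character(seqnames(snps))
    missing <- setdiff(unique(chroms), names(genome))
    if (length(missing))
        stop("SNP chromosome(s) not in genome: ",
             paste(missing, collapse = ", "))
    out <- genome
    chromLen <- setNames(Biostrings::width(genome), names(genome))
    for (ch in unique(chroms)) {
        pos <- start(snps)[chroms == ch]
        if (any(pos < 1L | pos > chromLen[[ch]])) {
            bad <- pos[pos < 1L | pos > chromLen[[ch]]][1]
            stop("SNP position out of range: ", ch, ":", bad)
        }
        out[[ch]] <- replaceLetterAt(out[[ch]], pos,
                                     strrep("N", length(pos)))
    }
    out
}

#' Partition genes by homologous-region overlap
#'
#' A gene is retained when the covered fraction of its genomic span is at
#' least \code{minOverlapFraction} (default 1: the gene must lie wholly
#' within homologous sequence).  The partition is exhaustive and
#' disjoint.
#'
#' @param genes A \code{GRangesList} of exons per gene from
#'   [readGffGenes()].
#' @param map A [HomologyMap-class].
#' @param minOverlapFraction Required covered fraction of the gene span,
#'   in \code{(0, 1]}.
#' @return A list with elements \code{retained} and \code{excluded}, both
#'   \code{GRangesList}s.
#' @export
classifyGenes <- function(genes, map, minOverlapFraction = 1.0) {
    if (!(minOverlapFraction > 0 && minOverlapFraction <= 1))
        stop("minOverlapFraction must be in (0, 1]")
    if (length(genes) == 0L)
        return(list(retained = genes, excluded = genes))
    span <- unlist(range(genes))
    hits <- GenomicRanges::findOverlaps(span, map, ignore.strand = TRUE)
    covered <- numeric(length(span))
    if (length(hits)) {
        w <- width(IRanges::pintersect(
            IRanges::ranges(span)[queryHits(hits)],
            IRanges::ranges(map)[subjectHits(hits)]))
        covered <- as.numeric(tapply(w, factor(queryHits(hits),
                                               levels = seq_along(span)),
                                     sum))
        covered[is.na(covered)] <- 0
    }
    frac <- covered / width(span)
    keep <- frac >= minOverlapFraction
    list(retained = genes[keep], excluded = genes[!keep])
}

#' Build the homology-restricted, SNP-masked analysis scaffold
#'
#' One-call wrapper over the reference-construction steps: extract and
#' merge homologous blocks from the whole-genome alignment, restrict the
#' SNP catalog to those blocks, N-mask the restricted sites in the
#' primary genome, and partition the annotation into genes inside vs
#' outside homologous sequence.
#'
#' @inheritParams extractHomologyBlocks
#' @inheritParams classifyGenes
#' @param snps SNP \code{GRanges} from [readVcfSnps()].
#' @param genome Primary genome \code{DNAStringSet}.
#' @param genes \code{GRangesList} from [readGffGenes()].
#' @return A list with \code{map}, \code{snps} (restricted),
#'   \code{maskedGenome}, \code{genes} (retained), \code{excludedGenes}.
#' @export
buildReference <- function(paf, snps, genome, genes,
                           minBlockLen = 1000L, minMapq = 0L,
                           allowedChroms = NULL, minOverlapFraction = 1.0) {
    map <- extractHomologyBlocks(paf, minBlockLen = minBlockLen,
                                 minMapq = minMapq,
                                 allowedChroms = allowedChroms)
    restricted <- restrictSnps(snps, map)
    masked <- maskSnps(genome, restricted)
    part <- classifyGenes(genes, map, minOverlapFraction)
    list(map = map, snps = restricted, maskedGenome = masked,
         genes = part$retained, excludedGenes = part$excluded)
}
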