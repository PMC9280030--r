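suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
    library(GenomicRanges)
    library(Biostrings)
})

# write a minimal SAM file from per-read vectors; returns the path
writeTestSam <- function(qname, flag, chrom, pos, cigar, seq,
                         seqLengths = c(chr1 = 1000L), mapq = 60L,
                         path = tempfile(fileext = ".sam")) {
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqLengths),
                     as.integer(seqLengths)))
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                   qname, as.integer(flag), chrom, as.integer(pos),
                   as.integer(mapq), cigar, seq)
    writeLines(c(hdr, rec), path)
    path
}

# width-1 SNP GRanges with cattle/yak alleles
makeSnps <- function(chrom, pos, cattle, yak) {
    gr <- GRanges(rep(chrom, length.out = length(pos)),
                  IRanges(pos, width = 1L))
    mcols(gr)$cattle <- cattle
    mcols(gr)$yak <- yak
    gr
}

# one-gene GRangesList of exons
makeGene <- function(id, chrom, starts, ends, strand = "+") {
    grl <- GRangesList(GRanges(chrom, IRanges(starts, ends),
                               strand = strand))
    names(grl) <- id
    grl
}

# HomologyMap from plain block coordinates
makeMap <- function(chrom, starts, ends, chromLen) {
    gr <- GRanges(chrom, IRanges(starts, ends),
                  seqlengths = chromLen)
    mcols(gr)$mateChrom <- as.character(chrom)
    mcols(gr)$mateStart <- starts
    mcols(gr)$mateEnd <- ends
    mcols(gr)$mateStrand <- "+"
    HomologyMap(gr)
}

# tally DataFrame shortcut
makeTally <- function(geneId, ic, iy, u, amb = 0L, sampleId = "S1") {
    DataFrame(geneId = geneId, sampleId = sampleId,
              informativeCattle = as.integer(ic),
              informativeYak = as.integer(iy),
              uninformative = as.integer(u),
              ambiguous = as.integer(amb))
}

# assemble an AlleleExpressionSet from parallel tally lists
makeAset <- function(tallies, tissues = NULL, totalMapped = NULL) {
    ids <- names(tallies)
    if (is.null(tissues)) tissues <- rep("lung", length(ids))
    meta <- data.frame(sampleId = ids,
                       animalId = paste0("A", seq_along(ids)),
                       tissue = tissues,
                       sireSpecies = "cattle",
                       stringsAsFactors = FALSE)
    if (is.null(totalMapped))
        totalMapped <- setNames(vapply(tallies, function(x)
            sum(x$informativeCattle + x$informativeYak +
                x$uninformative + x$ambiguous), integer(1)), ids)
    AlleleExpressionSet(tallies, meta, totalMapped)
}
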