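#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   alphabetFrequency replaceLetterAt subseq reverseComplement DNAString
#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag scanBam
#' @importFrom GenomicAlignments readGAlignments cigar qwidth njunc
#'   cigarRangesAlongReferenceSpace cigarRangesAlongQuerySpace
#' @importFrom rtracklayer import export
#' @importFrom utils read.table write.table
NULL

## All printed-format coordinate conversions live in this file.  Internal
## convention is the Bioconductor one: 1-based, closed IRanges/GRanges.
## PAF and BED are 0-based half-open on disk; VCF, SAM and GFF3 are 1-based.

#' Read a genome FASTA
#'
#' Loads a (masked or unmasked) genome as a \code{DNAStringSet}.  Only the
#' bases A, C, G, T and N are accepted; any other IUPAC code is rejected
#' with an error, since the allele-vote logic assumes unambiguous parental
#' alleles and N-masked SNP sites.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{DNAStringSet}.
#' @export
readGenome <- function(path) {
    x <- readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    if (length(x) == 0L || any(Biostrings::width(x) < 1L))
        stop("genome sequences must have length >= 1")
    af <- alphabetFrequency(x)
    bad <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
    if (any(bad > 0))
        stop("sequence '", names(x)[which(bad > 0)[1]],
             "' contains bases outside {A,C,G,T,N}")
    x
}

#' Write a genome FASTA
#'
#' @param x A \code{DNAStringSet}.
#' @param path Output path; lines wrapped at 60 columns.
#' @return \code{path}, invisibly.
#' @export
writeGenome <- function(x, path) {
    writeXStringSet(x, path, width = 60L)
    invisible(path)
}

.pafCols <- c("queryName", "queryLen", "queryStart", "queryEnd", "strand",
              "targetName", "targetLen", "targetStart", "targetEnd",
              "nMatches", "blockLen", "mapq")

#' Read a PAF whole-genome alignment
#'
#' Parses the 12 mandatory PAF columns (optional SAM-style tags are
#' ignored) into a data frame.  On-disk coordinates are 0-based half-open;
#' they are converted here to 1-based closed \code{*Start}/\code{*End}
#' columns, the package-wide convention.
#'
#' @param path Path to a PAF file.
#' @return A data frame with columns \code{queryName}, \code{queryLen},
#'   \code{queryStart}, \code{queryEnd}, \code{strand}, \code{targetName},
#'   \code{targetLen}, \code{targetStart}, \code{targetEnd},
#'   \code{nMatches}, \code{blockLen}, \code{mapq}.
#' @export
readPaf <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
        out <- as.data.frame(setNames(rep(list(integer(0)), 12), .pafCols))
        out$queryName <- out$targetName <- character(0)
        out$strand <- character(0)
        return(out)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 12L))
        stop("PAF parse error at line ", which(nf < 12L)[1],
             ": fewer than 12 mandatory columns")
    m <- t(vapply(fields, function(f) f[1:12], character(12)))
    out <- data.frame(
        queryName = m[, 1], queryLen = as.integer(m[, 2]),
        queryStart = as.integer(m[, 3]) + 1L, queryEnd = as.integer(m[, 4]),
        strand = m[, 5],
        targetName = m[, 6], targetLen = as.integer(m[, 7]),
        targetStart = as.integer(m[, 8]) + 1L, targetEnd = as.integer(m[, 9]),
        nMatches = as.integer(m[, 10]), blockLen = as.integer(m[, 11]),
        mapq = as.integer(m[, 12]),
        stringsAsFactors = FALSE)
    bad <- which(out$queryStart > out$queryEnd | out$queryEnd > out$queryLen |
                 out$targetStart > out$targetEnd | out$targetEnd > out$targetLen |
                 out$queryStart < 1L | out$targetStart < 1L)
    if (length(bad))
        stop("PAF validation error at line ", bad[1],
             ": interval not 0 <= start < end <= length")
    if (any(out$nMatches > out$blockLen))
        stop("PAF validation error: nMatches > blockLen at line ",
             which(out$nMatches > out$blockLen)[1])
    if (!all(out$strand %in% c("+", "-")))
        stop("PAF parse error: strand must be '+' or '-'")
    out
}

#' Write a PAF alignment table
#'
#' Inverse of [readPaf()]: 1-based closed internal coordinates are
#' converted back to PAF's 0-based half-open convention on write.
#'
#' @param paf A data frame as returned by [readPaf()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePaf <- function(paf, path) {
    lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                     paf$queryName, paf$queryLen, paf$queryStart - 1L,
                     paf$queryEnd, paf$strand, paf$targetName, paf$targetLen,
                     paf$targetStart - 1L, paf$targetEnd, paf$nMatches,
                     paf$blockLen, paf$mapq)
    writeLines(lines, path)
    invisible(path)
}

#' Read interspecies SNP sites from a VCF
#'
#' Loads biallelic single-nucleotide records from a VCF (v4.2) into a
#' width-1 \code{GRanges}.  The REF allele is taken as the cattle allele
#' and ALT as the yak allele: the input contract is a VCF called against
#' the cattle-coordinate reference.  Indels and multiallelic records are
#' skipped; the counts of skipped records are kept in
#' \code{metadata(x)$skipped} so nothing is dropped silently.
#'
#' @param path Path to a VCF file.
#' @return A \code{GRanges} with metadata columns \code{cattle} and
#'   \code{yak} (single characters), and \code{metadata()} entry
#'   \code{skipped = c(indel = n1, multiallelic = n2)}.
#' @export
readVcfSnps <- function(path) {
    vcf <- tryCatch(
        VariantAnnotation::readVcf(path),
        error = function(e) stop("VCF parse error: ", conditionMessage(e)))
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- VariantAnnotation::ref(vcf)
    alt <- VariantAnnotation::alt(vcf)
    nAlt <- lengths(alt)
    multi <- nAlt != 1L
    altChar <- rep(NA_character_, length(rr))
    altChar[!multi] <- as.character(unlist(alt[!multi]))
    refChar <- as.character(ref)
    indel <- !multi & (nchar(refChar) != 1L | nchar(altChar) != 1L |
                       !altChar %in% c("A", "C", "G", "T"))
    keep <- !multi & !indel
    out <- GRanges(seqnames(rr)[keep],
                   IRanges(start(rr)[keep], width = 1L))
    mcols(out)$cattle <- refChar[keep]
    mcols(out)$yak <- altChar[keep]
    bad <- mcols(out)$cattle == mcols(out)$yak |
        !mcols(out)$cattle %in% c("A", "C", "G", "T")
    if (any(bad))
        stop("invalid SNP record: REF and ALT must be distinct single bases")
    metadata(out)$skipped <- c(indel = sum(indel), multiallelic = sum(multi))
    out
}

#' Write SNP sites as a minimal VCF v4.2
#'
#' @param snps A width-1 \code{GRanges} with \code{cattle}/\code{yak}
#'   metadata columns (cattle = REF, yak = ALT).
#' @param path Output path.
#' @param contigLengths Optional named integer vector of contig lengths
#'   for the header.
#' @return \code{path}, invisibly.
#' @export
writeVcfSnps <- function(snps, path, contigLengths = NULL) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=hybridADE-simulator")
    if (!is.null(contigLengths))
        hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                              names(contigLengths),
                              as.integer(contigLengths)))
    hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                   as.character(seqnames(snps)), start(snps),
                   mcols(snps)$cattle, mcols(snps)$yak)
    writeLines(c(hdr, rec), path)
    invisible(path)
}

#' Read long-read transcript alignments from SAM/BAM
#'
#' Loads mapped alignments as a \code{GAlignments} with metadata columns
#' \code{qname}, \code{flag}, \code{mapq}, \code{seq} and
#' \code{isPrimary}.  Secondary (0x100) and supplementary (0x800) records
#' are retained but flagged non-primary; unmapped records are excluded,
#' with their count recorded in \code{metadata(x)$skipped["unmapped"]}.
#' A CIGAR whose read-consuming length disagrees with the stored sequence
#' is a validation error naming the read.
#'
#' @param path Path to a SAM (text) or BAM file.
#' @return A \code{GAlignments}.
#' @export
readSamAlignments <- function(path) {
    isSam <- grepl("\\.sam$", path, ignore.case = TRUE)
    bam <- if (isSam) {
        dest <- tempfile(fileext = "")
        tryCatch(asBam(path, dest, overwrite = TRUE, indexDestination = FALSE),
                 error = function(e) stop("SAM parse error: ",
                                          conditionMessage(e)))
    } else path
    flags <- scanBam(bam, param = ScanBamParam(what = "flag"))[[1]]$flag
    nUnmapped <- sum(bitwAnd(flags, 4L) != 0L)
    ga <- readGAlignments(bam, param = ScanBamParam(
        what = c("qname", "flag", "mapq", "seq"),
        flag = scanBamFlag(isUnmappedQuery = FALSE)))
    bad <- qwidth(ga) != Biostrings::width(mcols(ga)$seq)
    if (any(bad))
        stop("CIGAR/sequence length mismatch for read '",
             mcols(ga)$qname[which(bad)[1]], "'")
    mcols(ga)$isPrimary <- bitwAnd(mcols(ga)$flag, 0x900L) == 0L
    metadata(ga)$skipped <- c(unmapped = nUnmapped)
    ga
}

#' Write alignments back to SAM text
#'
#' Emits the mandatory SAM fields of a \code{GAlignments} read by
#' [readSamAlignments()] (QUAL is written as \code{*}).  Together with the
#' reader this round-trips all retained mandatory fields bit-exactly on
#' simulator-produced files.
#'
#' @param ga A \code{GAlignments} with \code{qname}, \code{flag},
#'   \code{mapq} and \code{seq} metadata columns.
#' @param path Output path.
#' @param seqLengths Named integer vector for the \code{@SQ} header lines;
#'   defaults to \code{seqlengths(ga)}.
#' @return \code{path}, invisibly.
#' @export
writeSamAlignments <- function(ga, path, seqLengths = NULL) {
    if (is.null(seqLengths)) seqLengths <- GenomeInfoDb::seqlengths(ga)
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqLengths),
                     as.integer(seqLengths)))
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                   mcols(ga)$qname, mcols(ga)$flag,
                   as.character(seqnames(ga)), start(ga),
                   mcols(ga)$mapq, cigar(ga),
                   as.character(mcols(ga)$seq))
    writeLines(c(hdr, rec), path)
    invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports \code{gene} features and their exons (linked through
#' \code{mRNA}/\code{transcript} features or directly) from a GFF3 file.
#' Exons of all transcripts of a gene are unioned into a single set of
#' disjoint intervals.  Exons whose \code{Parent} cannot be resolved to a
#' gene are skipped with a warning and counted in
#' \code{metadata(x)$skipped["orphanExon"]}.
#'
#' @param path Path to a GFF3 file.
#' @return A \code{GRangesList} of exons, one element per gene, named by
#'   gene ID, with per-gene metadata columns \code{geneId} and
#'   \code{biotype} on \code{mcols()}.
#' @export
readGffGenes <- function(path) {
    feats <- import(path, format = "gff3")
    genes <- feats[feats$type == "gene"]
    if (length(genes) == 0L) {
        out <- GRangesList()
        metadata(out)$skipped <- c(orphanExon = 0L)
        return(out)
    }
    geneIds <- genes$ID
    tx <- feats[feats$type %in% c("mRNA", "transcript")]
    tx2gene <- setNames(as.character(unlist(tx$Parent)), tx$ID)
    exons <- feats[feats$type == "exon"]
    parent <- as.character(unlist(exons$Parent))
    exGene <- ifelse(parent %in% geneIds, parent, tx2gene[parent])
    orphan <- is.na(exGene)
    if (any(orphan))
        warning(sum(orphan), " exon(s) with unresolvable Parent skipped")
    exons <- exons[!orphan]
    exGene <- exGene[!orphan]
    byGene <- GenomicRanges::reduce(
        GenomicRanges::split(exons, factor(exGene, levels = geneIds)))
    mcols(byGene)$geneId <- geneIds
    mcols(byGene)$biotype <-
        if (!is.null(genes$biotype)) as.character(genes$biotype)
        else if (!is.null(genes$gene_biotype)) as.character(genes$gene_biotype)
        else rep(NA_character_, length(genes))
    mcols(byGene)$geneStrand <- as.character(strand(genes))
    metadata(byGene)$skipped <- c(orphanExon = sum(orphan))
    byGene
}

#' Read / write the sample design table
#'
#' The design TSV has columns \code{sampleId}, \code{animalId},
#' \code{tissue} and \code{sireSpecies} (which species is the paternal
#' line).  The study design is five animals by two tissues (lung, liver),
#' but any design with unique (animal, tissue) pairs is accepted.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data frame.
#' @export
readSampleMeta <- function(path) {
    meta <- read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    need <- c("sampleId", "animalId", "tissue", "sireSpecies")
    if (!all(need %in% colnames(meta)))
        stop("sample metadata must have columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(meta[, c("animalId", "tissue")]))
        stop("(animalId, tissue) pairs must be unique")
    if (!all(meta$sireSpecies %in% c("cattle", "yak")))
        stop("sireSpecies must be 'cattle' or 'yak'")
    meta
}

#' @rdname readSampleMeta
#' @param meta A sample design data frame.
#' @export
writeSampleMeta <- function(meta, path) {
    write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a homology map as BED3+3
#'
#' On-disk format is BED-style 0-based half-open with three extra columns
#' for the secondary-species mate coordinates plus the mate strand;
#' chromosome lengths travel in \code{browser}-style header comments so
#' the map round-trips.
#'
#' @param map A [HomologyMap-class].
#' @param path Output path.
#' @return \code{path} (writer) or a \code{HomologyMap} (reader).
#' @export
writeHomologyBed <- function(map, path) {
    sl <- GenomeInfoDb::seqlengths(map)
    hdr <- sprintf("#chrom_length\t%s\t%d", names(sl), as.integer(sl))
    rec <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s",
                   as.character(seqnames(map)), start(map) - 1L, end(map),
                   mcols(map)$mateChrom, mcols(map)$mateStart - 1L,
                   mcols(map)$mateEnd, mcols(map)$mateStrand)
    writeLines(c(hdr, rec), path)
    invisible(path)
}

#' @rdname writeHomologyBed
#' @export
readHomologyBed <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#chrom_length\t", lines, value = TRUE)
    hf <- strsplit(hdr, "\t", fixed = TRUE)
    sl <- setNames(vapply(hf, function(f) as.integer(f[3]), integer(1)),
                   vapply(hf, function(f) f[2], character(1)))
    body <- lines[!startsWith(lines, "#")]
    if (length(body) == 0L)
        stop("no homologous regions in ", path)
    f <- strsplit(body, "\t", fixed = TRUE)
    m <- t(vapply(f, function(x) x[1:7], character(7)))
    gr <- GRanges(m[, 1],
                  IRanges(as.integer(m[, 2]) + 1L, as.integer(m[, 3])),
                  seqlengths = sl)
    mcols(gr)$mateChrom <- m[, 4]
    mcols(gr)$mateStart <- as.integer(m[, 5]) + 1L
    mcols(gr)$mateEnd <- as.integer(m[, 6])
    mcols(gr)$mateStrand <- m[, 7]
    HomologyMap(gr)
}

# internal TSV helpers with a fixed, deterministic column order
writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
readTsv <- function(path) {
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
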