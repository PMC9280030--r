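#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom GenomeInfoDb seqlengths seqlevels
NULL

#' HomologyMap: merged interspecies homologous blocks
#'
#' A \code{GRanges} subclass holding the homologous blocks between the
#' primary (cattle-coordinate) reference and the secondary species, after
#' filtering and merging.  Ranges live on primary-reference coordinates;
#' metadata columns \code{mateChrom}, \code{mateStart}, \code{mateEnd} and
#' \code{mateStrand} record the secondary-species coordinates of the
#' dominant (longest) alignment record contributing to each merged block.
#' Sequence lengths of the primary chromosomes are stored as
#' \code{seqlengths}, which is what makes genome-fraction statistics
#' well-defined.
#'
#' Validity: blocks are sorted and disjoint within each chromosome, lie
#' within \code{[1, seqlength]}, and every chromosome has a known length.
#'
#' @seealso [extractHomologyBlocks()], [homologousFraction()]
#' @export
setClass("HomologyMap", contains = "GRanges")

setValidity("HomologyMap", function(object) {
    msg <- character(0)
    sl <- GenomeInfoDb::seqlengths(object)
    if (any(is.na(sl)))
        msg <- c(msg, "all chromosomes must have a known seqlength")
    req <- c("mateChrom", "mateStart", "mateEnd", "mateStrand")
    if (!all(req %in% colnames(mcols(object))))
        msg <- c(msg, paste("missing metadata columns:",
                            paste(setdiff(req, colnames(mcols(object))),
                                  collapse = ", ")))
    if (length(object)) {
        if (S4Vectors::isSorted(object) == FALSE)
            msg <- c(msg, "blocks must be sorted")
        if (!GenomicRanges::isDisjoint(object))
            msg <- c(msg, "blocks must be disjoint after merging")
        if (!all(is.na(sl)) &&
            any(end(object) > sl[as.character(seqnames(object))],
                na.rm = TRUE))
            msg <- c(msg, "block beyond chromosome end")
        if (any(start(object) < 1L))
            msg <- c(msg, "block start before position 1")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn HomologyMap-class Construct a HomologyMap from a GRanges of
#'   merged blocks (must carry mate metadata columns and seqlengths).
#' @param blocks A \code{GRanges} of merged homologous blocks.
#' @return A \code{HomologyMap}.
#' @export
HomologyMap <- function(blocks) {
    new("HomologyMap", sort(blocks))
}

setMethod("show", "HomologyMap", function(object) {
    cat("HomologyMap with", length(object), "blocks on",
        length(GenomeInfoDb::seqlevels(object)), "chromosomes\n")
    cat(sprintf("  homologous fraction of genome: %.4f\n",
                homologousFraction(object)))
    callNextMethod()
})

#' AlleleExpressionSet: per-gene, per-sample parental allele counts
#'
#' A \code{SummarizedExperiment} subclass with one row per gene and one
#' column per sequenced sample, carrying the allelic read tallies of the
#' hybrid transcriptome as assays:
#' \describe{
#'   \item{informativeCattle, informativeYak}{integer counts of reads
#'     assigned to each parental haplotype by the SNP majority vote.}
#'   \item{uninformative}{reads overlapping the gene but covering no
#'     interspecies SNP.}
#'   \item{ambiguous}{reads with tied votes; excluded from all downstream
#'     counts.}
#'   \item{finalCattle, finalYak}{fractional counts after per-gene
#'     proportional redistribution of uninformative reads.}
#'   \item{unassigned}{uninformative reads of genes with zero informative
#'     reads, which cannot be redistributed.}
#' }
#' \code{colData} holds the sample design (\code{animalId}, \code{tissue},
#' \code{sireSpecies}) and \code{totalMapped}, the CPM denominator
#' (primary mapped reads in the sample, gene-assigned or not).
#'
#' @seealso [AlleleExpressionSet()], [redistributeUninformative()],
#'   [alleleCpm()], [runAdeTests()]
#' @export
setClass("AlleleExpressionSet",
         contains = "SummarizedExperiment")

setValidity("AlleleExpressionSet", function(object) {
    msg <- character(0)
    need <- c("informativeCattle", "informativeYak", "uninformative",
              "ambiguous")
    an <- SummarizedExperiment::assayNames(object)
    if (!all(need %in% an))
        msg <- c(msg, paste("missing assays:",
                            paste(setdiff(need, an), collapse = ", ")))
    for (a in intersect(c(need, "finalCattle", "finalYak", "unassigned"), an))
        if (any(SummarizedExperiment::assay(object, a) < 0, na.rm = TRUE))
            msg <- c(msg, paste("negative values in assay", a))
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("animalId", "tissue", "totalMapped") %in% colnames(cd)))
        msg <- c(msg, "colData must contain animalId, tissue, totalMapped")
    if ("finalCattle" %in% an) {
        tot1 <- SummarizedExperiment::assay(object, "finalCattle") +
            SummarizedExperiment::assay(object, "finalYak") +
            SummarizedExperiment::assay(object, "unassigned")
        tot2 <- SummarizedExperiment::assay(object, "informativeCattle") +
            SummarizedExperiment::assay(object, "informativeYak") +
            SummarizedExperiment::assay(object, "uninformative")
        if (max(abs(tot1 - tot2)) > 1e-9)
            msg <- c(msg, "final counts + unassigned must equal non-ambiguous reads")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "AlleleExpressionSet", function(object) {
    cat("AlleleExpressionSet:", nrow(object), "genes x", ncol(object),
        "samples\n")
    if ("finalCattle" %in% SummarizedExperiment::assayNames(object)) {
        fc <- sum(SummarizedExperiment::assay(object, "finalCattle"))
        fy <- sum(SummarizedExperiment::assay(object, "finalYak"))
        cat(sprintf("  redistributed counts: cattle %.0f, yak %.0f (cattle fraction %.3f)\n",
                    fc, fy, fc / (fc + fy)))
    }
    callNextMethod()
})

#' Accessors for AlleleExpressionSet assays
#'
#' Convenience accessors for the allelic count assays; prefer these over
#' direct \code{assay()} calls.
#'
#' @param x An \code{AlleleExpressionSet}.
#' @return A numeric matrix (genes x samples).
#' @name allele-accessors
NULL

#' @rdname allele-accessors
#' @export
informativeCattle <- function(x) SummarizedExperiment::assay(x, "informativeCattle")
#' @rdname allele-accessors
#' @export
informativeYak <- function(x) SummarizedExperiment::assay(x, "informativeYak")
#' @rdname allele-accessors
#' @export
finalCattle <- function(x) SummarizedExperiment::assay(x, "finalCattle")
#' @rdname allele-accessors
#' @export
finalYak <- function(x) SummarizedExperiment::assay(x, "finalYak")
#' @rdname allele-accessors
#' @export
uninformativeCounts <- function(x) SummarizedExperiment::assay(x, "uninformative")
#' @rdname allele-accessors
#' @export
ambiguousCounts <- function(x) SummarizedExperiment::assay(x, "ambiguous")
#' @rdname allele-accessors
#' @export
totalMapped <- function(x) SummarizedExperiment::colData(x)$totalMapped
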