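#' Tally per-gene allelic read counts for one sample
#'
#' Aggregates per-read origin calls into per-gene tallies of informative
#' cattle/yak reads, uninformative (SNP-free) reads and ambiguous
#' (tied-vote) reads.  Calls with no gene are dropped and counted in
#' \code{metadata(x)$skipped["noGene"]}.
#'
#' @param calls A \code{DataFrame} from [assignAlleles()] for one sample.
#' @param sampleId Sample identifier attached to every row.
#' @return A \code{DataFrame} with columns \code{geneId}, \code{sampleId},
#'   \code{informativeCattle}, \code{informativeYak}, \code{uninformative},
#'   \code{ambiguous}.
#' @export
tallyGeneCounts <- function(calls, sampleId) {
    noGene <- is.na(calls$geneId)
    calls <- calls[!noGene, , drop = FALSE]
    genes <- sort(unique(calls$geneId))
    f <- factor(calls$geneId, levels = genes)
    tab <- table(f, calls$call)
    out <- DataFrame(geneId = genes,
                     sampleId = rep(sampleId, length(genes)),
                     informativeCattle = as.integer(tab[, "CATTLE"]),
                     informativeYak = as.integer(tab[, "YAK"]),
                     uninformative = as.integer(tab[, "UNINFORMATIVE"]),
                     ambiguous = as.integer(tab[, "AMBIGUOUS"]))
    metadata(out)$skipped <- c(noGene = sum(noGene))
    out
}

#' Proportionally redistribute SNP-free reads
#'
#' Reads without any interspecies SNP cannot be assigned directly; they
#' are split between the two alleles in the ratio of the gene's
#' informative reads.  With informative counts \eqn{c} and \eqn{y}
#' (\eqn{i = c + y > 0}) and \eqn{u} uninformative reads, the final
#' counts are \eqn{c(1 + u/i)} and \eqn{y(1 + u/i)} — the informative
#' ratio is preserved exactly and \code{finalCattle + finalYak} equals
#' the gene's non-ambiguous read total.  Genes with \eqn{i = 0} get zero
#' final counts and keep their uninformative reads as \code{unassigned};
#' no library-wide fallback ratio is used, and such genes are excluded
#' from ADE testing.
#'
#' @param counts A \code{DataFrame} from [tallyGeneCounts()] (or any
#'   table with the informative/uninformative columns).
#' @return The input with added numeric columns \code{finalCattle},
#'   \code{finalYak}, \code{unassigned}.
#' @export
redistributeUninformative <- function(counts) {
    i <- counts$informativeCattle + counts$informativeYak
    scale <- ifelse(i > 0, 1 + counts$uninformative / i, 0)
    counts$finalCattle <- counts$informativeCattle * scale
    counts$finalYak <- counts$informativeYak * scale
    counts$unassigned <- ifelse(i > 0, 0, as.numeric(counts$uninformative))
    counts
}

#' Assemble an AlleleExpressionSet from per-sample tallies
#'
#' Binds per-sample tally tables into the package's central genes x
#' samples container, applying [redistributeUninformative()] on the way
#' in.
#'
#' @param countsList Named list (by sample ID) of \code{DataFrame}s from
#'   [tallyGeneCounts()].
#' @param meta Sample design data frame ([readSampleMeta()]); rows
#'   matched to \code{names(countsList)} by \code{sampleId}.
#' @param totalMapped Named integer vector: primary mapped reads per
#'   sample (the CPM denominator).
#' @return An [AlleleExpressionSet-class].
#' @export
AlleleExpressionSet <- function(countsList, meta, totalMapped) {
    sampleIds <- names(countsList)
    stopifnot(all(sampleIds %in% meta$sampleId),
              all(sampleIds %in% names(totalMapped)))
    countsList <- lapply(countsList, redistributeUninformative)
    genes <- sort(unique(unlist(lapply(countsList, function(x) x$geneId))))
    mk <- function(col) {
        m <- matrix(0, nrow = length(genes), ncol = length(sampleIds),
                    dimnames = list(genes, sampleIds))
        for (s in sampleIds) {
            x <- countsList[[s]]
            m[x$geneId, s] <- x[[col]]
        }
        m
    }
    assays <- list(informativeCattle = mk("informativeCattle"),
                   informativeYak = mk("informativeYak"),
                   uninformative = mk("uninformative"),
                   ambiguous = mk("ambiguous"),
                   finalCattle = mk("finalCattle"),
                   finalYak = mk("finalYak"),
                   unassigned = mk("unassigned"))
    cd <- meta[match(sampleIds, meta$sampleId), , drop = FALSE]
    cd$totalMapped <- as.numeric(totalMapped[sampleIds])
    rownames(cd) <- sampleIds
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = S4Vectors::DataFrame(cd))
    new("AlleleExpressionSet", se)
}

#' Counts per million mapped reads
#'
#' CPM for each allele and for the gene total, using each sample's total
#' primary mapped reads (gene-assigned or not) as denominator, so that
#' per-sample gene CPMs sum to at most one million (with equality when
#' every mapped read is gene-assigned).
#'
#' @param x An [AlleleExpressionSet-class].
#' @return A list of matrices \code{cattle}, \code{yak}, \code{total}.
#' @export
alleleCpm <- function(x) {
    tm <- totalMapped(x)
    if (any(tm <= 0)) stop("totalMapped must be positive")
    sc <- 1e6 / tm
    cattle <- sweep(finalCattle(x), 2, sc, `*`)
    yak <- sweep(finalYak(x), 2, sc, `*`)
    list(cattle = cattle, yak = yak, total = cattle + yak)
}

#' Low-expression filter
#'
#' A gene is testable in a sample when it has at least \code{minReads}
#' non-ambiguous reads there (informative + uninformative); the default
#' of 3 implements "more than 2 mapped transcript sequences".
#'
#' @param x An [AlleleExpressionSet-class] or a tally \code{DataFrame}.
#' @param minReads Minimum non-ambiguous read count (default 3).
#' @return For a set: a logical genes x samples matrix. For a tally
#'   table: a list with elements \code{kept} and \code{dropped}.
#' @export
filterLowExpression <- function(x, minReads = 3L) {
    if (minReads < 1L) stop("minReads must be >= 1")
    if (is(x, "AlleleExpressionSet")) {
        informativeCattle(x) + informativeYak(x) +
            uninformativeCounts(x) >= minReads
    } else {
        tot <- x$informativeCattle + x$informativeYak + x$uninformative
        list(kept = x[tot >= minReads, , drop = FALSE],
             dropped = x[tot < minReads, , drop = FALSE])
    }
}

#' Rarefaction of gene discovery
#'
#' Subsamples the gene-assigned reads of a sample without replacement at
#' each requested depth and reports the mean number of distinct genes
#' detected (>= 1 read) over \code{nReps} replicates.  Deterministic
#' given \code{seed}; the caller's RNG state is untouched.
#'
#' @param calls A \code{DataFrame} from [assignAlleles()] (rows with
#'   \code{NA} gene are ignored).
#' @param depths Integer vector of subsampling depths; each must not
#'   exceed the number of gene-assigned reads.
#' @param nReps Subsampling replicates per depth (default 10).
#' @param seed RNG seed.
#' @return A data frame with columns \code{depth}, \code{meanGenes}.
#' @export
rarefactionCurve <- function(calls, depths, nReps = 10L, seed = 1L) {
    geneOfRead <- calls$geneId[!is.na(calls$geneId)]
    total <- length(geneOfRead)
    if (any(depths > total))
        stop("depth exceeds number of gene-assigned reads (", total, ")")
    withSeed(seed, {
        meanGenes <- vapply(depths, function(d) {
            if (d == 0L) return(0)
            mean(vapply(seq_len(nReps), function(r)
                length(unique(sample(geneOfRead, d))), numeric(1)))
        }, numeric(1))
        data.frame(depth = as.integer(depths), meanGenes = meanGenes)
    })
}

#' Pairwise Pearson correlation of samples
#'
#' Correlation between sample expression profiles, computed for each pair
#' on the genes kept (testable) in both samples, on \code{log2(CPM + 1)}
#' by default or raw CPM with \code{log2 = FALSE}.  A pair with a
#' zero-variance profile gets \code{NA}.
#'
#' @param x An [AlleleExpressionSet-class].
#' @param keep Optional logical genes x samples matrix (defaults to
#'   [filterLowExpression()] at its default threshold).
#' @param log2 Transform CPM to \code{log2(CPM + 1)} first (default TRUE).
#' @return A symmetric samples x samples matrix with unit diagonal.
#' @export
correlationMatrix <- function(x, keep = NULL, log2 = TRUE) {
    if (ncol(x) < 2L) stop("need at least two samples")
    if (is.null(keep)) keep <- filterLowExpression(x)
    cpm <- alleleCpm(x)$total
    if (log2) cpm <- log2(cpm + 1)
    n <- ncol(cpm)
    out <- matrix(NA_real_, n, n, dimnames = list(colnames(cpm),
                                                  colnames(cpm)))
    diag(out) <- 1
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        g <- keep[, i] & keep[, j]
        if (sum(g) >= 2L &&
            stats::sd(cpm[g, i]) > 0 && stats::sd(cpm[g, j]) > 0)
            out[i, j] <- out[j, i] <- stats::cor(cpm[g, i], cpm[g, j])
    }
    out
}
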