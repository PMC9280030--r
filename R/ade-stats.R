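#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-method two-sided p-value for the table
#' \code{[[a, b], [c, d]]} with fixed margins: the sum of hypergeometric
#' probabilities of all tables with the same margins whose probability
#' does not exceed that of the observed table, using a relative
#' tolerance of 1e-7 on the comparison (the convention of standard
#' implementations, which guards against ties lost to floating-point
#' rounding).
#'
#' @param a,b,c,d Non-negative integer cell counts (row-wise).
#' @return The two-sided p-value in \code{(0, 1]}.
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
    cells <- c(a, b, c, d)
    if (any(cells < 0)) stop("cell counts must be non-negative")
    if (all(cells == 0)) stop("at least one cell must be positive")
    m <- a + c            # column-1 total
    n <- b + d            # column-2 total
    k <- a + b            # row-1 total
    lo <- max(0L, k - n)
    hi <- min(k, m)
    support <- lo:hi
    dens <- stats::dhyper(support, m, n, k)
    dObs <- dens[support == a]
    relErr <- 1 + 1e-7
    p <- sum(dens[dens <= dObs * relErr])
    min(p, 1)
}

#' Allelic fold change
#'
#' Ratio of the larger to the smaller allele count; \code{Inf} when one
#' allele is unobserved (monoallelic expression passes any finite
#' threshold).
#'
#' @param cattleCount,yakCount Non-negative counts (not both zero).
#' @return A value \code{>= 1}, possibly \code{Inf}.
#' @export
foldChange <- function(cattleCount, yakCount) {
    if (cattleCount < 0 || yakCount < 0) stop("counts must be non-negative")
    if (cattleCount + yakCount == 0) stop("both counts are zero")
    hi <- pmax(cattleCount, yakCount)
    lo <- pmin(cattleCount, yakCount)
    if (lo == 0) Inf else hi / lo
}

#' Test one gene for allelic differential expression
#'
#' Builds the 2x2 table of the gene's allelic counts against the rest of
#' the library's allelic counts —
#' \code{[[geneCattle, geneYak], [libCattle - geneCattle, libYak - geneYak]]}
#' — which controls for genome-wide assignment imbalance, and combines
#' the two-sided Fisher exact p with a fold-change gate: the gene is
#' significant when \code{foldChange > fcThreshold} and
#' \code{p < alpha}.  Counts are integerized (half away from zero) at
#' this boundary, since the exact test requires integers.  With
#' \code{method = "binomial"} a two-sided binomial test against a
#' balanced (0.5) null replaces the library-background Fisher test, as a
#' sensitivity analysis.
#'
#' @param geneCattle,geneYak The gene's (redistributed) allele counts.
#' @param libCattle,libYak Library totals of assigned allele counts in
#'   the sample; must be at least the gene's counts.
#' @param alpha Significance level (default 0.05).
#' @param fcThreshold Fold-change gate (default 2).
#' @param method \code{"library"} (default) or \code{"binomial"}.
#' @return A one-row data frame: \code{cattleCount}, \code{yakCount},
#'   \code{foldChange}, \code{pValue}, \code{significant},
#'   \code{direction} (\code{CATTLE}/\code{YAK}/\code{NONE}).
#' @export
testGeneAde <- function(geneCattle, geneYak, libCattle, libYak,
                        alpha = 0.05, fcThreshold = 2,
                        method = c("library", "binomial")) {
    method <- match.arg(method)
    gc <- roundHalfAway(geneCattle)
    gy <- roundHalfAway(geneYak)
    if (gc + gy == 0) stop("gene has no assigned reads after rounding")
    if (method == "library") {
        lc <- roundHalfAway(libCattle)
        ly <- roundHalfAway(libYak)
        if (lc < gc || ly < gy)
            stop("library totals must be >= gene counts")
        p <- fisherExactTwoSided(gc, gy, lc - gc, ly - gy)
    } else {
        p <- stats::binom.test(gc, gc + gy, 0.5)$p.value
    }
    fc <- foldChange(gc, gy)
    sig <- fc > fcThreshold && p < alpha
    dir <- if (!sig) "NONE" else if (gy > gc) "YAK" else "CATTLE"
    data.frame(cattleCount = gc, yakCount = gy, foldChange = fc,
               pValue = p, significant = sig, direction = dir,
               stringsAsFactors = FALSE)
}

#' Run per-sample ADE tests across an AlleleExpressionSet
#'
#' For each sample, tests every gene passing the low-expression filter
#' whose informative reads allow redistribution (genes with zero
#' informative reads are untestable).  Library totals are the sample's
#' summed rounded final counts over all genes.  A Benjamini-Hochberg
#' column \code{bhQ} is reported per sample for reference but does not
#' drive \code{significant}, which implements the per-gene
#' \code{FC > fcThreshold & p < alpha} rule.
#'
#' @param x An [AlleleExpressionSet-class].
#' @param alpha,fcThreshold Significance rule (defaults 0.05 and 2).
#' @param minReads Low-expression filter threshold (default 3).
#' @param method Passed to [testGeneAde()].
#' @return A \code{DataFrame} with one row per tested (gene, sample):
#'   \code{geneId}, \code{sampleId}, \code{cattleCount}, \code{yakCount},
#'   \code{foldChange}, \code{pValue}, \code{bhQ}, \code{significant},
#'   \code{direction}.
#' @export
runAdeTests <- function(x, alpha = 0.05, fcThreshold = 2, minReads = 3L,
                        method = c("library", "binomial")) {
    method <- match.arg(method)
    keep <- filterLowExpression(x, minReads)
    fcMat <- roundHalfAway(finalCattle(x))
    fyMat <- roundHalfAway(finalYak(x))
    res <- list()
    for (s in colnames(x)) {
        libC <- sum(fcMat[, s])
        libY <- sum(fyMat[, s])
        testable <- which(keep[, s] & (fcMat[, s] + fyMat[, s]) > 0)
        if (length(testable) == 0L) next
        rows <- lapply(testable, function(g)
            testGeneAde(fcMat[g, s], fyMat[g, s], libC, libY,
                        alpha = alpha, fcThreshold = fcThreshold,
                        method = method))
        df <- do.call(rbind, rows)
        df <- cbind(geneId = rownames(x)[testable], sampleId = s, df)
        df$bhQ <- stats::p.adjust(df$pValue, method = "BH")
        res[[s]] <- df
    }
    if (length(res) == 0L)
        return(DataFrame(geneId = character(0), sampleId = character(0)))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    DataFrame(out[, c("geneId", "sampleId", "cattleCount", "yakCount",
                      "foldChange", "pValue", "bhQ", "significant",
                      "direction")])
}

#' Classify genes by cross-replicate ADE ubiquity and direction
#'
#' A gene shows ubiquitous ADE in a tissue when it was tested
#' (post-filter) in all animals of that tissue and significant in every
#' one.  Tissue pattern is \code{LUNG_ONLY} / \code{LIVER_ONLY} /
#' \code{BOTH} / \code{NONE} from the two ubiquity flags.  Among
#' ubiquitous genes, the direction class is \code{YAK} or \code{CATTLE}
#' when every significant per-sample result agrees, otherwise
#' \code{VARIABLE}; non-ubiquitous genes get \code{NONE}.
#'
#' @param results \code{DataFrame} from [runAdeTests()].
#' @param meta Sample design data frame.
#' @return A \code{DataFrame} with one row per tested gene:
#'   \code{geneId}, \code{ubiquitousLung}, \code{ubiquitousLiver},
#'   \code{tissuePattern}, \code{directionClass}.
#' @export
classifyAde <- function(results, meta) {
    tissues <- c("lung", "liver")
    nAnimals <- vapply(tissues, function(t)
        length(unique(meta$animalId[meta$tissue == t])), integer(1))
    resTissue <- meta$tissue[match(results$sampleId, meta$sampleId)]
    genes <- sort(unique(results$geneId))
    ubiq <- sapply(tissues, function(t) {
        inT <- resTissue == t
        nTested <- table(factor(results$geneId[inT], levels = genes))
        nSig <- table(factor(results$geneId[inT & results$significant],
                             levels = genes))
        as.integer(nTested) == nAnimals[t] & nTested == nSig &
            nAnimals[t] > 0L
    })
    if (length(genes) == 1L) ubiq <- matrix(ubiq, nrow = 1)
    pattern <- ifelse(ubiq[, 1] & ubiq[, 2], "BOTH",
               ifelse(ubiq[, 1], "LUNG_ONLY",
               ifelse(ubiq[, 2], "LIVER_ONLY", "NONE")))
    dirClass <- vapply(seq_along(genes), function(i) {
        if (!any(ubiq[i, ])) return("NONE")
        dirs <- unique(results$direction[results$geneId == genes[i] &
                                         results$significant])
        if (identical(dirs, "YAK")) "YAK"
        else if (identical(dirs, "CATTLE")) "CATTLE"
        else "VARIABLE"
    }, character(1))
    DataFrame(geneId = genes,
              ubiquitousLung = ubiq[, 1],
              ubiquitousLiver = ubiq[, 2],
              tissuePattern = factor(pattern, levels = c("LUNG_ONLY",
                  "LIVER_ONLY", "BOTH", "NONE")),
              directionClass = factor(dirClass, levels = c("YAK", "CATTLE",
                  "VARIABLE", "NONE")))
}

#' Summary table of the ADE analysis
#'
#' Tabulates the analysis headline numbers: genes significant in at
#' least one sample, ubiquitous genes per tissue, direction classes
#' (which partition the ubiquitous set: yak + cattle + variable = total
#' ubiquitous), and tissue patterns.
#'
#' @param results \code{DataFrame} from [runAdeTests()].
#' @param classifications \code{DataFrame} from [classifyAde()].
#' @return A data frame with columns \code{metric}, \code{count}.
#' @export
summarizeAde <- function(results, classifications) {
    cl <- classifications
    ubiq <- cl$ubiquitousLung | cl$ubiquitousLiver
    data.frame(
        metric = c("ade_any_sample", "ubiquitous_total", "ubiquitous_lung",
                   "ubiquitous_liver", "direction_yak", "direction_cattle",
                   "direction_variable", "pattern_lung_only",
                   "pattern_liver_only", "pattern_both"),
        count = c(length(unique(results$geneId[results$significant])),
                  sum(ubiq),
                  sum(cl$ubiquitousLung),
                  sum(cl$ubiquitousLiver),
                  sum(cl$directionClass == "YAK"),
                  sum(cl$directionClass == "CATTLE"),
                  sum(cl$directionClass == "VARIABLE"),
                  sum(cl$tissuePattern == "LUNG_ONLY"),
                  sum(cl$tissuePattern == "LIVER_ONLY"),
                  sum(cl$tissuePattern == "BOTH")))
}
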