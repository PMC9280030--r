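#' Run the full allelic-expression analysis over a dataset directory
#'
#' Orchestrates the stages build-ref, assign, quantify, test and
#' classify over a directory laid out like the simulator's output
#' ([simulateDataset()]): \code{cattle.fa}, \code{homology.paf},
#' \code{snps.vcf}, \code{genes.gff3}, \code{samples.tsv} and one
#' \code{<sampleId>.sam} per sample.  Each stage reads only the previous
#' stage's declared outputs; per-stage record counts are logged as
#' structured \code{key=value} lines so callers can assert conservation
#' (reads parsed = assigned + no-gene + non-primary).  Output tables are
#' written with a deterministic column order, so a rerun with the same
#' inputs and seed is byte-identical.
#'
#' @param dataDir Input directory.
#' @param outDir Output directory (created if needed).
#' @param minBlockLen,minMapq,allowedChroms,minOverlapFraction Reference
#'   construction thresholds ([extractHomologyBlocks()],
#'   [classifyGenes()]).
#' @param minReads Low-expression filter (default 3).
#' @param alpha,fcThreshold ADE significance rule (defaults 0.05, 2).
#' @param method ADE test variant ([testGeneAde()]).
#' @param rarefactionDepths Optional depths for a rarefaction table of
#'   the first sample (NULL to skip).
#' @param seed Seed for the rarefaction subsampling.
#' @return Invisibly, a list with the main in-memory results
#'   (\code{map}, \code{aset}, \code{results}, \code{classifications},
#'   \code{summary}, \code{log}, \code{manifest}).
#' @export
runPipeline <- function(dataDir, outDir,
                        minBlockLen = 1000L, minMapq = 0L,
                        allowedChroms = NULL, minOverlapFraction = 1.0,
                        minReads = 3L, alpha = 0.05, fcThreshold = 2,
                        method = c("library", "binomial"),
                        rarefactionDepths = NULL, seed = 1L) {
    method <- match.arg(method)
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    log <- character(0)

    ## stage: build-ref
    paf <- readPaf(file.path(dataDir, "homology.paf"))
    snps <- readVcfSnps(file.path(dataDir, "snps.vcf"))
    genome <- readGenome(file.path(dataDir, "cattle.fa"))
    genes <- readGffGenes(file.path(dataDir, "genes.gff3"))
    ref <- buildReference(paf, snps, genome, genes,
                          minBlockLen = minBlockLen, minMapq = minMapq,
                          allowedChroms = allowedChroms,
                          minOverlapFraction = minOverlapFraction)
    writeHomologyBed(ref$map, file.path(outDir, "homology.bed"))
    writeGenome(ref$maskedGenome, file.path(outDir, "masked.fa"))
    writeTsv(data.frame(geneId = names(ref$genes)),
             file.path(outDir, "genes_retained.tsv"))
    log <- c(log, logLine("build-ref",
                          blocks = length(ref$map),
                          homologousFraction =
                              round(homologousFraction(ref$map), 6),
                          snpsRetained = length(ref$snps),
                          genesRetained = length(ref$genes),
                          genesExcluded = length(ref$excludedGenes)))

    ## stage: assign (per sample)
    meta <- readSampleMeta(file.path(dataDir, "samples.tsv"))
    countsList <- list(); totalMapped <- integer(0)
    allCallsFirst <- NULL
    for (s in meta$sampleId) {
        al <- readSamAlignments(file.path(dataDir, paste0(s, ".sam")))
        calls <- assignAlleles(al, ref$snps, ref$genes)
        callDf <- as.data.frame(calls)
        writeTsv(callDf, file.path(outDir, paste0("calls_", s, ".tsv")))
        nPrimary <- nrow(callDf)
        totalMapped[s] <- nPrimary
        tl <- tallyGeneCounts(calls, s)
        countsList[[s]] <- tl
        if (is.null(allCallsFirst)) allCallsFirst <- calls
        log <- c(log, logLine("assign", sample = s,
                              parsed = nPrimary +
                                  metadata(calls)$skipped[["nonPrimary"]],
                              nonPrimary =
                                  metadata(calls)$skipped[["nonPrimary"]],
                              assigned = nPrimary -
                                  metadata(tl)$skipped[["noGene"]],
                              noGene = metadata(tl)$skipped[["noGene"]]))
    }

    ## stage: quantify
    aset <- AlleleExpressionSet(countsList, meta, totalMapped)
    cpm <- alleleCpm(aset)
    countsDf <- do.call(rbind, lapply(names(countsList), function(s) {
        x <- as.data.frame(redistributeUninformative(countsList[[s]]))
        x$cpmCattle <- x$finalCattle / totalMapped[s] * 1e6
        x$cpmYak <- x$finalYak / totalMapped[s] * 1e6
        x
    }))
    writeTsv(countsDf, file.path(outDir, "counts.tsv"))
    corr <- correlationMatrix(aset,
                              keep = filterLowExpression(aset, minReads))
    writeTsv(cbind(sampleId = rownames(corr), as.data.frame(corr)),
             file.path(outDir, "correlation.tsv"))
    if (!is.null(rarefactionDepths)) {
        rar <- rarefactionCurve(allCallsFirst, rarefactionDepths,
                                seed = seed)
        writeTsv(rar, file.path(outDir, "rarefaction.tsv"))
    }
    keptPerSample <- colSums(filterLowExpression(aset, minReads))
    log <- c(log, logLine("quantify", genes = nrow(aset),
                          samples = ncol(aset),
                          meanKept = round(mean(keptPerSample), 2)))

    ## stage: test
    results <- runAdeTests(aset, alpha = alpha, fcThreshold = fcThreshold,
                           minReads = minReads, method = method)
    writeTsv(as.data.frame(results), file.path(outDir, "ade_results.tsv"))
    log <- c(log, logLine("test", tested = nrow(results),
                          significant = sum(results$significant)))

    ## stage: classify
    classifications <- classifyAde(results, meta)
    writeTsv(as.data.frame(classifications),
             file.path(outDir, "ade_classification.tsv"))
    summaryTab <- summarizeAde(results, classifications)
    writeTsv(summaryTab, file.path(outDir, "ade_summary.tsv"))
    log <- c(log, logLine("classify",
                          ubiquitous = sum(classifications$ubiquitousLung |
                                           classifications$ubiquitousLiver)))

    writeLines(log, file.path(outDir, "run_log.txt"))
    files <- sort(setdiff(list.files(outDir), "manifest.tsv"))
    manifest <- data.frame(file = files,
                           md5 = unname(tools::md5sum(
                               file.path(outDir, files))),
                           stringsAsFactors = FALSE)
    writeTsv(manifest, file.path(outDir, "manifest.tsv"))
    invisible(list(map = ref$map, aset = aset, results = results,
                   classifications = classifications,
                   summary = summaryTab, log = log, manifest = manifest))
}

#' @rdname runPipeline
#' @param ... Passed to [runPipeline()].
#' @export
runAll <- function(dataDir, outDir, ...) runPipeline(dataDir, outDir, ...)
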