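#' Simulation configuration for the synthetic hybrid transcriptome
#'
#' Bundles and validates the parameters of the built-in simulator, whose
#' defaults emulate the study design: two parental haplotypes diverged at
#' a ~1.2 percent SNP rate, a small non-homologous (species-specific)
#' share of the genome, spliced gene models, error-bearing full-length
#' reads at a 5 percent total per-base error rate, and five animals by
#' two tissues (lung, liver).
#'
#' @param nChroms Number of chromosomes (default 2).
#' @param chromLength Chromosome length in bp (default 3e5).
#' @param nGenes Number of genes (default 100).
#' @param exonsPerGene Integer range of exon counts (default 1..5).
#' @param geneLengthMeanlog,geneLengthSdlog Log-normal parameters of
#'   transcript length in bp (defaults log(1500), 0.35).
#' @param intronLengthRange Intron length range in bp (default 80..400).
#' @param snpRate Per-bp interspecies SNP rate inside homologous tracts
#'   (default 0.012).
#' @param subRate,insRate,delRate Per-base substitution / insertion /
#'   deletion error rates of the reads (defaults 0.035, 0.0075, 0.0075 —
#'   5 percent total).
#' @param indelGeomProb Geometric parameter of indel lengths
#'   (default 0.7; lengths are 1 + Geom(p)).
#' @param truncationRate Probability that a read is 5'-truncated
#'   (default 0: full-length non-chimeric reads are retained full
#'   length).
#' @param readsPerGeneMeanlog,readsPerGeneSdlog Log-normal parameters of
#'   per-gene expected read count per sample (defaults log(30), 0.8).
#' @param adeFraction Fraction of genes with true allelic differential
#'   expression (default 0.1).
#' @param fcLevels True fold-change levels for ADE genes
#'   (default c(2, 4, 8)); a gene's true cattle fraction is
#'   \code{fc/(1+fc)} or \code{1/(1+fc)}.
#' @param tissueSpecificFraction Fraction of ADE genes whose imbalance is
#'   restricted to one tissue (default 0.25).
#' @param nAnimals Number of animals (default 5).
#' @param tissues Tissues sampled per animal (default lung, liver).
#' @param nonHomologousFraction Fraction of each chromosome occupied by a
#'   species-specific tract (default 0.06).
#' @param nNonHomologousGenes Genes placed inside the species-specific
#'   tract, to be excluded downstream (default 2).
#' @param uninformativeRate Fraction of reads carrying no SNP in the
#'   counts-level sampling layer ([simulateAlleleCounts()]; default 0.2).
#' @param seed Default RNG seed for the simulation functions.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nChroms = 2L, chromLength = 3e5L,
                             nGenes = 100L, exonsPerGene = c(1L, 5L),
                             geneLengthMeanlog = log(1500),
                             geneLengthSdlog = 0.35,
                             intronLengthRange = c(80L, 400L),
                             snpRate = 0.012, subRate = 0.035,
                             insRate = 0.0075, delRate = 0.0075,
                             indelGeomProb = 0.7, truncationRate = 0,
                             readsPerGeneMeanlog = log(30),
                             readsPerGeneSdlog = 0.8,
                             adeFraction = 0.1, fcLevels = c(2, 4, 8),
                             tissueSpecificFraction = 0.25,
                             nAnimals = 5L,
                             tissues = c("lung", "liver"),
                             nonHomologousFraction = 0.06,
                             nNonHomologousGenes = 2L,
                             uninformativeRate = 0.2,
                             seed = 1L) {
    cfg <- as.list(environment())
    rates <- c(snpRate, subRate, insRate, delRate, truncationRate,
               adeFraction, tissueSpecificFraction, nonHomologousFraction,
               uninformativeRate)
    if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
    if (nGenes < 1L) stop("nGenes must be >= 1")
    if (any(fcLevels <= 1)) stop("fcLevels must exceed 1")
    if (nNonHomologousGenes > nGenes)
        stop("nNonHomologousGenes cannot exceed nGenes")
    class(cfg) <- "SimulationConfig"
    cfg
}

.randomBases <- function(n) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# a base different from each element of `base`, uniform over the 3 others
.otherBase <- function(base) {
    alts <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                   nrow = 3,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
    pick <- sample.int(3L, length(base), replace = TRUE)
    alts[cbind(pick, match(base, colnames(alts)))]
}

#' Simulate the parental reference scaffold
#'
#' Generates a random cattle genome; the yak genome is a copy carrying
#' Bernoulli(\code{snpRate}) substitutions inside homologous tracts and
#' fully divergent sequence in one species-specific tract per chromosome
#' (totaling \code{nonHomologousFraction} of the genome, with no SNP
#' records there).  Spliced gene models are placed without overlap, a
#' configurable few inside the species-specific tracts; PAF records
#' describe the true homologous tracts.  Byte-identical under a fixed
#' seed and config.
#'
#' @param config A [simulationConfig()].
#' @param seed RNG seed (default \code{config$seed}).
#' @return A list: \code{cattleGenome}, \code{yakGenome}
#'   (\code{DNAStringSet}), \code{snps} (\code{GRanges} with
#'   cattle/yak alleles), \code{genes} (\code{GRangesList} of exons),
#'   \code{paf} (data frame), \code{nonHomologous} (\code{GRanges}).
#' @export
simulateReference <- function(config, seed = config$seed) {
    withSeed(seed, {
        L <- as.integer(config$chromLength)
        chroms <- paste0("chr", seq_len(config$nChroms))
        cattle <- list(); yak <- list()
        snpList <- list(); tractList <- list(); pafList <- list()
        for (ci in seq_along(chroms)) {
            ch <- chroms[ci]
            bases <- .randomBases(L)
            tractLen <- as.integer(round(config$nonHomologousFraction * L))
            tractStart <- if (tractLen > 0)
                sample.int(L - tractLen, 1L) + 1L else NA_integer_
            tractIdx <- if (tractLen > 0)
                seq(tractStart, tractStart + tractLen - 1L) else integer(0)
            yakBases <- bases
            yakBases[tractIdx] <- .randomBases(length(tractIdx))
            snpPos <- which(stats::runif(L) < config$snpRate)
            snpPos <- setdiff(snpPos, tractIdx)
            yakBases[snpPos] <- .otherBase(bases[snpPos])
            cattle[[ch]] <- paste(bases, collapse = "")
            yak[[ch]] <- paste(yakBases, collapse = "")
            snpList[[ch]] <- data.frame(
                chrom = rep(ch, length(snpPos)), pos = snpPos,
                cattle = bases[snpPos], yak = yakBases[snpPos],
                stringsAsFactors = FALSE)
            tractList[[ch]] <- if (tractLen > 0)
                data.frame(chrom = ch, start = tractStart,
                           end = tractStart + tractLen - 1L) else NULL
            # homologous segments = complement of the tract
            segs <- if (tractLen > 0) {
                rbind(if (tractStart > 1)
                          c(1L, tractStart - 1L),
                      if (tractStart + tractLen - 1L < L)
                          c(tractStart + tractLen, L))
            } else matrix(c(1L, L), nrow = 1)
            nsnp <- vapply(seq_len(nrow(segs)), function(i)
                sum(snpPos >= segs[i, 1] & snpPos <= segs[i, 2]),
                integer(1))
            pafList[[ch]] <- data.frame(
                queryName = ch, queryLen = L,
                queryStart = segs[, 1], queryEnd = segs[, 2],
                strand = "+",
                targetName = ch, targetLen = L,
                targetStart = segs[, 1], targetEnd = segs[, 2],
                nMatches = segs[, 2] - segs[, 1] + 1L - nsnp,
                blockLen = segs[, 2] - segs[, 1] + 1L,
                mapq = 60L, stringsAsFactors = FALSE)
        }
        snpDf <- do.call(rbind, snpList)
        snps <- GRanges(snpDf$chrom, IRanges(snpDf$pos, width = 1L))
        mcols(snps)$cattle <- snpDf$cattle
        mcols(snps)$yak <- snpDf$yak
        tractDf <- do.call(rbind, tractList)
        nonHomologous <- if (is.null(tractDf)) GRanges() else
            GRanges(tractDf$chrom, IRanges(tractDf$start, tractDf$end))
        genes <- .placeGenes(config, chroms, L, nonHomologous)
        list(cattleGenome = DNAStringSet(unlist(cattle)),
             yakGenome = DNAStringSet(unlist(yak)),
             snps = snps, genes = genes,
             paf = do.call(rbind, pafList),
             nonHomologous = nonHomologous)
    })
}

# place spliced gene models without overlap; a few inside the
# species-specific tracts (to be excluded downstream), the rest wholly
# within homologous sequence
.placeGenes <- function(config, chroms, L, nonHomologous) {
    nGenes <- config$nGenes
    nNH <- config$nNonHomologousGenes
    ids <- sprintf("g%04d", seq_len(nGenes))
    inTract <- c(rep(TRUE, nNH), rep(FALSE, nGenes - nNH))
    # candidate intervals: homologous flanks (FALSE) and tracts (TRUE)
    ivs <- list()
    for (ch in chroms) {
        tr <- nonHomologous[seqnames(nonHomologous) == ch]
        if (length(tr)) {
            s <- start(tr)[1]; e <- end(tr)[1]
            if (s > 1) ivs[[length(ivs) + 1]] <-
                list(chrom = ch, lo = 1L, hi = s - 1L, tract = FALSE)
            if (e < L) ivs[[length(ivs) + 1]] <-
                list(chrom = ch, lo = e + 1L, hi = L, tract = FALSE)
            ivs[[length(ivs) + 1]] <-
                list(chrom = ch, lo = s, hi = e, tract = TRUE)
        } else {
            ivs[[length(ivs) + 1]] <-
                list(chrom = ch, lo = 1L, hi = L, tract = FALSE)
        }
    }
    cursor <- vapply(ivs, function(iv) iv$lo, integer(1))
    exonsList <- vector("list", nGenes)
    geneChrom <- character(nGenes)
    geneStrand <- character(nGenes)
    exRange <- config$exonsPerGene[1]:config$exonsPerGene[2]
    inRange <- config$intronLengthRange[1]:config$intronLengthRange[2]
    for (g in seq_len(nGenes)) {
        nEx <- exRange[sample.int(length(exRange), 1L)]
        txLen <- max(nEx * 30L,
                     as.integer(round(stats::rlnorm(1,
                         config$geneLengthMeanlog, config$geneLengthSdlog))))
        extra <- txLen - nEx * 20L
        exLens <- 20L + as.integer(stats::rmultinom(1, extra,
                                                    rep(1 / nEx, nEx)))
        inLens <- if (nEx > 1)
            inRange[sample.int(length(inRange), nEx - 1L,
                               replace = TRUE)] else integer(0)
        span <- sum(exLens) + sum(inLens)
        ok <- which(vapply(seq_along(ivs), function(i)
            ivs[[i]]$tract == inTract[g] &&
                cursor[i] + span + 100L <= ivs[[i]]$hi, logical(1)))
        if (length(ok) == 0L && inTract[g]) {
            # species-specific tracts are short; shrink the gene to fit
            cand <- which(vapply(ivs, `[[`, logical(1), "tract"))
            room <- vapply(cand, function(i)
                ivs[[i]]$hi - cursor[i] - 100L, numeric(1))
            best <- cand[which.max(room)]
            budget <- as.integer(max(room) - sum(inLens))
            if (budget >= 60L * nEx) {
                exLens <- rep(budget %/% (2L * nEx), nEx)
                span <- sum(exLens) + sum(inLens)
                ok <- best
            }
        }
        if (length(ok) == 0L)
            stop("cannot place gene ", ids[g], " without overlap; ",
                 "increase chromLength or reduce nGenes")
        iv <- ok[sample.int(length(ok), 1L)]
        gap <- sample(50:500, 1L)
        startPos <- min(cursor[iv] + gap,
                        ivs[[iv]]$hi - span + 1L)
        exStarts <- startPos + cumsum(c(0L, exLens[-nEx] + inLens))
        exonsList[[g]] <- IRanges(exStarts, width = exLens)
        geneChrom[g] <- ivs[[iv]]$chrom
        geneStrand[g] <- sample(c("+", "-"), 1L)
        cursor[iv] <- startPos + span
    }
    grl <- GRangesList(lapply(seq_len(nGenes), function(g)
        GRanges(geneChrom[g], exonsList[[g]], strand = geneStrand[g])))
    names(grl) <- ids
    mcols(grl)$geneId <- ids
    mcols(grl)$biotype <- "protein_coding"
    mcols(grl)$geneStrand <- geneStrand
    grl
}

#' Simulate true per-gene expression and allelic imbalance
#'
#' Draws each gene's expected read count from a log-normal and its true
#' cattle-allele fraction: 0.5 for null genes; for ADE genes, a fold
#' change drawn from \code{fcLevels} with direction Bernoulli(0.5),
#' giving fraction \code{fc/(1+fc)} (cattle-favoring) or \code{1/(1+fc)}
#' (yak-favoring).  A configurable subset of ADE genes is imbalanced in
#' one tissue only.
#'
#' @param config A [simulationConfig()].
#' @param genes \code{GRangesList} from [simulateReference()].
#' @param seed RNG seed.
#' @return A data frame (the ground truth): \code{geneId},
#'   \code{exprLevel}, \code{adeTrue}, \code{trueFc},
#'   \code{cattleFraction}, \code{tissueSpecific}, \code{adeTissue}.
#' @export
simulateExpression <- function(config, genes, seed = config$seed + 1L) {
    withSeed(seed, {
        n <- length(genes)
        level <- stats::rlnorm(n, config$readsPerGeneMeanlog,
                               config$readsPerGeneSdlog)
        ade <- stats::runif(n) < config$adeFraction
        fc <- rep(1, n)
        fc[ade] <- config$fcLevels[sample.int(length(config$fcLevels),
                                              sum(ade), replace = TRUE)]
        towardCattle <- stats::runif(n) < 0.5
        frac <- rep(0.5, n)
        frac[ade] <- ifelse(towardCattle[ade],
                            fc[ade] / (1 + fc[ade]),
                            1 / (1 + fc[ade]))
        tissueSpecific <- ade & stats::runif(n) < config$tissueSpecificFraction
        adeTissue <- rep(NA_character_, n)
        adeTissue[tissueSpecific] <- sample(config$tissues,
                                            sum(tissueSpecific),
                                            replace = TRUE)
        data.frame(geneId = names(genes), exprLevel = level,
                   adeTrue = ade, trueFc = fc, cattleFraction = frac,
                   tissueSpecific = tissueSpecific, adeTissue = adeTissue,
                   stringsAsFactors = FALSE)
    })
}

#' Default sample design of the simulation
#'
#' Sample names follow the study's convention: prefix F for lung, G for
#' liver, suffixed by the animal number.
#'
#' @param config A [simulationConfig()].
#' @return A sample design data frame ([readSampleMeta()] layout).
#' @export
simulationDesign <- function(config) {
    animals <- paste0("A", seq_len(config$nAnimals))
    prefix <- c(lung = "F", liver = "G")
    rows <- expand.grid(animalId = animals, tissue = config$tissues,
                        stringsAsFactors = FALSE)
    data.frame(
        sampleId = paste0(prefix[rows$tissue],
                          sub("^A", "", rows$animalId)),
        animalId = rows$animalId,
        tissue = rows$tissue,
        sireSpecies = rep(c("cattle", "yak"),
                          length.out = config$nAnimals)[
                              match(rows$animalId, animals)],
        stringsAsFactors = FALSE)
}

# spliced transcript base vectors (reference orientation) for one gene
.transcriptBases <- function(genomeChars, exons) {
    idx <- unlist(Map(seq.int, start(exons), end(exons)), use.names = FALSE)
    list(idx = idx, bases = genomeChars[idx])
}

#' Simulate error-bearing full-length reads with truth alignments
#'
#' For each sample and gene, draws a Poisson read count around the
#' gene's expression level and the parental haplotype of each read from
#' the gene's (tissue-adjusted) true cattle fraction.  Each read copies
#' the spliced transcript of its haplotype and is corrupted by
#' substitutions (uniform over the three alternative bases) and short
#' geometric indels; deletions are never placed over a SNP column, so
#' the vote-error model stays exactly enumerable.  The true CIGAR
#' against the cattle-coordinate reference is tracked throughout
#' (introns become N operations) — reads are emitted pre-aligned and no
#' external aligner is involved.  Read names encode nothing about the
#' truth, which lives in the returned sidecar table.
#'
#' @param config A [simulationConfig()].
#' @param reference Output of [simulateReference()].
#' @param truth Output of [simulateExpression()].
#' @param meta Sample design (default [simulationDesign()]).
#' @param seed RNG seed.
#' @return A list: \code{sam} (named list of per-sample data frames with
#'   columns qname, flag, chrom, pos, mapq, cigar, seq), \code{readTruth}
#'   (data frame readId, sampleId, geneId, haplotype), \code{totalMapped}
#'   (named vector).
#' @export
simulateReads <- function(config, reference, truth,
                          meta = simulationDesign(config),
                          seed = config$seed + 2L) {
    withSeed(seed, {
        chromChars <- list(
            cattle = lapply(as.character(reference$cattleGenome),
                            function(s) strsplit(s, "")[[1]]),
            yak = lapply(as.character(reference$yakGenome),
                         function(s) strsplit(s, "")[[1]]))
        genes <- reference$genes
        snpPosByChrom <- split(start(reference$snps),
                               as.character(seqnames(reference$snps)))
        geneInfo <- lapply(names(genes), function(g) {
            ex <- genes[[g]]
            ch <- as.character(seqnames(ex))[1]
            idx <- unlist(Map(seq.int, start(ex), end(ex)),
                          use.names = FALSE)
            list(chrom = ch, idx = idx,
                 cattleTx = chromChars$cattle[[ch]][idx],
                 yakTx = chromChars$yak[[ch]][idx],
                 snpCol = which(idx %in% snpPosByChrom[[ch]]),
                 strand = as.character(strand(ex))[1])
        })
        names(geneInfo) <- names(genes)

        samList <- list(); truthList <- list()
        for (si in seq_len(nrow(meta))) {
            sampleId <- meta$sampleId[si]
            tissue <- meta$tissue[si]
            rows <- list(); trows <- list(); counter <- 0L
            for (g in seq_along(geneInfo)) {
                gi <- geneInfo[[g]]
                tr <- truth[g, ]
                frac <- if (tr$adeTrue &&
                            (!tr$tissueSpecific || tr$adeTissue == tissue))
                    tr$cattleFraction else 0.5
                nReads <- stats::rpois(1, tr$exprLevel)
                if (nReads == 0L) next
                haps <- ifelse(stats::runif(nReads) < frac, "cattle", "yak")
                rds <- lapply(seq_len(nReads), function(r) .corruptRead(
                    if (haps[r] == "cattle") gi$cattleTx else gi$yakTx,
                    gi$idx, gi$snpCol, config))
                ok <- !vapply(rds, is.null, logical(1))
                if (!any(ok)) { counter <- counter + nReads; next }
                ids <- sprintf("%s_r%06d", sampleId,
                               counter + seq_len(nReads))
                counter <- counter + nReads
                rows[[length(rows) + 1]] <- data.frame(
                    qname = ids[ok],
                    flag = if (gi$strand == "-") 16L else 0L,
                    chrom = gi$chrom,
                    pos = vapply(rds[ok], `[[`, integer(1), "pos"),
                    mapq = 60L,
                    cigar = vapply(rds[ok], `[[`, character(1), "cigar"),
                    seq = vapply(rds[ok], `[[`, character(1), "seq"),
                    stringsAsFactors = FALSE)
                trows[[length(trows) + 1]] <- data.frame(
                    readId = ids[ok], sampleId = sampleId,
                    geneId = names(geneInfo)[g],
                    haplotype = haps[ok], stringsAsFactors = FALSE)
            }
            samList[[sampleId]] <- do.call(rbind, rows)
            truthList[[sampleId]] <- do.call(rbind, trows)
        }
        readTruth <- do.call(rbind, truthList)
        rownames(readTruth) <- NULL
        list(sam = samList, readTruth = readTruth,
             totalMapped = vapply(samList, function(x)
                 if (is.null(x)) 0L else nrow(x), integer(1)))
    })
}

# corrupt one transcript copy: substitutions, short indels (deletions
# avoid SNP columns), optional 5'-truncation; returns pos/cigar/seq
.corruptRead <- function(txBases, refIdx, snpCol, config) {
    m <- length(txBases)
    keepFrom <- 1L
    if (config$truncationRate > 0 &&
        stats::runif(1) < config$truncationRate)
        keepFrom <- 1L + as.integer(floor(stats::runif(1, 0, 0.5) * m))
    cols <- keepFrom:m
    bases <- txBases[cols]
    idx <- refIdx[cols]
    snpMask <- logical(length(cols))
    snpMask[snpCol[snpCol >= keepFrom] - keepFrom + 1L] <- TRUE
    n <- length(cols)

    u <- stats::runif(3L * n)
    sub <- u[seq_len(n)] < config$subRate
    bases[sub] <- .otherBase(bases[sub])

    deleted <- logical(n)
    delAt <- which(u[n + seq_len(n)] < config$delRate)
    for (s in delAt) {
        len <- 1L + stats::rgeom(1, config$indelGeomProb)
        span <- s:min(n, s + len - 1L)
        if (any(snpMask[span]) || any(deleted[span])) next
        deleted[span] <- TRUE
    }
    insLen <- integer(n)
    insAt <- which(u[2L * n + seq_len(n)] < config$insRate)
    insLen[insAt] <- 1L + stats::rgeom(length(insAt), config$indelGeomProb)

    keep <- !deleted
    if (!any(keep)) return(NULL)
    # trim columns before the first / after the last aligned base
    first <- which(keep)[1]
    last <- which(keep)[sum(keep)]
    cols2 <- first:last
    bases <- bases[cols2]; idx <- idx[cols2]
    deleted <- deleted[cols2]; insLen <- insLen[cols2]
    n <- length(cols2)

    # per-column op entries: optional I before the column, optional N for
    # the intron gap before the column, then M or D for the column itself
    gapBefore <- c(0L, diff(idx) - 1L)
    colOp <- rep("M", n); colOp[deleted] <- "D"
    jIns <- which(insLen > 0L)
    jGap <- which(gapBefore > 0L)
    entryCol <- c(jIns, jGap, seq_len(n))
    entrySub <- c(rep(1L, length(jIns)), rep(2L, length(jGap)),
                  rep(3L, n))
    entryOp <- c(rep("I", length(jIns)), rep("N", length(jGap)), colOp)
    entryLen <- c(insLen[jIns], gapBefore[jGap], rep(1L, n))
    ord <- order(entryCol, entrySub)
    ops <- entryOp[ord]; lens <- entryLen[ord]
    r <- rle(ops)
    runLens <- as.integer(rowsum(lens, rep(seq_along(r$lengths),
                                           r$lengths)))
    pieces <- bases; pieces[deleted] <- ""
    if (length(jIns))
        pieces[jIns] <- paste0(
            vapply(insLen[jIns], function(l)
                paste(.randomBases(l), collapse = ""), character(1)),
            pieces[jIns])
    list(pos = idx[1],
         cigar = paste0(runLens, r$values, collapse = ""),
         seq = paste(pieces, collapse = ""))
}

#' Counts-level allelic sampling layer of the simulator
#'
#' Draws per-gene, per-sample allelic tallies directly from the
#' statistical model the read-level simulator realizes: read depth
#' Poisson around the gene's expression level, a fixed fraction of reads
#' SNP-free (uninformative), and informative reads split
#' binomially by the gene's true (tissue-adjusted) cattle fraction.
#' This layer makes large-cohort statistical validation (type-I error,
#' power, estimator bias) affordable; the read-level layer exercises the
#' identical model end to end at desk scale.
#'
#' @param config A [simulationConfig()].
#' @param truth Output of [simulateExpression()].
#' @param meta Sample design (default [simulationDesign(config)]).
#' @param seed RNG seed.
#' @return Named list (by sample) of tally \code{DataFrame}s in the
#'   [tallyGeneCounts()] layout.
#' @export
simulateAlleleCounts <- function(config, truth,
                                 meta = simulationDesign(config),
                                 seed = config$seed + 3L) {
    withSeed(seed, {
        out <- list()
        for (si in seq_len(nrow(meta))) {
            tissue <- meta$tissue[si]
            frac <- ifelse(truth$adeTrue &
                           (!truth$tissueSpecific |
                            truth$adeTissue == tissue),
                           truth$cattleFraction, 0.5)
            frac[is.na(frac)] <- 0.5
            n <- stats::rpois(nrow(truth), truth$exprLevel)
            u <- stats::rbinom(nrow(truth), n, config$uninformativeRate)
            inf <- n - u
            ic <- stats::rbinom(nrow(truth), inf, frac)
            out[[meta$sampleId[si]]] <- DataFrame(
                geneId = truth$geneId,
                sampleId = meta$sampleId[si],
                informativeCattle = ic,
                informativeYak = inf - ic,
                uninformative = u,
                ambiguous = 0L)
        }
        out
    })
}

#' Write a complete simulated dataset to disk
#'
#' Emits the standard-format files of a simulation: both parental
#' genome FASTAs, the SNP VCF, the gene-model GFF3, the homology PAF,
#' one SAM per sample, the sample design TSV, the gene- and read-level
#' truth TSVs, and a manifest with md5 checksums.
#'
#' @param reference Output of [simulateReference()].
#' @param truth Output of [simulateExpression()].
#' @param reads Output of [simulateReads()].
#' @param meta Sample design data frame.
#' @param outDir Output directory (created if needed).
#' @return The manifest data frame (\code{file}, \code{md5}), invisibly
#'   written as \code{manifest.tsv}.
#' @export
writeDataset <- function(reference, truth, reads, meta, outDir) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    sl <- setNames(Biostrings::width(reference$cattleGenome),
                   names(reference$cattleGenome))
    writeGenome(reference$cattleGenome, file.path(outDir, "cattle.fa"))
    writeGenome(reference$yakGenome, file.path(outDir, "yak.fa"))
    writeVcfSnps(reference$snps, file.path(outDir, "snps.vcf"),
                 contigLengths = sl)
    .writeGff3(reference$genes, file.path(outDir, "genes.gff3"))
    writePaf(reference$paf, file.path(outDir, "homology.paf"))
    for (s in names(reads$sam))
        .writeSamTable(reads$sam[[s]], sl,
                       file.path(outDir, paste0(s, ".sam")))
    writeSampleMeta(meta, file.path(outDir, "samples.tsv"))
    writeTsv(truth, file.path(outDir, "truth_genes.tsv"))
    writeTsv(reads$readTruth, file.path(outDir, "truth_reads.tsv"))
    files <- setdiff(list.files(outDir), "manifest.tsv")
    manifest <- data.frame(
        file = files,
        md5 = unname(tools::md5sum(file.path(outDir, files))),
        stringsAsFactors = FALSE)
    writeTsv(manifest, file.path(outDir, "manifest.tsv"))
    invisible(manifest)
}

.writeSamTable <- function(df, seqLengths, path) {
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqLengths),
                     as.integer(seqLengths)))
    rec <- if (is.null(df) || nrow(df) == 0L) character(0) else
        sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                df$qname, df$flag, df$chrom, df$pos, df$mapq, df$cigar,
                df$seq)
    writeLines(c(hdr, rec), path)
    invisible(path)
}

.writeGff3 <- function(genes, path) {
    lines <- "##gff-version 3"
    for (g in names(genes)) {
        ex <- genes[[g]]
        ch <- as.character(seqnames(ex))[1]
        st <- as.character(strand(ex))[1]
        lines <- c(lines,
            sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=protein_coding",
                    ch, min(start(ex)), max(end(ex)), st, g),
            sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                    ch, min(start(ex)), max(end(ex)), st, g, g),
            sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                    ch, start(ex), end(ex), st, g, seq_along(ex), g))
    }
    writeLines(lines, path)
    invisible(path)
}

#' One-call simulation of a complete dataset on disk
#'
#' Composes [simulateReference()], [simulateExpression()],
#' [simulateReads()] and [writeDataset()] under a single seed.
#'
#' @param config A [simulationConfig()].
#' @param outDir Output directory.
#' @param seed Master seed (default \code{config$seed}).
#' @return Invisibly, a list with the in-memory simulation components
#'   and the file manifest.
#' @export
simulateDataset <- function(config = simulationConfig(), outDir,
                            seed = config$seed) {
    reference <- simulateReference(config, seed = seed)
    truth <- simulateExpression(config, reference$genes, seed = seed + 1L)
    meta <- simulationDesign(config)
    reads <- simulateReads(config, reference, truth, meta,
                           seed = seed + 2L)
    manifest <- writeDataset(reference, truth, reads, meta, outDir)
    invisible(list(reference = reference, truth = truth, reads = reads,
                   meta = meta, manifest = manifest))
}
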