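smallCfg <- simulationConfig(nGenes = 8, chromLength = 4e4L,
                             nAnimals = 1, tissues = "lung",
                             nNonHomologousGenes = 1L)

test_that("the simulator is byte-deterministic under a fixed seed", {
    d1 <- tempfile(); d2 <- tempfile()
    m1 <- simulateDataset(smallCfg, d1, seed = 51)$manifest
    m2 <- simulateDataset(smallCfg, d2, seed = 51)$manifest
    expect_identical(m1$md5, m2$md5)
    m3 <- simulateDataset(smallCfg, tempfile(), seed = 52)$manifest
    expect_false(all(m3$md5 == m1$md5))
})

test_that("a zero SNP rate leaves homologous tracts identical", {
    cfg <- simulationConfig(nGenes = 4, chromLength = 2e4L, snpRate = 0,
                            nNonHomologousGenes = 0L)
    ref <- simulateReference(cfg, seed = 53)
    expect_equal(length(ref$snps), 0L)
    tract <- ref$nonHomologous[1]
    flank <- IRanges::setdiff(
        IRanges::IRanges(1L, cfg$chromLength),
        IRanges::ranges(tract))
    for (i in seq_along(flank)) {
        s <- IRanges::start(flank)[i]; e <- IRanges::end(flank)[i]
        expect_equal(
            as.character(subseq(ref$cattleGenome[["chr1"]], s, e)),
            as.character(subseq(ref$yakGenome[["chr1"]], s, e)))
    }
    # and the species-specific tract diverges
    expect_false(as.character(subseq(ref$cattleGenome[["chr1"]],
                                     start(tract), end(tract))) ==
                 as.character(subseq(ref$yakGenome[["chr1"]],
                                     start(tract), end(tract))))
})

test_that("the SNP count is consistent with the binomial model", {
    cfg <- simulationConfig(nGenes = 4, chromLength = 1e5L,
                            snpRate = 0.012)
    ref <- simulateReference(cfg, seed = 54)
    homLen <- sum(width(ref$cattleGenome)) -
        sum(width(ref$nonHomologous))
    expected <- 0.012 * homLen
    expect_lt(abs(length(ref$snps) - expected),
              4 * sqrt(expected * (1 - 0.012)))
    # no SNP records inside species-specific tracts
    expect_equal(length(IRanges::subsetByOverlaps(ref$snps,
                                                  ref$nonHomologous)), 0L)
})

test_that("true allelic fractions follow the fold-change model", {
    cfg0 <- simulationConfig(nGenes = 50, adeFraction = 0)
    ref <- simulateReference(simulationConfig(nGenes = 50,
                                              chromLength = 3e5L),
                             seed = 55)
    t0 <- simulateExpression(cfg0, ref$genes, seed = 56)
    expect_true(all(t0$cattleFraction == 0.5))
    expect_false(any(t0$adeTrue))

    cfg1 <- simulationConfig(nGenes = 50, adeFraction = 1,
                             fcLevels = 4)
    t1 <- simulateExpression(cfg1, ref$genes, seed = 57)
    expect_true(all(t1$adeTrue))
    expect_true(all(t1$cattleFraction %in% c(0.8, 0.2)))
    # ADE flag consistent with |log2 allelic ratio| >= log2(fc)
    lr <- abs(log2(t1$cattleFraction / (1 - t1$cattleFraction)))
    expect_true(all(lr >= log2(2) - 1e-12))
})

test_that("read-level parental ratios of null genes center on one half", {
    cfg <- simulationConfig(nGenes = 600, adeFraction = 0,
                            readsPerGeneMeanlog = log(40),
                            readsPerGeneSdlog = 0.2)
    truth <- data.frame(geneId = sprintf("g%04d", 1:600),
                        exprLevel = 40, adeTrue = FALSE, trueFc = 1,
                        cattleFraction = 0.5, tissueSpecific = FALSE,
                        adeTissue = NA_character_)
    meta <- data.frame(sampleId = "S1", animalId = "A1", tissue = "lung",
                       sireSpecies = "cattle")
    counts <- simulateAlleleCounts(cfg, truth, meta, seed = 58)$S1
    inf <- counts$informativeCattle + counts$informativeYak
    frac <- sum(counts$informativeCattle) / sum(inf)
    se <- 0.5 / sqrt(sum(inf))
    expect_lt(abs(frac - 0.5), 4 * se)
})

test_that("error-free reads carry true haplotype alleles and intron N ops", {
    cfg <- simulationConfig(nGenes = 6, chromLength = 3e4L,
                            nAnimals = 1, tissues = "lung",
                            subRate = 0, insRate = 0, delRate = 0,
                            exonsPerGene = c(2L, 2L),
                            nNonHomologousGenes = 0L)
    ref <- simulateReference(cfg, seed = 59)
    truth <- simulateExpression(cfg, ref$genes, seed = 60)
    reads <- simulateReads(cfg, ref, truth, simulationDesign(cfg),
                           seed = 61)
    sam <- reads$sam$F1
    # every 2-exon read spans exactly one intron: a single N op whose
    # length equals the gap between the gene's exons
    nOps <- regmatches(sam$cigar, gregexpr("[0-9]+N", sam$cigar))
    expect_true(all(lengths(nOps) == 1L))
    g1 <- ref$genes[[reads$readTruth$geneId[1]]]
    intron <- start(g1)[2] - end(g1)[1] - 1L
    expect_equal(as.integer(sub("N", "", nOps[[1]])), intron)
    # no errors: M ops only besides the intron
    expect_false(any(grepl("[IDSX]", sam$cigar)))
})

test_that("substitution errors hit SNP observations at the configured rate", {
    cfg <- simulationConfig(nGenes = 20, chromLength = 1e5L,
                            nAnimals = 1, tissues = "lung",
                            subRate = 0.05, insRate = 0, delRate = 0,
                            readsPerGeneMeanlog = log(60),
                            readsPerGeneSdlog = 0.2,
                            nNonHomologousGenes = 0L)
    ref <- simulateReference(cfg, seed = 62)
    truth <- simulateExpression(cfg, ref$genes, seed = 63)
    reads <- simulateReads(cfg, ref, truth, simulationDesign(cfg),
                           seed = 64)
    d <- tempfile(); dir.create(d)
    writeDataset(ref, truth, reads, simulationDesign(cfg), d)
    al <- readSamAlignments(file.path(d, "F1.sam"))
    obs <- snpObservations(al, ref$snps)
    hap <- reads$readTruth$haplotype[match(obs$readId,
                                           reads$readTruth$readId)]
    trueAllele <- ifelse(hap == "cattle",
                         mcols(ref$snps)$cattle[match(paste(obs$chrom,
                                                            obs$pos),
                             paste(as.character(seqnames(ref$snps)),
                                   start(ref$snps)))],
                         mcols(ref$snps)$yak[match(paste(obs$chrom,
                                                         obs$pos),
                             paste(as.character(seqnames(ref$snps)),
                                   start(ref$snps)))])
    disagree <- mean(obs$base != trueAllele)
    n <- nrow(obs)
    expect_gt(n, 1e4)
    expect_lt(abs(disagree - 0.05), 4 * sqrt(0.05 * 0.95 / n))
})

test_that("the dataset manifest reflects the design arithmetic", {
    d <- tempfile()
    m <- simulateDataset(smallCfg, d, seed = 65)$manifest
    expect_equal(sum(grepl("\\.sam$", m$file)), 1L)  # 1 animal x 1 tissue
    expect_true(all(c("cattle.fa", "yak.fa", "snps.vcf", "genes.gff3",
                      "homology.paf", "samples.tsv", "truth_genes.tsv",
                      "truth_reads.tsv") %in% m$file))
    cfg2 <- simulationConfig(nGenes = 6, chromLength = 3e4L,
                             nAnimals = 2, nNonHomologousGenes = 0L)
    m2 <- simulateDataset(cfg2, tempfile(), seed = 66)$manifest
    expect_equal(sum(grepl("\\.sam$", m2$file)), 4L)  # 2 animals x 2 tissues
})

test_that("emitted SAM is internally consistent", {
    d <- tempfile()
    simulateDataset(smallCfg, d, seed = 67)
    # the reader validates CIGAR-implied query length == sequence length
    al <- readSamAlignments(file.path(d, "F1.sam"))
    expect_gt(length(al), 0L)
    expect_true(all(GenomicAlignments::qwidth(al) ==
                    width(mcols(al)$seq)))
})
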