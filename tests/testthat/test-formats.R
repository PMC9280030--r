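test_that("PAF parsing maps the mandatory fields and converts coordinates", {
    f <- tempfile(fileext = ".paf")
    writeLines("q1\t1000\t0\t500\t+\tt1\t2000\t100\t600\t480\t500\t60", f)
    p <- readPaf(f)
    expect_equal(nrow(p), 1L)
    expect_equal(p$queryName, "q1")
    # 0-based half-open 0..500 becomes 1-based closed 1..500
    expect_equal(c(p$queryStart, p$queryEnd), c(1L, 500L))
    expect_equal(c(p$targetStart, p$targetEnd), c(101L, 600L))
    expect_equal(p$nMatches, 480L)
    expect_equal(p$mapq, 60L)

    writeLines(character(0), f)
    expect_equal(nrow(readPaf(f)), 0L)

    writeLines("q1\t1000\t0\t500\t+\tt1\t2000\t100\t600\t480\t500", f)
    expect_error(readPaf(f), "12 mandatory columns")

    writeLines("q1\t1000\t500\t500\t+\tt1\t2000\t100\t600\t480\t500\t60", f)
    expect_error(readPaf(f), "validation error")
})

test_that("PAF coordinates round-trip through write and read", {
    f <- tempfile(fileext = ".paf")
    orig <- "q1\t1000\t0\t500\t-\tt1\t2000\t100\t600\t480\t500\t60"
    writeLines(orig, f)
    p <- readPaf(f)
    f2 <- tempfile(fileext = ".paf")
    writePaf(p, f2)
    expect_identical(readLines(f2), orig)
})

test_that("VCF SNP reading keeps biallelic SNVs and counts skips", {
    f <- tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 "##contig=<ID=chr1,length=1000>",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                 "chr1\t101\t.\tA\tG\t.\tPASS\t.",
                 "chr1\t150\t.\tAT\tA\t.\tPASS\t.",
                 "chr1\t200\t.\tC\tG,T\t.\tPASS\t."), f)
    snps <- readVcfSnps(f)
    expect_equal(length(snps), 1L)
    expect_equal(start(snps), 101L)  # VCF POS is already 1-based
    expect_equal(mcols(snps)$cattle, "A")
    expect_equal(mcols(snps)$yak, "G")
    expect_equal(metadata(snps)$skipped[["indel"]], 1L)
    expect_equal(metadata(snps)$skipped[["multiallelic"]], 1L)
})

test_that("VCF SNPs round-trip through the simulator's writer", {
    snps <- makeSnps("chr1", c(10L, 20L), c("A", "C"), c("G", "T"))
    f <- tempfile(fileext = ".vcf")
    writeVcfSnps(snps, f, contigLengths = c(chr1 = 100L))
    back <- readVcfSnps(f)
    expect_equal(start(back), start(snps))
    expect_equal(mcols(back)$cattle, mcols(snps)$cattle)
    expect_equal(mcols(back)$yak, mcols(snps)$yak)
})

test_that("SAM reading converts, filters unmapped and flags secondaries", {
    f <- writeTestSam(
        qname = c("r1", "r2", "r3"),
        flag = c(0L, 256L, 4L),
        chrom = c("chr1", "chr1", "*"),
        pos = c(11L, 1L, 0L),
        cigar = c("10M", "5M10N5M", "*"),
        seq = c("ACGTACGTAC", "ACGTAACGTA", "AAAA"))
    al <- readSamAlignments(f)
    expect_equal(length(al), 2L)  # unmapped excluded
    expect_equal(metadata(al)$skipped[["unmapped"]], 1L)
    expect_equal(start(al)[1], 11L)
    expect_equal(GenomicAlignments::cigar(al)[1], "10M")
    expect_identical(mcols(al)$isPrimary, c(TRUE, FALSE))
})

test_that("SAM round-trips all retained mandatory fields bit-exactly", {
    cfg <- simulationConfig(nGenes = 8, chromLength = 4e4L, nAnimals = 1,
                            tissues = "lung", nNonHomologousGenes = 1L)
    ref <- simulateReference(cfg, seed = 21)
    truth <- simulateExpression(cfg, ref$genes, seed = 22)
    reads <- simulateReads(cfg, ref, truth, simulationDesign(cfg),
                           seed = 23)
    d <- tempfile(); dir.create(d)
    manifest <- writeDataset(ref, truth, reads, simulationDesign(cfg), d)
    samIn <- file.path(d, "F1.sam")
    al <- readSamAlignments(samIn)
    samOut <- tempfile(fileext = ".sam")
    writeSamAlignments(al, samOut)
    stripQual <- function(p) {
        x <- readLines(p)
        x <- x[!startsWith(x, "@")]
        vapply(strsplit(x, "\t"), function(f)
            paste(f[c(1:6, 10)], collapse = "\t"), character(1))
    }
    expect_identical(sort(stripQual(samOut)), sort(stripQual(samIn)))
})

test_that("GFF3 gene models are converted and exon unions taken", {
    f <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=gA",
                 "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=gA.t1;Parent=gA",
                 "chr1\tsrc\texon\t1\t51\t.\t+\t.\tID=e1;Parent=gA.t1",
                 "chr1\tsrc\texon\t41\t81\t.\t+\t.\tID=e2;Parent=gA.t1"), f)
    g <- readGffGenes(f)
    expect_equal(names(g), "gA")
    ex <- g[["gA"]]
    # overlapping exons merged into one interval
    expect_equal(length(ex), 1L)
    expect_equal(c(start(ex), end(ex)), c(1L, 81L))

    writeLines(c("##gff-version 3",
                 "chr1\tsrc\tregion\t1\t100\t.\t+\t.\tID=r1"), f)
    expect_equal(length(readGffGenes(f)), 0L)

    writeLines(c("##gff-version 3",
                 "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=gA",
                 "chr1\tsrc\texon\t1\t50\t.\t+\t.\tID=e1;Parent=gA",
                 "chr1\tsrc\texon\t60\t70\t.\t+\t.\tID=e2;Parent=ghost"), f)
    expect_warning(g <- readGffGenes(f), "unresolvable Parent")
    expect_equal(metadata(g)$skipped[["orphanExon"]], 1L)
    expect_equal(length(g[["gA"]]), 1L)
})

test_that("genome FASTA reading enforces the A/C/G/T/N alphabet", {
    f <- tempfile(fileext = ".fa")
    writeLines(c(">chr1", "ACGTN"), f)
    g <- readGenome(f)
    expect_equal(as.character(g[["chr1"]]), "ACGTN")
    writeLines(c(">chr1", "ACGRT"), f)
    expect_error(readGenome(f), "outside \\{A,C,G,T,N\\}")
})

test_that("sample metadata is validated on read", {
    f <- tempfile(fileext = ".tsv")
    meta <- data.frame(sampleId = c("F1", "G1"), animalId = c("A1", "A1"),
                       tissue = c("lung", "liver"),
                       sireSpecies = c("cattle", "cattle"))
    writeSampleMeta(meta, f)
    expect_equal(readSampleMeta(f), meta)
    meta$tissue <- c("lung", "lung")
    writeSampleMeta(meta, f)
    expect_error(readSampleMeta(f), "unique")
})

test_that("homology map round-trips through BED3+3", {
    map <- makeMap("chr1", c(1L, 501L), c(100L, 900L), c(chr1 = 1000L))
    f <- tempfile(fileext = ".bed")
    writeHomologyBed(map, f)
    back <- readHomologyBed(f)
    expect_equal(start(back), start(map))
    expect_equal(end(back), end(map))
    expect_equal(GenomeInfoDb::seqlengths(back), GenomeInfoDb::seqlengths(map))
    # printed form is 0-based half-open
    body <- grep("^#", readLines(f), invert = TRUE, value = TRUE)
    expect_equal(strsplit(body[1], "\t")[[1]][2:3], c("0", "100"))
})
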