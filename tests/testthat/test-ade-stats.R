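# independent enumeration oracle: hypergeometric probabilities from
# log-binomial coefficients, no dhyper
enumFisher <- function(a, b, c, d) {
    n <- a + b + c + d; k <- a + b; c1 <- a + c
    lo <- max(0L, k - (n - c1)); hi <- min(k, c1)
    x <- lo:hi
    p <- exp(lchoose(c1, x) + lchoose(n - c1, k - x) - lchoose(n, k))
    min(sum(p[p <= p[x == a] * (1 + 1e-7)]), 1)
}

test_that("the two-sided Fisher p matches enumeration and known values", {
    expect_equal(fisherExactTwoSided(5, 5, 500, 500), 1.0)
    # only the two extreme tables are as improbable as [[10,0],[0,10]]
    expect_equal(fisherExactTwoSided(10, 0, 0, 10), 2 / choose(20, 10),
                 tolerance = 1e-12)
    set.seed(11)
    for (i in 1:300) {
        t <- rpois(4, sample(c(2, 10, 80), 1))
        if (sum(t) == 0) next
        expect_equal(fisherExactTwoSided(t[1], t[2], t[3], t[4]),
                     enumFisher(t[1], t[2], t[3], t[4]),
                     tolerance = 1e-9)
        expect_equal(fisherExactTwoSided(t[1], t[2], t[3], t[4]),
                     stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                     tolerance = 1e-9)
    }
    expect_error(fisherExactTwoSided(-1, 2, 3, 4), "non-negative")
    expect_error(fisherExactTwoSided(0, 0, 0, 0), "positive")
})

test_that("the Fisher p is symmetric and 1 at the modal table", {
    set.seed(12)
    for (i in 1:50) {
        t <- rpois(4, 15)
        if (sum(t) == 0) next
        p <- fisherExactTwoSided(t[1], t[2], t[3], t[4])
        expect_equal(p, fisherExactTwoSided(t[2], t[1], t[4], t[3]))
        expect_equal(p, fisherExactTwoSided(t[3], t[4], t[1], t[2]))
    }
    # proportional rows make the observed table modal
    expect_equal(fisherExactTwoSided(20, 10, 200, 100), 1.0)
})

test_that("fold change is max/min with monoallelic infinity", {
    expect_equal(foldChange(36, 12), 3.0)
    expect_equal(foldChange(10, 10), 1.0)
    expect_equal(foldChange(10, 0), Inf)
    expect_error(foldChange(0, 0), "both counts are zero")
    expect_error(foldChange(-1, 5), "non-negative")
})

test_that("gene-level ADE testing combines the p-value and the FC gate", {
    r <- testGeneAde(40, 10, 1e5, 1e5)
    expect_equal(r$foldChange, 4.0)
    expect_equal(r$pValue, enumFisher(40, 10, 1e5 - 40, 1e5 - 10),
                 tolerance = 1e-9)
    expect_lt(r$pValue, 0.05)
    expect_true(r$significant)
    expect_equal(r$direction, "CATTLE")

    r2 <- testGeneAde(30, 20, 1e5, 1e5)
    expect_equal(r2$foldChange, 1.5)
    expect_false(r2$significant)   # FC gate regardless of p
    expect_equal(r2$direction, "NONE")

    r3 <- testGeneAde(5, 5, 1e5, 1e5)
    expect_equal(r3$foldChange, 1.0)
    expect_equal(r3$pValue, 1.0)
    expect_false(r3$significant)

    # fractional redistributed counts are integerized half-away-from-zero
    r4 <- testGeneAde(10.5, 2.4, 1e3, 1e3)
    expect_equal(c(r4$cattleCount, r4$yakCount), c(11, 2))

    expect_error(testGeneAde(40, 10, 30, 1e5), "library totals")
    rb <- testGeneAde(40, 10, 1e5, 1e5, method = "binomial")
    expect_equal(rb$pValue, stats::binom.test(40, 50, 0.5)$p.value)
})

mkResults <- function(df) {
    DataFrame(geneId = df$geneId, sampleId = df$sampleId,
              cattleCount = 10, yakCount = 30, foldChange = 3,
              pValue = ifelse(df$significant, 0.001, 0.5),
              bhQ = 0.1, significant = df$significant,
              direction = df$direction)
}

fullMeta <- data.frame(
    sampleId = c(paste0("F", 1:5), paste0("G", 1:5)),
    animalId = rep(paste0("A", 1:5), 2),
    tissue = rep(c("lung", "liver"), each = 5),
    sireSpecies = "cattle", stringsAsFactors = FALSE)

test_that("ubiquity requires significance in every animal of a tissue", {
    df <- data.frame(
        geneId = "g1",
        sampleId = fullMeta$sampleId,
        significant = c(rep(TRUE, 5), c(TRUE, TRUE, TRUE, FALSE, FALSE)),
        direction = c(rep("YAK", 8), "NONE", "NONE"),
        stringsAsFactors = FALSE)
    cl <- classifyAde(mkResults(df), fullMeta)
    expect_true(cl$ubiquitousLung)
    expect_false(cl$ubiquitousLiver)
    expect_equal(as.character(cl$tissuePattern), "LUNG_ONLY")
    expect_equal(as.character(cl$directionClass), "YAK")

    df2 <- df
    df2$significant <- TRUE
    df2$direction <- rep(c("YAK", "CATTLE"), each = 5)
    cl2 <- classifyAde(mkResults(df2), fullMeta)
    expect_equal(as.character(cl2$tissuePattern), "BOTH")
    expect_equal(as.character(cl2$directionClass), "VARIABLE")

    df3 <- df
    df3$significant <- c(rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 2))
    df3$direction <- ifelse(df3$significant, "YAK", "NONE")
    cl3 <- classifyAde(mkResults(df3), fullMeta)
    expect_equal(as.character(cl3$tissuePattern), "NONE")
    expect_equal(as.character(cl3$directionClass), "NONE")
})

test_that("a gene untested in one animal cannot be ubiquitous", {
    df <- data.frame(geneId = "g1",
                     sampleId = fullMeta$sampleId[c(1:4, 6:10)],
                     significant = TRUE, direction = "YAK",
                     stringsAsFactors = FALSE)  # F5 missing
    cl <- classifyAde(mkResults(df), fullMeta)
    expect_false(cl$ubiquitousLung)
    expect_true(cl$ubiquitousLiver)
})

test_that("the ADE summary tabulates classes and handles empties", {
    df <- rbind(
        data.frame(geneId = "gLungYak", sampleId = fullMeta$sampleId,
                   significant = rep(c(TRUE, FALSE), each = 5),
                   direction = rep(c("YAK", "NONE"), each = 5)),
        data.frame(geneId = "gBothCattle", sampleId = fullMeta$sampleId,
                   significant = TRUE, direction = "CATTLE"),
        data.frame(geneId = "gNone", sampleId = fullMeta$sampleId,
                   significant = FALSE, direction = "NONE"))
    res <- mkResults(df)
    cl <- classifyAde(res, fullMeta)
    s <- summarizeAde(res, cl)
    get <- function(m) s$count[s$metric == m]
    expect_equal(get("ade_any_sample"), 2L)
    expect_equal(get("ubiquitous_total"), 2L)
    expect_equal(get("direction_yak"), 1L)
    expect_equal(get("direction_cattle"), 1L)
    expect_equal(get("direction_variable"), 0L)
    expect_equal(get("pattern_lung_only"), 1L)
    expect_equal(get("pattern_both"), 1L)

    sEmpty <- summarizeAde(res[0, ], cl[0, ])
    expect_true(all(sEmpty$count == 0))
})

test_that("runAdeTests tests only filtered, informative genes", {
    tallies <- list(
        S1 = makeTally(c("gBig", "gTiny", "gNoInf", "gNull"),
                       ic = c(40L, 1L, 0L, 500L),
                       iy = c(10L, 1L, 0L, 500L),
                       u = c(0L, 0L, 10L, 0L), sampleId = "S1"))
    aset <- makeAset(tallies)
    res <- runAdeTests(aset, minReads = 3L)
    # gTiny fails the filter; gNoInf has no informative reads
    expect_setequal(res$geneId, c("gBig", "gNull"))
    # library totals include every gene: (40+1+500, 10+1+500)
    big <- res[res$geneId == "gBig", ]
    expect_equal(big$pValue,
                 stats::fisher.test(matrix(c(40, 10, 501, 501), 2,
                                           byrow = TRUE))$p.value,
                 tolerance = 1e-12)
    expect_true(big$significant)
    expect_false(res$significant[res$geneId == "gNull"])
    resB <- runAdeTests(aset, minReads = 3L, method = "binomial")
    expect_equal(resB$pValue[resB$geneId == "gBig"],
                 stats::binom.test(40, 50, 0.5)$p.value)
})
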