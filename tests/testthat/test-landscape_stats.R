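test_that("rank-based decile bins follow the floor(10*(rank-1)/n) rule", {
    x <- mkTfcrSet(seq(0L, 9000L, by = 1000L), seq(0L, 9000L, by = 1000L) +
                       500L, sc = 1:10)
    x <- assignDecileBins(x, axis = "sc")
    expect_equal(decileBin(x, "sc"), 0:9)

    y <- assignDecileBins(mkTfcrSet(seq_len(3) * 1000L,
                                    seq_len(3) * 1000L + 100L,
                                    tc = c(5L, 1L, 9L)), axis = "tc")
    expect_equal(sort(decileBin(y, "tc")), c(0L, 3L, 6L))

    z <- assignDecileBins(mkTfcrSet(seq_len(20) * 1000L,
                                    seq_len(20) * 1000L + 100L,
                                    sc = sample(20)), axis = "sc")
    expect_equal(as.vector(table(decileBin(z, "sc"))), rep(2L, 10))
})

test_that("equal-width binning is available as the documented alternative", {
    x <- mkTfcrSet(seq_len(4) * 1000L, seq_len(4) * 1000L + 100L,
                   sc = c(0, 4.9, 5, 10))
    x <- assignDecileBins(x, axis = "sc", method = "value")
    expect_equal(decileBin(x, "sc"), c(0L, 4L, 5L, 9L))
})

test_that("correlation split separates linear and saturated strata", {
    tc <- 1:100
    x <- mkTfcrSet(tc * 10000L, tc * 10000L + 500L, tc = tc, sc = 2 * tc)
    s <- tcScCorrelationSplit(x, 50)
    expect_equal(s$r_low, 1)
    expect_equal(s$r_high, 1)
    expect_equal(s$n_low + s$n_high, 100L)

    set.seed(10)
    eps <- runif(100, -1e-6, 1e-6)
    y <- mkTfcrSet(tc * 10000L, tc * 10000L + 500L, tc = tc,
                   sc = pmin(tc, 50) + 10 + eps)
    s2 <- tcScCorrelationSplit(y, 50)
    expect_gt(s2$r_low, 0.99)
    expect_lt(abs(s2$r_high), 0.1)

    # a 2-point stratum is flagged, not fabricated
    z <- mkTfcrSet(c(1000L, 2000L, 3000L), c(1500L, 2500L, 3500L),
                   tc = c(1L, 2L, 60L), sc = c(1, 2, 3))
    s3 <- tcScCorrelationSplit(z, 50)
    expect_true(is.na(s3$r_low) && s3$reason_low == "too_few")
    expect_true(is.na(s3$r_high) && s3$reason_high == "too_few")
    expect_error(tcScCorrelationSplit(TFCRSet(), 50), "empty")
})

test_that("Pearson r agrees with a textbook two-pass formula", {
    set.seed(9)
    for (i in 1:20) {
        n <- sample(5:200, 1)
        tc <- sample.int(100, n, replace = TRUE)
        sc <- runif(n, 0, 50)
        x <- mkTfcrSet(seq_len(n) * 2000L, seq_len(n) * 2000L + 500L,
                       tc = tc, sc = sc)
        s <- tcScCorrelationSplit(x, max(tc) + 1)
        expect_equal(s$r_low, pearsonTwoPass(tc, sc), tolerance = 1e-12)
    }
})

test_that("expression enrichment flags bins whose TFCRs cover high-FPKM genes", {
    # 10 TFCRs, bins 0..9 on both axes; genes only under the bin-9 window
    x <- mkTfcrSet(seq(0L, 90000L, by = 10000L),
                   seq(0L, 90000L, by = 10000L) + 1000L,
                   tc = 1:10, sc = 1:10)
    x <- assignDecileBins(x)
    genes <- mkGenes("chr1", c(90100L, 30000L), c(90600L, 30500L),
                     c("+", "+"), id = c("HI", "LO"))
    expr <- c(HI = 50, LO = 0.1)
    df <- expressionEnrichmentByBin(x, genes, expr, highExprCutoff = 5)
    tcRows <- df[df$axis == "TC", ]
    expect_equal(tcRows$value[tcRows$bin == 9], 1)
    expect_equal(tcRows$value[tcRows$bin %in% 0:8], rep(0, 9))
    expect_true(all(df$value >= 0 & df$value <= 1, na.rm = TRUE))
    # no gene covered by any TFCR -> all zero
    far <- mkGenes("chr2", 1000L, 2000L, "+")
    df0 <- expressionEnrichmentByBin(x, far, c(G001 = 99),
                                     highExprCutoff = 5)
    expect_true(all(df0$value == 0))
    expect_warning(expressionEnrichmentByBin(x, GRanges(), expr),
                   "no genes")
})

test_that("element overlap proportions behave at the extremes", {
    x <- assignDecileBins(mkTfcrSet(seq(0L, 90000L, by = 10000L),
                                    seq(0L, 90000L, by = 10000L) + 1000L,
                                    tc = 1:10, sc = 10:1))
    tiling <- GRanges("chr1", IRanges(1, 100000))
    mcols(tiling) <- DataFrame(element_class = "promoter")
    df <- elementOverlapByBin(x, tiling)
    expect_true(all(df$value == 1))
    df0 <- elementOverlapByBin(x, tiling[0])
    expect_true(all(df0$value == 0))
    # pooled proportion equals the union contribution of disjoint classes
    twoClasses <- GRanges("chr1", IRanges(c(1, 10001), c(1000, 11000)))
    mcols(twoClasses) <- DataFrame(element_class = c("promoter",
                                                     "enhancer"))
    df2 <- elementOverlapByBin(x, twoClasses)
    pooledTc <- df2[df2$axis == "TC" & df2$element_class == "pooled", ]
    promTc <- df2[df2$axis == "TC" & df2$element_class == "promoter", ]
    enhTc <- df2[df2$axis == "TC" & df2$element_class == "enhancer", ]
    expect_equal(pooledTc$value, promTc$value + enhTc$value)
})

test_that("mutation rate is per-kb of window and shard-invariant", {
    x <- assignDecileBins(mkTfcrSet(1000L, 2000L, tc = 3L, sc = 5))
    v <- GRanges("chr1", IRanges(c(1200L, 1800L) + 1L, c(1201L, 1801L)))
    mcols(v) <- DataFrame(id = c("a", "b"))
    df <- mutationRateByBin(x, v)
    expect_equal(df$value[df$axis == "TC" & df$bin == 0], 2)
    expect_true(all(mutationRateByBin(x, v[0])$value %in% c(0, NA)))

    # splitting the variant set into shards and summing counts changes
    # nothing: rates derive from per-window counts
    set.seed(13)
    n <- 30L
    xs <- assignDecileBins(mkTfcrSet(seq_len(n) * 5000L,
                                     seq_len(n) * 5000L + 1000L,
                                     tc = sample.int(50, n, TRUE),
                                     sc = runif(n, 0, 20)))
    pos <- sort(sample.int(160000, 500))
    vv <- GRanges("chr1", IRanges(pos + 1L, pos + 1L))
    mcols(vv) <- DataFrame(id = sprintf("v%d", seq_along(vv)))
    whole <- mutationRateByBin(xs, vv)
    shardA <- vv[seq_along(vv) %% 2 == 0]
    shardB <- vv[seq_along(vv) %% 2 == 1]
    cA <- countOverlaps(granges(xs), shardA)
    cB <- countOverlaps(granges(xs), shardB)
    both <- countOverlaps(granges(xs), vv)
    expect_equal(cA + cB, both)
    expect_equal(whole$value,
                 mutationRateByBin(xs, c(shardA, shardB))$value)
})

test_that("the exploratory breakpoint scan recovers a planted breakpoint", {
    set.seed(21)
    tc <- 1:200
    sc <- pmin(tc, 80) + rnorm(200, 0, 2)
    x <- mkTfcrSet(tc * 5000L, tc * 5000L + 500L, tc = tc, sc = pmax(sc, 0))
    scan <- scanCorrelationBreakpoint(x, c(20, 50, 80, 120))
    expect_equal(attr(scan, "best"), 80)
})
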