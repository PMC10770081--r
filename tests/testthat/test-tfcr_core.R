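test_that("a single TFBS yields a unit-height density peaked at its midpoint", {
    p <- computeDensity(mkTfbs(1000L, "A"), tfcrParams(gridStep = 1))
    expect_equal(max(profileValues(p)), 1, tolerance = 1e-9)
    expect_equal(profilePositions(p)[which.max(profileValues(p))], 1000)
    expect_length(profileValues(computeDensity(mkTfbs(integer(0),
        character(0)))), 0L)
    expect_error(suppressWarnings(
        computeDensity(c(mkTfbs(10L, "A", "chr1"),
                         mkTfbs(10L, "A", "chr2")))),
        "single chromosome")
})

test_that("density between two sites matches the direct kernel sum", {
    # sites at 1000 and 1200, sigma 300: density(1100) = 2*exp(-100^2/(2*300^2))
    p <- computeDensity(mkTfbs(c(1000L, 1200L), c("A", "B")),
                        tfcrParams(gridStep = 1))
    at1100 <- profileValues(p)[profilePositions(p) == 1100]
    expect_equal(at1100, 1.8919189, tolerance = 1e-6)
    expect_equal(at1100, bruteDensity(c(1000, 1200), 1100, 300),
                 tolerance = 1e-9)
})

test_that("summit calling is unimodal under 2*sigma and splits far sites", {
    prm <- tfcrParams(gridStep = 1)
    # two equal kernels 200 bp apart: one summit at the midpoint
    s <- callSummits(computeDensity(mkTfbs(c(1000L, 1200L), c("A", "B")),
                                    prm))
    expect_equal(s, 1100)
    # 2 kb apart: two summits, each at its own site (cross-talk ~2e-10)
    s2 <- callSummits(computeDensity(mkTfbs(c(1000L, 3000L), c("A", "B")),
                                     prm))
    expect_length(s2, 2L)
    expect_true(all(abs(s2 - c(1000, 3000)) <= 1))
    expect_length(callSummits(computeDensity(mkTfbs(integer(0),
        character(0)))), 0L)
})

test_that("plateau summits land on the plateau midpoint", {
    p <- new("DensityProfile", chrom = "chr1", gridStart = 0,
             gridStep = 10L, values = c(0, 1, 2, 2, 2, 1, 0))
    expect_equal(callSummits(p), 30)   # indices 3..5 -> midpoint index 4
    p2 <- new("DensityProfile", chrom = "chr1", gridStart = 0,
              gridStep = 10L, values = c(0, 1, 2, 2, 1, 0))
    expect_equal(callSummits(p2), 20)  # even run: tie toward lower coord
})

test_that("contributor assignment matches the kernel threshold rule", {
    prm <- tfcrParams()
    tfbs <- mkTfbs(c(2000L, 2600L, 2700L), c("A", "B", "C"))
    idx <- assignContributingTfbs(2000, tfbs, prm)
    # 600 bp: exp(-2) ~ 0.135 > 0.1 in; 700 bp: exp(-2.72) ~ 0.066 out
    expect_equal(idx, c(1L, 2L))
})

test_that("window rule adds half the bandwidth beyond the farthest contributor", {
    prm <- tfcrParams()
    expect_equal(computeWindow(5000, 5000, prm), c(4850, 5150))
    expect_equal(computeWindow(5000, c(5000, 5100, 4600), prm),
                 c(4450, 5550))
    # contributor at distance 50 -> half-width 200
    expect_equal(diff(computeWindow(5000, 5050, prm)) / 2, 200)
    expect_error(computeWindow(5000, numeric(0), prm), "empty")
})

test_that("TC counts distinct TF names", {
    expect_equal(computeTc(c("A", "B", "C")), 3L)
    expect_equal(computeTc(c("A", "A", "A")), 1L)
    expect_equal(computeTc(c("A", "A", "B")), 2L)
    expect_error(computeTc(character(0)), "empty")
})

test_that("SC is the mean of overlapping peak scores, 0 when none overlap", {
    w <- mkTfcrSet(1000L, 2000L)
    peaks <- mkPeaks(c(900L, 1500L), c(1100L, 1600L), c(10, 20))
    expect_equal(computeSc(granges(w), peaks), 15)
    # half-open: a peak ending exactly at the window start is excluded
    edge <- mkPeaks(800L, 1000L, 99)
    expect_equal(computeSc(granges(w), edge), 0)
    expect_equal(computeSc(granges(w), mkPeaks(integer(0), integer(0),
                                               numeric(0))), 0)
})

test_that("identifyTfcrs composes summit, window, TC and SC", {
    prm <- tfcrParams(gridStep = 1)
    x <- identifyTfcrs(mkTfbs(1000L, "A"), mkPeaks(900L, 1200L, 8),
                       prm, condition = "tumor")
    expect_length(x, 1L)
    expect_equal(summits(x), 1000L)
    expect_equal(c(start(x) - 1L, end(x)), c(850L, 1150L))
    expect_equal(tfComplexity(x), 1L)
    expect_equal(accessibilityScore(x), 8)
    expect_equal(tfcrCondition(x), "tumor")

    # two distinct TFs 200 bp apart merge into one TFCR with TC = 2
    y <- identifyTfcrs(mkTfbs(c(1000L, 1200L), c("A", "B")),
                       mkPeaks(integer(0), integer(0), numeric(0)),
                       prm, condition = "normal")
    expect_length(y, 1L)
    expect_equal(summits(y), 1100L)
    expect_equal(c(start(y) - 1L, end(y)), c(850L, 1350L))
    expect_equal(tfComplexity(y), 2L)
    expect_equal(accessibilityScore(y), 0)

    # two 5-site clusters 50 kb apart stay separate with per-cluster TC
    set.seed(7)
    mids <- c(round(rnorm(5, 100000, 75)), round(rnorm(5, 150000, 75)))
    tfs <- c(sprintf("T%d", 1:5), sprintf("U%d", 1:3), "U1", "U2")
    z <- identifyTfcrs(mkTfbs(as.integer(mids), tfs),
                       mkPeaks(integer(0), integer(0), numeric(0)),
                       tfcrParams(), condition = "tumor")
    expect_length(z, 2L)
    expect_equal(tfComplexity(z), c(5L, 3L))
    expect_warning(identifyTfcrs(mkTfbs(integer(0), character(0)),
                                 mkPeaks(integer(0), integer(0),
                                         numeric(0))),
                   "no TFBS")
})

test_that("identical inputs give byte-identical TFCR tables", {
    set.seed(11)
    mids <- as.integer(sort(sample.int(50000, 60)) + 10000L)
    tfs <- sample(sprintf("TF%d", 1:8), 60, replace = TRUE)
    peaks <- mkPeaks(c(12000L, 30000L), c(16000L, 33000L), c(4, 9))
    f1 <- tempfile(); f2 <- tempfile()
    writeTfcrTable(identifyTfcrs(mkTfbs(mids, tfs), peaks), f1)
    writeTfcrTable(identifyTfcrs(mkTfbs(mids, tfs), peaks), f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("doubling coordinates and sigma doubles the summit positions", {
    set.seed(3)
    mids <- as.integer(sort(sample(2000:20000, 40)))
    prm1 <- tfcrParams(sigma = 300, gridStep = 1)
    prm2 <- tfcrParams(sigma = 600, gridStep = 2L)
    s1 <- callSummits(computeDensity(mkTfbs(mids, rep("A", 40)), prm1))
    s2 <- callSummits(computeDensity(mkTfbs(2L * mids, rep("A", 40)),
                                     prm2))
    expect_equal(s2, 2 * s1)
})
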