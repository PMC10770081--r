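test_that("gain/lost/stable classification matches the examples", {
    tum <- mkTfcrSet(0L, 100L, condition = "tumor")
    nor <- mkTfcrSet(50L, 150L, condition = "normal")
    d <- classifyDifferential(tum, nor)
    expect_length(gainTfcrs(d), 0L)
    expect_length(lostTfcrs(d), 0L)
    expect_equal(unname(nonoverlapFractions(d)), c(0, 0))

    nor2 <- mkTfcrSet(200L, 300L, condition = "normal")
    d2 <- classifyDifferential(tum, nor2)
    expect_length(gainTfcrs(d2), 1L)
    expect_length(lostTfcrs(d2), 1L)

    # adjacent half-open windows do not overlap
    d3 <- classifyDifferential(mkTfcrSet(0L, 100L),
                               mkTfcrSet(100L, 200L,
                                         condition = "normal"))
    expect_length(gainTfcrs(d3), 1L)

    expect_warning(classifyDifferential(tum, TFCRSet()), "empty")
})

randomSets <- function(n, chroms = c("chr1", "chr2")) {
    chrom <- sample(chroms, n, replace = TRUE)
    s0 <- sample.int(50000, n)
    data.frame(chrom = chrom, start0 = s0,
               end0 = s0 + sample(50:2000, n, replace = TRUE))
}

test_that("classification equals the all-pairs oracle and conserves counts", {
    set.seed(31)
    for (rep in 1:10) {
        tdf <- randomSets(sample(10:60, 1))
        ndf <- randomSets(sample(10:60, 1))
        tum <- mkTfcrSet(tdf$start0, tdf$end0, chrom = tdf$chrom)
        nor <- mkTfcrSet(ndf$start0, ndf$end0, chrom = ndf$chrom,
                         condition = "normal")
        d <- classifyDifferential(tum, nor)
        oracle <- brutePartition(tdf, ndf)
        expect_equal(sort(match(tfcrId(gainTfcrs(d)), tfcrId(tum))),
                     oracle$gain)
        expect_equal(sort(match(tfcrId(lostTfcrs(d)), tfcrId(nor))),
                     oracle$lost)
        expect_equal(length(gainTfcrs(d)) +
                         length(stableTfcrs(d, "tumor")), length(tum))
        expect_equal(length(lostTfcrs(d)) +
                         length(stableTfcrs(d, "normal")), length(nor))
        # swapping condition labels swaps gain<->lost exactly
        dSwap <- classifyDifferential(nor, tum)
        expect_equal(tfcrId(gainTfcrs(dSwap)), tfcrId(lostTfcrs(d)))
        expect_equal(tfcrId(lostTfcrs(dSwap)), tfcrId(gainTfcrs(d)))
    }
})

test_that("gamma is the scaled product of shifted decile bins", {
    x <- mkTfcrSet(c(1000L, 2000L, 3000L), c(1500L, 2500L, 3500L),
                   tc_bin = c(9L, 0L, 9L), sc_bin = c(9L, 0L, 8L))
    expect_equal(gammaScore(x), c(1, 0.01, 0.9))
    # gamma = 1 exactly characterizes TC9 & SC9
    grid <- expand.grid(tc = 0:9, sc = 0:9)
    g <- mkTfcrSet(seq_len(100) * 1000L, seq_len(100) * 1000L + 100L,
                   tc_bin = grid$tc, sc_bin = grid$sc)
    gam <- gammaScore(g)
    expect_true(all(gam > 0 & gam <= 1))
    expect_equal(which(gam == 1), which(grid$tc == 9 & grid$sc == 9))
    expect_error(gammaScore(mkTfcrSet(1L, 100L)), "bins")
})

test_that("gene coverage uses the promoter-extended, strand-aware body", {
    genes <- mkGenes("chr1", c(10000L, 50000L), c(15000L, 55000L),
                     c("+", "-"), id = c("PLUS", "MINUS"))
    # window inside the body
    hit <- mapTfcrsToGenes(mkTfcrSet(11000L, 12000L), genes)
    expect_equal(unname(unlist(hit)), "PLUS")
    # window only in [TSS-2000, TSS) of the + strand gene
    prom <- mapTfcrsToGenes(mkTfcrSet(8500L, 9500L), genes)
    expect_equal(unname(unlist(prom)), "PLUS")
    # 10 kb upstream: not covered
    none <- mapTfcrsToGenes(mkTfcrSet(0L, 500L), genes)
    expect_length(unlist(none), 0L)
    # - strand promoter extends rightward of the body end
    minusProm <- mapTfcrsToGenes(mkTfcrSet(56000L, 56500L), genes)
    expect_equal(unname(unlist(minusProm)), "MINUS")
    minusFar <- mapTfcrsToGenes(mkTfcrSet(47500L, 47900L), genes)
    expect_length(unlist(minusFar), 0L)
})

screenFixture <- function(fpkm) {
    # one TC9/SC9 gain TFCR over GENE1, one TC9/SC8 gain TFCR over GENE2
    gain <- mkTfcrSet(c(10000L, 50000L), c(11000L, 51000L),
                      tc_bin = c(9L, 9L), sc_bin = c(9L, 8L))
    d <- classifyDifferential(gain, mkTfcrSet(90000L, 91000L,
                                              condition = "normal"))
    genes <- mkGenes("chr1", c(10200L, 50200L), c(10800L, 50800L),
                     c("+", "+"), id = c("GENE1", "GENE2"))
    screenCandidates(d, genes, fpkm)
}

test_that("candidate screen applies the TC9/SC9 and FPKM >= 5 rules", {
    out <- screenFixture(c(GENE1 = 7, GENE2 = 100))
    expect_equal(out$gene_id, "GENE1")   # TC9/SC8 coverage never qualifies
    expect_true(out$selected)
    expect_equal(out$max_gamma, 1)

    boundary <- screenFixture(c(GENE1 = 4.9, GENE2 = 1))
    expect_false(boundary$selected)
    expect_false(boundary$passes_expression_filter)
    exact5 <- screenFixture(c(GENE1 = 5, GENE2 = 1))
    expect_true(exact5$selected)

    expect_warning(missing <- screenFixture(c(GENE2 = 9)), "absent")
    expect_false(missing$passes_expression_filter)
})

test_that("screen output is invariant to input row order", {
    set.seed(41)
    n <- 40L
    s0 <- sample.int(500000, n)
    gain <- mkTfcrSet(s0, s0 + 800L,
                      tc_bin = sample(0:9, n, TRUE),
                      sc_bin = sample(0:9, n, TRUE))
    nor <- mkTfcrSet(900000L, 901000L, condition = "normal")
    genes <- mkGenes("chr1", s0 + 100L, s0 + 700L, rep("+", n))
    expr <- setNames(runif(n, 0, 20), mcols(genes)$gene_id)
    d1 <- classifyDifferential(gain, nor)
    perm <- sample(n)
    d2 <- classifyDifferential(gain[perm], nor)
    out1 <- screenCandidates(d1, genes, expr)
    out2 <- screenCandidates(d2, genes[sample(n)], expr[sample(n)])
    expect_equal(out1, out2)
})
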