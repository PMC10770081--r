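fimoHeader <- paste(c("motif_id", "motif_alt_id", "sequence_name",
                      "start", "stop", "strand", "score", "p-value",
                      "q-value", "matched_sequence"), collapse = "\t")

test_that("FIMO hits are converted from 1-based inclusive coordinates", {
    f <- writeTsv(c(fimoHeader,
                    "MA0001\tTP53\tchr1\t101\t110\t+\t12.3\t1e-5\t0.01\tACGTACGTAC",
                    "MA0002\t\tchr1\t51\t60\t-\t3.1\t1e-4\t0.2\tACGTACGTAC"))
    hits <- readFimoHits(f)
    expect_length(hits, 2L)
    # length preservation: stop - start + 1 in file == width internally
    expect_equal(width(hits), c(10L, 10L))
    tp53 <- hits[mcols(hits)$tf_name == "TP53"]
    expect_equal(start(tp53) - 1L, 100L)   # 0-based start
    expect_equal(end(tp53), 110L)          # half-open end
    expect_equal(mcols(tp53)$midpoint, 105L)
    # tf_name falls back to motif_id when motif_alt_id is empty
    expect_equal(mcols(hits)$tf_name[1L], "MA0002")  # sorted by coordinate
    # records come back sorted by (chrom, start)
    expect_true(!is.unsorted(start(hits)))
})

test_that("FIMO reader handles empty files, bad rows, and the q-value filter", {
    expect_length(readFimoHits(writeTsv(c("# comment", fimoHeader))), 0L)
    bad <- writeTsv(c(fimoHeader,
                      "MA0001\tTP53\tchr1\t101\t110\t+\t1\t1e-5\t0.01\tA",
                      "MA0001\tTP53\tchr1\t110\t101\t+\t1\t1e-5\t0.01\tA"))
    expect_error(readFimoHits(bad), "line 3")
    expect_error(readFimoHits(writeTsv(c(fimoHeader,
        "MA0001\tTP53\tchr1\tx\t110\t+\t1\t1e-5\t0.01\tA"))), "line 2")
    f <- writeTsv(c(fimoHeader,
                    "MA0001\tA\tchr1\t101\t110\t+\t1\t1e-5\t0.005\tA",
                    "MA0001\tB\tchr1\t201\t210\t+\t1\t1e-5\t0.5\tA"))
    expect_equal(mcols(readFimoHits(f, maxQvalue = 0.05))$tf_name, "A")
    # chromosome aliasing is explicit, never implicit
    aliased <- readFimoHits(f, chromAlias = c(chr1 = "1"))
    expect_equal(as.character(seqnames(aliased)), c("1", "1"))
})

test_that("narrowPeak scores come from signalValue, BED5 from column 5", {
    np <- writeTsv("chr1\t100\t600\tp1\t800\t.\t12.5\t-1\t-1\t250")
    peaks <- readNarrowPeak(np, source = "ATAC", condition = "tumor")
    expect_equal(mcols(peaks)$score, 12.5)
    expect_equal(c(start(peaks) - 1L, end(peaks)), c(100L, 600L))
    expect_equal(mcols(peaks)$source, "ATAC")
    # scoreColumn override uses the capped BED score instead
    expect_equal(mcols(readNarrowPeak(np, scoreColumn = "score"))$score,
                 800)
    bed5 <- writeTsv("chr2\t0\t200\tp2\t33")
    expect_equal(mcols(readNarrowPeak(bed5, "DNase", "normal"))$score, 33)
    expect_error(readNarrowPeak(writeTsv("chr1\t600\t100\tp\t5")),
                 "line 1")
    expect_error(readNarrowPeak(writeTsv("chr1\t0\t100\tp\t-2")),
                 "line 1")
})

test_that("BED-like gene reader derives the TSS from the strand", {
    f <- writeTsv(c("chr1\t1000\t5000\tGENE1\t0\t+",
                    "chr1\t1000\t5000\tGENE2\t0\t-"))
    genes <- readBedLike(f, kind = "gene")
    expect_equal(mcols(genes)$tss, c(1000L, 4999L))
    expect_equal(mcols(genes)$gene_id, c("GENE1", "GENE2"))
    expect_error(readBedLike(writeTsv("chr1\t0\t10\tG\t0\t."), "gene"),
                 "strand")
})

test_that("variant and element readers type their records", {
    v <- readBedLike(writeTsv(c("chr1\t99\t100\trs1", "chr2\t5\t6\trs2")),
                     kind = "variant")
    expect_equal(width(v), c(1L, 1L))
    expect_equal(start(v) - 1L, c(99L, 5L))
    vcf <- writeTsv(c("##fileformat=VCFv4.2",
                      "#CHROM\tPOS\tID\tREF\tALT",
                      "chr1\t100\trs1\tA\tG"), ext = ".vcf")
    expect_equal(start(readBedLike(vcf, "variant")) - 1L, 99L)

    e <- readBedLike(writeTsv("chr1\t10\t60\tpromoter"), "element")
    expect_equal(mcols(e)$element_class, "promoter")
    expect_warning(
        e2 <- readBedLike(writeTsv("chr1\t10\t60\tsilencer"), "element"),
        "other")
    expect_equal(mcols(e2)$element_class, "other")
})

test_that("expression table rejects duplicates and negative FPKM", {
    expect_equal(readExpressionTable(writeTsv("GENE1\t7.2")),
                 c(GENE1 = 7.2))
    withHeader <- writeTsv(c("gene_id\tfpkm", "G1\t1.5", "G2\t0"))
    expect_equal(readExpressionTable(withHeader), c(G1 = 1.5, G2 = 0))
    expect_error(readExpressionTable(writeTsv(c("G1\t1", "G1\t2"))),
                 "duplicate")
    expect_error(readExpressionTable(writeTsv("GENE2\t-1")),
                 "nonnegative")
})

test_that("the TFCR table round-trips through write/read", {
    set.seed(42)
    n <- 100L
    s0 <- sort(sample.int(1e6, n)) * 2L
    x <- mkTfcrSet(s0, s0 + sample(100:900, n, replace = TRUE),
                   tc = sample(1:40, n, replace = TRUE),
                   sc = round(runif(n, 0, 60), 6),
                   tc_bin = sample(0:9, n, replace = TRUE),
                   sc_bin = sample(0:9, n, replace = TRUE))
    f <- tempfile()
    writeTfcrTable(x, f)
    y <- readTfcrTable(f)
    expect_equal(as.character(seqnames(y)), as.character(seqnames(x)))
    expect_equal(start(y), start(x))
    expect_equal(end(y), end(x))
    expect_identical(as.data.frame(mcols(y)), as.data.frame(mcols(x)))
    # header-only file for an empty set; NA bins survive the round trip
    writeTfcrTable(TFCRSet(), f)
    expect_equal(readLines(f), paste(c("#chrom", "start", "end", "tfcr_id",
        "summit", "tc", "sc", "tc_bin", "sc_bin", "condition",
        "n_contrib"), collapse = "\t"))
    expect_length(readTfcrTable(f), 0L)
    z <- mkTfcrSet(100L, 400L)          # bins unassigned
    writeTfcrTable(z, f)
    expect_true(grepl("\tNA\tNA\t", readLines(f)[2L]))
    expect_true(is.na(decileBin(readTfcrTable(f), "tc")))
})
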