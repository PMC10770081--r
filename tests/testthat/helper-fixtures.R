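# Fixture builders shared across test files.  Everything is generated in
# code; nothing is read from stored data.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

# TFBS GRanges with the given 0-based midpoints (width-10 sites).
mkTfbs <- function(mids, tf, chrom = "chr1") {
    gr <- GRanges(rep(chrom, length.out = length(mids)),
                  IRanges(start = mids - 4L, end = mids + 5L))
    mcols(gr) <- DataFrame(tf_name = tf)
    gr
}

mkPeaks <- function(start0, end0, score, chrom = "chr1",
                    condition = "tumor") {
    gr <- GRanges(rep(chrom, length.out = length(start0)),
                  IRanges(start0 + 1L, end0))
    mcols(gr) <- DataFrame(score = score,
                           source = rep(if (condition == "tumor") "ATAC"
                                        else "DNase", length(gr)),
                           condition = rep(condition, length(gr)))
    gr
}

# Hand-built TFCRSet from 0-based half-open windows.
mkTfcrSet <- function(start0, end0, chrom = "chr1",
                      summit = (start0 + end0) %/% 2L,
                      tc = rep(1L, length(start0)),
                      sc = rep(0, length(start0)),
                      condition = "tumor",
                      tc_bin = rep(NA_integer_, length(start0)),
                      sc_bin = rep(NA_integer_, length(start0)),
                      idPrefix = condition) {
    gr <- GRanges(rep(chrom, length.out = length(start0)),
                  IRanges(start0 + 1L, end0))
    mcols(gr) <- DataFrame(
        tfcr_id = sprintf("%s_fx%04d", idPrefix, seq_along(gr)),
        summit = as.integer(summit),
        tc = as.integer(tc), sc = as.numeric(sc),
        tc_bin = as.integer(tc_bin), sc_bin = as.integer(sc_bin),
        condition = rep(condition, length.out = length(gr)),
        n_contrib = rep(1L, length(gr)))
    TFCRSet(gr)
}

mkGenes <- function(chrom, start0, end0, strand, id = NULL) {
    if (is.null(id)) id <- sprintf("G%03d", seq_along(start0))
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
    strand(gr) <- strand
    tss <- ifelse(strand == "+", start0, end0 - 1L)
    mcols(gr) <- DataFrame(gene_id = id, symbol = id,
                           tss = as.integer(tss))
    gr
}

writeTsv <- function(lines, ext = ".tsv") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}

# Cached default synthetic run shared by the heavier tests.
.runCache <- new.env(parent = emptyenv())
defaultRun <- function(seed = 17) {
    key <- sprintf("run_%d", seed)
    if (!exists(key, envir = .runCache)) {
        land <- generateLandscape(syntheticConfig(seed = seed))
        tumor <- assignDecileBins(
            identifyTfcrs(land$tfbsTumor, land$peaksTumor, tfcrParams(),
                          condition = "tumor"))
        normal <- assignDecileBins(
            identifyTfcrs(land$tfbsNormal, land$peaksNormal, tfcrParams(),
                          condition = "normal"))
        assign(key, list(land = land, tumor = tumor, normal = normal),
               envir = .runCache)
    }
    get(key, envir = .runCache)
}
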