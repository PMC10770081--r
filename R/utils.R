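# Internal helpers shared across modules.

# GRanges from 0-based half-open coordinates.
.gr0 <- function(chrom, start0, end0, ...) {
    GRanges(chrom, IRanges(start = start0 + 1, end = end0), ...)
}

# 0-based half-open coordinates of a GRanges.
.start0 <- function(gr) start(gr) - 1L
.end0 <- function(gr) end(gr)

# Make two GRanges comparable in findOverlaps without seqlevel warnings.
.harmonize <- function(a, b) {
    lev <- union(seqlevels(a), seqlevels(b))
    seqlevels(a) <- lev
    seqlevels(b) <- lev
    list(a, b)
}

# Shortest decimal string that round-trips through as.numeric (for lossless
# text serialization of scores).
.fmtNum <- function(x) {
    vapply(x, function(v) {
        if (is.na(v)) return("NA")
        for (d in c(15L, 16L, 17L)) {
            s <- sprintf("%.*g", d, v)
            if (as.numeric(s) == v) return(s)
        }
        s
    }, character(1))
}

# Deterministic chromosome ordering (plain lexicographic).
.chromLevels <- function(ch) sort(unique(as.character(ch)))

# Rank with deterministic tie-break by (chrom, position): rank 1 is the
# smallest value; ties are ordered along the genome.
.tiedRank <- function(values, chrom, pos) {
    o <- order(values,
               match(as.character(chrom), .chromLevels(chrom)),
               pos)
    r <- integer(length(values))
    r[o] <- seq_along(values)
    r
}

.stopIfMissingBins <- function(x, what) {
    if (any(is.na(decileBin(x, "tc"))) || any(is.na(decileBin(x, "sc"))))
        stop(what, " requires TC and SC decile bins; ",
             "run assignDecileBins() first", call. = FALSE)
    invisible(TRUE)
}
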