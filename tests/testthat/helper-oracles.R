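# Independent brute-force oracles.  These deliberately avoid the package's
# code paths: exact kernel sums by direct evaluation, local maxima by a
# linear scan, interval overlap by all-pairs comparison.

# Exact (untruncated) sum of unit-height Gaussians at positions xs.
bruteDensity <- function(mids, xs, sigma) {
    v <- numeric(length(xs))
    for (m in mids) v <- v + exp(-(xs - m)^2 / (2 * sigma^2))
    v
}

# Plateau-aware local maxima by linear scan; out-of-range neighbors count
# as -Inf, plateau reported at its midpoint (ties toward the lower index).
bruteLocalMaxima <- function(xs, v) {
    out <- numeric(0)
    n <- length(v)
    i <- 1L
    while (i <= n) {
        j <- i
        while (j < n && v[j + 1L] == v[i]) j <- j + 1L
        leftLower <- i == 1L || v[i - 1L] < v[i]
        rightLower <- j == n || v[j + 1L] < v[i]
        if (leftLower && rightLower) out <- c(out, xs[(i + j) %/% 2L])
        i <- j + 1L
    }
    out
}

# Half-open interval overlap on 0-based coordinates.
bruteOverlaps <- function(chrom1, s1, e1, chrom2, s2, e2) {
    chrom1 == chrom2 & s1 < e2 & s2 < e1
}

# All-pairs gain/lost/stable partition of two window sets given as
# data.frames with columns chrom, start0, end0.
brutePartition <- function(tumor, normal) {
    tHit <- logical(nrow(tumor))
    nHit <- logical(nrow(normal))
    for (i in seq_len(nrow(tumor))) {
        for (j in seq_len(nrow(normal))) {
            if (bruteOverlaps(tumor$chrom[i], tumor$start0[i],
                              tumor$end0[i], normal$chrom[j],
                              normal$start0[j], normal$end0[j])) {
                tHit[i] <- TRUE
                nHit[j] <- TRUE
            }
        }
    }
    list(gain = which(!tHit), stable_tumor = which(tHit),
         lost = which(!nHit), stable_normal = which(nHit))
}

# Mean score of peaks overlapping a window, 0 if none (all 0-based).
bruteSc <- function(ws, we, peakS, peakE, peakScore) {
    hit <- peakS < we & ws < peakE
    if (!any(hit)) 0 else mean(peakScore[hit])
}

# Textbook two-pass Pearson correlation.
pearsonTwoPass <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
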