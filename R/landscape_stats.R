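# Decile binning of TC/SC, the TC-SC correlation breakpoint analysis, and
# the per-bin enrichment diagnostics (expression, regulatory elements,
# mutation rate).

#' Assign decile bins to TC and/or SC
#'
#' The default binning is rank-based (equal frequency): with `n` TFCRs the
#' TFCR of rank `r` (ascending in the axis value, ties broken
#' deterministically by chromosome and summit coordinate) receives bin
#' `floor(10 * (r - 1) / n)`, so bin 9 holds the top decile, every bin is
#' populated once `n >= 10`, and per-bin counts differ by at most one when
#' values are distinct.  `method = "value"` instead cuts the value range
#' into ten equal-width intervals.
#'
#' Binning is intended to be performed within one condition at a time
#' (tumor TFCRs against tumor TFCRs).
#'
#' @param x a [TFCRSet-class].
#' @param axis axes to bin: any subset of `c("tc", "sc")` (default both).
#' @param method `"rank"` (equal frequency, default) or `"value"`
#'   (equal width).
#' @return `x` with the corresponding `tc_bin` / `sc_bin` columns filled.
#' @examples
#' # 10 TFCRs with SC = 1..10 receive sc_bin = 0..9
#' @export
assignDecileBins <- function(x, axis = c("tc", "sc"),
                             method = c("rank", "value")) {
    stopifnot(is(x, "TFCRSet"))
    axis <- match.arg(axis, c("tc", "sc"), several.ok = TRUE)
    method <- match.arg(method)
    if (!length(x)) return(x)
    n <- length(x)
    for (ax in axis) {
        v <- mcols(x)[[ax]]
        bin <- if (method == "rank") {
            r <- .tiedRank(v, seqnames(x), summits(x))
            as.integer((10L * (r - 1L)) %/% n)
        } else {
            rng <- range(v)
            if (rng[1L] == rng[2L]) rep(0L, n)
            else pmin(9L, as.integer(floor(10 * (v - rng[1L]) /
                                           (rng[2L] - rng[1L]))))
        }
        mcols(x)[[paste0(ax, "_bin")]] <- bin
    }
    x
}

#' TC-SC correlation split at a TC breakpoint
#'
#' Computes the Pearson correlation of TC and SC separately in the strata
#' `TC < threshold` and `TC >= threshold`.  In the published landscape the
#' correlation is positive below the breakpoint (170 in tumor, 50 in
#' normal) and disappears above it, consistent with accessibility
#' saturating as binding sites accumulate.  Strata with fewer than 3 TFCRs
#' or zero variance report `NA` with a reason code instead of a fabricated
#' coefficient.
#'
#' @param x a [TFCRSet-class] with TC and SC populated.
#' @param threshold TC cutoff separating the strata.
#' @return a list of class `CorrelationSplit` with elements `threshold`,
#'   `r_low`, `p_low`, `n_low`, `reason_low` and the `_high` counterparts
#'   (`reason_*` is `NA`, `"too_few"` or `"zero_variance"`).
#' @export
tcScCorrelationSplit <- function(x, threshold) {
    stopifnot(is(x, "TFCRSet"), length(threshold) == 1L)
    if (!length(x)) stop("cannot analyze an empty TFCRSet")
    tc <- tfComplexity(x)
    sc <- accessibilityScore(x)
    one <- function(idx) {
        n <- length(idx)
        if (n < 3L)
            return(list(r = NA_real_, p = NA_real_, n = n,
                        reason = "too_few"))
        if (sd(tc[idx]) == 0 || sd(sc[idx]) == 0)
            return(list(r = NA_real_, p = NA_real_, n = n,
                        reason = "zero_variance"))
        ct <- cor.test(tc[idx], sc[idx], method = "pearson")
        list(r = unname(ct$estimate), p = ct$p.value, n = n,
             reason = NA_character_)
    }
    lo <- one(which(tc < threshold))
    hi <- one(which(tc >= threshold))
    structure(list(threshold = threshold,
                   r_low = lo$r, p_low = lo$p, n_low = lo$n,
                   reason_low = lo$reason,
                   r_high = hi$r, p_high = hi$p, n_high = hi$n,
                   reason_high = hi$reason),
              class = "CorrelationSplit")
}

#' @export
print.CorrelationSplit <- function(x, ...) {
    fmt <- function(r, p, n, reason) {
        if (is.na(r)) sprintf("undefined (%s, n=%d)", reason, n)
        else sprintf("r=%.3f (p=%.3g, n=%d)", r, p, n)
    }
    cat("TC-SC correlation split at TC =", x$threshold, "\n",
        " TC <  threshold:", fmt(x$r_low, x$p_low, x$n_low, x$reason_low),
        "\n",
        " TC >= threshold:", fmt(x$r_high, x$p_high, x$n_high,
                                 x$reason_high), "\n")
    invisible(x)
}

#' Scan for the TC breakpoint maximizing the correlation contrast
#'
#' Exploratory helper (not part of the published procedure): evaluates
#' [tcScCorrelationSplit()] over candidate thresholds and returns the one
#' maximizing `|r_low - r_high|` among thresholds where both strata are
#' defined.
#'
#' @param x a [TFCRSet-class].
#' @param thresholds numeric vector of candidate TC cutoffs.
#' @return a data.frame of thresholds and stratum correlations, with the
#'   selected threshold in attribute `"best"`.
#' @export
scanCorrelationBreakpoint <- function(x, thresholds) {
    rows <- lapply(thresholds, function(th) {
        s <- tcScCorrelationSplit(x, th)
        data.frame(threshold = th, r_low = s$r_low, r_high = s$r_high,
                   n_low = s$n_low, n_high = s$n_high)
    })
    out <- do.call(rbind, rows)
    contrast <- abs(out$r_low - out$r_high)
    best <- if (all(is.na(contrast))) NA_real_
            else out$threshold[which.max(contrast)]
    attr(out, "best") <- best
    out
}

.binSummaryFrame <- function(x, axis, value, metric, extra = NULL) {
    bins <- decileBin(x, axis)
    n <- tabulate(bins + 1L, nbins = 10L)
    df <- data.frame(axis = toupper(axis), bin = 0:9, n_tfcr = n,
                     metric = metric, value = value,
                     stringsAsFactors = FALSE)
    if (!is.null(extra)) df <- cbind(df[1:3], extra, df[4:5])
    df
}

.perBinProportion <- function(x, axis, flag) {
    bins <- decileBin(x, axis)
    vapply(0:9, function(b) {
        idx <- which(bins == b)
        if (!length(idx)) return(NA_real_)
        mean(flag[idx])
    }, numeric(1))
}

#' Proportion of TFCRs covering a highly expressed gene, per decile bin
#'
#' A TFCR covers a gene when its window overlaps the promoter-extended gene
#' body (see [mapTfcrsToGenes()]).  "Highly expressed" defaults to the top
#' quartile of genes with FPKM > 0; pass a numeric FPKM threshold to
#' override.
#'
#' @param x a [TFCRSet-class] with bins assigned.
#' @param genes gene `GRanges` (as from `readBedLike(kind = "gene")`).
#' @param expression named FPKM vector (as from [readExpressionTable()]).
#' @param highExprCutoff numeric FPKM cutoff, or `NULL` for the top-quartile
#'   default.
#' @param promoterUpstream upstream promoter extension in bp (default 2000).
#' @return data.frame with columns axis, bin, n_tfcr, metric, value; value
#'   is the per-bin proportion (NA for empty bins).
#' @export
expressionEnrichmentByBin <- function(x, genes, expression,
                                      highExprCutoff = NULL,
                                      promoterUpstream = 2000) {
    stopifnot(is(x, "TFCRSet"))
    .stopIfMissingBins(x, "expressionEnrichmentByBin()")
    if (!length(genes)) {
        warning("no genes supplied; all proportions are 0", call. = FALSE)
        covHigh <- rep(FALSE, length(x))
    } else {
        fpkm <- expression[match(mcols(genes)$gene_id, names(expression))]
        fpkm[is.na(fpkm)] <- 0
        if (is.null(highExprCutoff)) {
            pos <- fpkm[fpkm > 0]
            highExprCutoff <- if (length(pos)) unname(quantile(pos, 0.75))
                              else Inf
        }
        high <- genes[fpkm >= highExprCutoff]
        covHigh <- if (length(high)) {
            ext <- .extendUpstream(high, promoterUpstream)
            hx <- .harmonize(granges(x), ext)
            overlapsAny(hx[[1L]], hx[[2L]])
        } else rep(FALSE, length(x))
    }
    do.call(rbind, lapply(c("tc", "sc"), function(ax)
        .binSummaryFrame(x, ax, .perBinProportion(x, ax, covHigh),
                         "high_expr_proportion")))
}

#' Proportion of TFCRs overlapping regulatory elements, per decile bin
#'
#' @param x a [TFCRSet-class] with bins assigned.
#' @param elements element `GRanges` with an `element_class` column (as
#'   from `readBedLike(kind = "element")`).
#' @return data.frame with one row per axis, bin and element class (plus a
#'   `"pooled"` class over all elements); `value` is the proportion of the
#'   bin's TFCRs whose window overlaps at least one such element.
#' @export
elementOverlapByBin <- function(x, elements) {
    stopifnot(is(x, "TFCRSet"))
    .stopIfMissingBins(x, "elementOverlapByBin()")
    classes <- c("pooled",
                 if (length(elements))
                     sort(unique(mcols(elements)$element_class)))
    do.call(rbind, lapply(classes, function(cl) {
        sub <- if (cl == "pooled") elements
               else elements[mcols(elements)$element_class == cl]
        flag <- if (length(sub)) {
            hx <- .harmonize(granges(x), granges(sub))
            overlapsAny(hx[[1L]], hx[[2L]])
        } else rep(FALSE, length(x))
        do.call(rbind, lapply(c("tc", "sc"), function(ax)
            .binSummaryFrame(x, ax, .perBinProportion(x, ax, flag),
                             "element_proportion",
                             extra = data.frame(element_class = cl))))
    }))
}

#' Mutation rate inside TFCR windows, per decile bin
#'
#' Rate = (variants falling in the bin's windows) / (total window length)
#' * 1000, in variants per kb.  Each TFCR window is counted independently
#' (overlapping windows are not merged), so the statistic is invariant to
#' sharding the variant file.
#'
#' @param x a [TFCRSet-class] with bins assigned.
#' @param variants width-1 variant `GRanges` (as from
#'   `readBedLike(kind = "variant")`).
#' @return data.frame with columns axis, bin, n_tfcr, metric, value.
#' @export
mutationRateByBin <- function(x, variants) {
    stopifnot(is(x, "TFCRSet"))
    .stopIfMissingBins(x, "mutationRateByBin()")
    counts <- if (length(variants)) {
        hx <- .harmonize(granges(x), granges(variants))
        countOverlaps(hx[[1L]], hx[[2L]])
    } else rep(0L, length(x))
    widths <- width(x)   # closed-interval width == half-open length
    do.call(rbind, lapply(c("tc", "sc"), function(ax) {
        bins <- decileBin(x, ax)
        rate <- vapply(0:9, function(b) {
            idx <- which(bins == b)
            if (!length(idx)) return(NA_real_)
            1000 * sum(counts[idx]) / sum(widths[idx])
        }, numeric(1))
        .binSummaryFrame(x, ax, rate, "mutation_rate_per_kb")
    }))
}
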