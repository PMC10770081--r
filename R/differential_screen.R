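# Tumor vs normal classification of TFCRs, the carcinogenic-potential
# score over TC/SC deciles, gene coverage, and the candidate-gene screen.

#' Classify tumor vs normal TFCRs into gain / lost / stable
#'
#' Two TFCRs overlap when their windows share at least one base pair
#' (half-open intersection nonempty).  Gain-TFCRs are tumor TFCRs with no
#' overlapping normal TFCR; lost-TFCRs are normal TFCRs with no
#' overlapping tumor TFCR; the remaining members of each side are stable.
#' By construction `gain + stableTumor` partitions the tumor set and
#' `lost + stableNormal` the normal set, so e.g. the gain count equals the
#' tumor non-overlap fraction times the tumor count.
#'
#' @param tumor,normal [TFCRSet-class] objects with windows computed.
#' @param minOverlapFrac minimum fraction of the smaller window that must
#'   be shared for an overlap to count (default 0: any shared bp).
#' @return a [DifferentialTfcrs-class] object.  An empty input side yields
#'   a valid degenerate result (everything gain or lost) with a warning.
#' @export
classifyDifferential <- function(tumor, normal, minOverlapFrac = 0) {
    stopifnot(is(tumor, "TFCRSet"), is(normal, "TFCRSet"))
    if (!length(tumor) || !length(normal))
        warning("one side is empty; every TFCR on the other side is ",
                "classified as condition-unique", call. = FALSE)
    hx <- .harmonize(granges(tumor), granges(normal))
    hits <- findOverlaps(hx[[1L]], hx[[2L]])
    if (minOverlapFrac > 0 && length(hits)) {
        ov <- width(pintersect(hx[[1L]][queryHits(hits)],
                               hx[[2L]][subjectHits(hits)]))
        ref <- pmin(width(tumor)[queryHits(hits)],
                    width(normal)[subjectHits(hits)])
        hits <- hits[ov / ref >= minOverlapFrac]
    }
    tHit <- unique(queryHits(hits))
    nHit <- unique(subjectHits(hits))
    tAll <- seq_along(tumor)
    nAll <- seq_along(normal)
    new("DifferentialTfcrs",
        gain = tumor[setdiff(tAll, tHit)],
        stableTumor = tumor[sort(tHit)],
        lost = normal[setdiff(nAll, nHit)],
        stableNormal = normal[sort(nHit)],
        nonoverlapTumor = if (length(tumor))
            1 - length(tHit) / length(tumor) else NaN,
        nonoverlapNormal = if (length(normal))
            1 - length(nHit) / length(normal) else NaN)
}

#' Carcinogenic-potential score of TFCRs
#'
#' The default score is `gamma = (tc_bin + 1) * (sc_bin + 1) / 100` over
#' the decile bins: monotone non-decreasing in each bin, with maximum 1
#' attained exactly when both bins equal 9, so selecting `gamma == 1`
#' reproduces the operational "TC9 and SC9" rule.  The exact weighting used
#' in the original screen is unpublished; this is the simplest monotone
#' score with the right maximizer, and [screenCandidates()] accepts any
#' replacement via its `gammaFun` argument.
#'
#' @param x a [TFCRSet-class] with decile bins assigned.
#' @return numeric vector of scores in (0, 1].
#' @examples
#' # tc_bin = 9, sc_bin = 9  ->  gamma = 1
#' # tc_bin = 0, sc_bin = 0  ->  gamma = 0.01
#' @export
gammaScore <- function(x) {
    stopifnot(is(x, "TFCRSet"))
    .stopIfMissingBins(x, "gammaScore()")
    (decileBin(x, "tc") + 1) * (decileBin(x, "sc") + 1) / 100
}

# Promoter-extended gene interval: the gene body extended upstream of the
# TSS by `upstream` bp, strand-aware.
.extendUpstream <- function(genes, upstream) {
    minus <- as.character(strand(genes)) == "-"
    s <- ifelse(minus, start(genes),
                pmax(1L, start(genes) - as.integer(upstream)))
    e <- ifelse(minus, end(genes) + as.integer(upstream), end(genes))
    GRanges(seqnames(genes), IRanges(s, e))
}

#' Map TFCRs to covered genes
#'
#' A gene is covered by a TFCR when the TFCR window overlaps the gene body
#' extended upstream of the TSS by `promoterUpstream` bp (strand-aware),
#' the common regulatory-genomics coverage convention.
#'
#' @param x a [TFCRSet-class].
#' @param genes gene `GRanges` with `gene_id` and strand.
#' @param promoterUpstream upstream extension in bp (default 2000).
#' @return a `CharacterList` (one element per TFCR, named by `tfcr_id`) of
#'   covered gene ids.
#' @export
mapTfcrsToGenes <- function(x, genes, promoterUpstream = 2000) {
    stopifnot(is(x, "TFCRSet"))
    out <- setNames(vector("list", length(x)), tfcrId(x))
    if (length(x) && length(genes)) {
        ext <- .extendUpstream(genes, promoterUpstream)
        hx <- .harmonize(granges(x), ext)
        hits <- findOverlaps(hx[[1L]], hx[[2L]])
        ids <- mcols(genes)$gene_id
        for (q in seq_along(x)) out[[q]] <- character(0)
        if (length(hits)) {
            sp <- split(ids[subjectHits(hits)],
                        factor(queryHits(hits), levels = seq_along(x)))
            out <- setNames(lapply(sp, unique), tfcrId(x))
        }
    } else {
        out <- setNames(rep(list(character(0)), length(x)), tfcrId(x))
    }
    CharacterList(out)
}

#' Screen for candidate genes under top-decile gain-TFCRs
#'
#' Candidate genes are the genes covered by at least one gain-TFCR in both
#' the top TC decile and the top SC decile (equivalently, with the default
#' score, `gamma == 1`).  Candidates are then filtered on expression:
#' `selected` requires FPKM >= `fpkmMin` (default 5).  Genes absent from
#' the expression table are retained with `passes_expression_filter =
#' FALSE` and a warning.
#'
#' @param diff a [DifferentialTfcrs-class] whose gain TFCRs carry decile
#'   bins (assign bins on the full tumor set before classifying).
#' @param genes gene `GRanges`.
#' @param expression named FPKM vector.
#' @param fpkmMin expression threshold (default 5).
#' @param promoterUpstream coverage rule extension (default 2000 bp).
#' @param gammaFun scoring function taking a `TFCRSet` and returning one
#'   score per TFCR (default [gammaScore()]).
#' @return data.frame sorted by decreasing max supporting score then gene
#'   id, with columns `gene_id`, `symbol`, `n_supporting_gain_tfcrs`,
#'   `supporting_tfcr_ids`, `max_gamma`, `fpkm`,
#'   `passes_expression_filter`, `selected`.
#' @export
screenCandidates <- function(diff, genes, expression, fpkmMin = 5,
                             promoterUpstream = 2000,
                             gammaFun = gammaScore) {
    stopifnot(is(diff, "DifferentialTfcrs"))
    gain <- gainTfcrs(diff)
    empty <- data.frame(gene_id = character(0), symbol = character(0),
                        n_supporting_gain_tfcrs = integer(0),
                        supporting_tfcr_ids = character(0),
                        max_gamma = numeric(0), fpkm = numeric(0),
                        passes_expression_filter = logical(0),
                        selected = logical(0), stringsAsFactors = FALSE)
    if (!length(gain) || !length(genes)) return(empty)
    .stopIfMissingBins(gain, "screenCandidates()")

    top <- gain[decileBin(gain, "tc") == 9L & decileBin(gain, "sc") == 9L]
    if (!length(top)) return(empty)
    topGenes <- sort(unique(unlist(mapTfcrsToGenes(top, genes,
                                                   promoterUpstream))))
    if (!length(topGenes)) return(empty)

    covered <- mapTfcrsToGenes(gain, genes, promoterUpstream)
    gamma <- gammaFun(gain)
    rows <- lapply(topGenes, function(g) {
        sup <- which(vapply(covered, function(ids) g %in% ids, logical(1)))
        fp <- unname(expression[g])
        data.frame(gene_id = g,
                   symbol = mcols(genes)$symbol[
                       match(g, mcols(genes)$gene_id)],
                   n_supporting_gain_tfcrs = length(sup),
                   supporting_tfcr_ids = paste(sort(tfcrId(gain)[sup]),
                                               collapse = ","),
                   max_gamma = max(gamma[sup]),
                   fpkm = if (length(fp)) fp else NA_real_,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (any(is.na(out$fpkm)))
        warning("gene(s) absent from the expression table: ",
                paste(out$gene_id[is.na(out$fpkm)], collapse = ", "),
                call. = FALSE)
    out$passes_expression_filter <- !is.na(out$fpkm) & out$fpkm >= fpkmMin
    out$selected <- out$passes_expression_filter
    out <- out[order(-out$max_gamma, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
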