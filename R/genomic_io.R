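# Readers and writers for the on-disk formats the pipeline touches.  All
# readers convert to the internal GRanges representation at the boundary;
# coordinate-bearing text formats (FIMO = 1-based inclusive, BED/narrowPeak
# = 0-based half-open) are normalized here and nowhere else.

# Split a text file into data lines, keeping original line numbers.
.dataLines <- function(path, comment = "^#", dropTrack = FALSE) {
    lines <- readLines(path)
    keep <- !grepl(comment, lines) & nzchar(trimws(lines))
    if (dropTrack)
        keep <- keep & !grepl("^(track|browser)\\b", lines)
    list(lines = lines[keep], lineno = which(keep))
}

.parseErr <- function(lineno, what) {
    stop(sprintf("parse error at line %d: %s", lineno, what), call. = FALSE)
}

.field <- function(parts, k) {
    vapply(parts, function(p) if (length(p) >= k) p[[k]] else NA_character_,
           character(1))
}

.asInt <- function(x, lineno, what) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
        .parseErr(lineno[bad[1L]], paste0("non-integer ", what, " '",
                                          x[bad[1L]], "'"))
    v
}

.asNum <- function(x, lineno, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & x != "NA")
    if (length(bad))
        .parseErr(lineno[bad[1L]], paste0("non-numeric ", what, " '",
                                          x[bad[1L]], "'"))
    v
}

#' Read FIMO motif-scan hits as TFBS records
#'
#' Parses tab-separated FIMO output (columns `motif_id`, `motif_alt_id`,
#' `sequence_name`, `start`, `stop`, `strand`, `score`, `p-value`,
#' `q-value`, `matched_sequence`; 1-based inclusive coordinates) into a
#' `GRanges` of transcription factor binding sites.  Coordinates are
#' converted to the internal convention so that interval length is
#' preserved (`stop - start + 1` in the file equals the width).  The TF
#' name is taken from `motif_alt_id` when present, else `motif_id`.  The
#' site `midpoint` metadata column (0-based, `floor((start0 + end0)/2)`) is
#' the kernel center used by [computeDensity()].
#'
#' @param path path to a FIMO TSV file; `#` comment lines and the header
#'   are skipped.
#' @param maxQvalue optional q-value cutoff; hits with a larger q-value are
#'   dropped (default `NULL`: keep every hit, since the upstream scan
#'   threshold is the caller's choice).
#' @param chromAlias optional named character vector mapping sequence names
#'   in the file to the chromosome names used elsewhere (names = file
#'   spelling).  Chromosome names are otherwise matched as exact strings.
#' @return `GRanges` sorted by (chrom, start) with metadata columns
#'   `tf_name`, `motif_id`, `score`, `midpoint`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("motif_id\tmotif_alt_id\tsequence_name\tstart\tstop\tstrand\tscore\tp-value\tq-value\tmatched_sequence",
#'              "MA0001\tTP53\tchr1\t101\t110\t+\t12.3\t1e-5\t0.01\tACGTACGTAC"),
#'            f)
#' readFimoHits(f)
#' @export
readFimoHits <- function(path, maxQvalue = NULL, chromAlias = NULL) {
    dl <- .dataLines(path)
    lines <- dl$lines
    lineno <- dl$lineno
    # drop the FIMO header row if present
    if (length(lines) && grepl("^motif_id\\b", lines[1L])) {
        lines <- lines[-1L]
        lineno <- lineno[-1L]
    }
    empty <- GRanges()
    mcols(empty) <- DataFrame(tf_name = character(0),
                              motif_id = character(0),
                              score = numeric(0), midpoint = integer(0))
    if (!length(lines)) return(empty)

    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 6L)
    if (length(short))
        .parseErr(lineno[short[1L]], "expected at least 6 tab-separated fields")

    motif <- .field(parts, 1L)
    alt <- .field(parts, 2L)
    chrom <- .field(parts, 3L)
    start1 <- .asInt(.field(parts, 4L), lineno, "start")
    stop1 <- .asInt(.field(parts, 5L), lineno, "stop")
    score <- .asNum(.field(parts, 7L), lineno, "score")
    qval <- .asNum(.field(parts, 9L), lineno, "q-value")

    bad <- which(stop1 < start1 | start1 < 1L)
    if (length(bad))
        .parseErr(lineno[bad[1L]],
                  sprintf("invalid coordinates start=%d stop=%d",
                          start1[bad[1L]], stop1[bad[1L]]))

    tf <- ifelse(!is.na(alt) & nzchar(alt) & alt != ".", alt, motif)
    if (any(!nzchar(tf)))
        .parseErr(lineno[which(!nzchar(tf))[1L]], "empty TF name")
    if (!is.null(chromAlias)) {
        hit <- match(chrom, names(chromAlias))
        chrom <- ifelse(is.na(hit), chrom, unname(chromAlias[hit]))
    }

    keep <- rep(TRUE, length(tf))
    if (!is.null(maxQvalue))
        keep <- is.na(qval) | qval <= maxQvalue
    if (!any(keep)) return(empty)

    start0 <- start1 - 1L            # 1-based inclusive -> 0-based half-open
    end0 <- stop1
    gr <- .gr0(chrom[keep], start0[keep], end0[keep])
    mcols(gr) <- DataFrame(
        tf_name = tf[keep],
        motif_id = motif[keep],
        score = score[keep],
        midpoint = as.integer((start0[keep] + end0[keep]) %/% 2L))
    st <- .field(parts, 6L)[keep]
    st[!st %in% c("+", "-")] <- "*"
    strand(gr) <- st
    gr[order(match(as.character(seqnames(gr)), .chromLevels(seqnames(gr))),
             start(gr))]
}

#' Read accessibility peaks (ENCODE narrowPeak or BED5)
#'
#' @param path peak file; narrowPeak (BED6+4) rows use the continuous
#'   `signalValue` column as the peak score, plain BED5 rows use column 5.
#' @param source assay: `"ATAC"` or `"DNase"`.
#' @param condition `"tumor"` or `"normal"`.
#' @param scoreColumn for narrowPeak input, `"signalValue"` (default,
#'   column 7) or `"score"` (the capped BED score, column 5).
#' @return `GRanges` with metadata columns `score`, `source`, `condition`.
#' @export
readNarrowPeak <- function(path, source = c("ATAC", "DNase"),
                           condition = c("tumor", "normal"),
                           scoreColumn = c("signalValue", "score")) {
    source <- match.arg(source)
    condition <- match.arg(condition)
    scoreColumn <- match.arg(scoreColumn)
    dl <- .dataLines(path, dropTrack = TRUE)
    empty <- GRanges()
    mcols(empty) <- DataFrame(score = numeric(0), source = character(0),
                              condition = character(0))
    if (!length(dl$lines)) return(empty)

    parts <- strsplit(dl$lines, "\t", fixed = TRUE)
    lineno <- dl$lineno
    nf <- lengths(parts)
    if (any(nf < 5L))
        .parseErr(lineno[which(nf < 5L)[1L]],
                  "expected at least 5 tab-separated fields")
    chrom <- .field(parts, 1L)
    s0 <- .asInt(.field(parts, 2L), lineno, "start")
    e0 <- .asInt(.field(parts, 3L), lineno, "end")
    bad <- which(e0 <= s0 | s0 < 0L)
    if (length(bad))
        .parseErr(lineno[bad[1L]],
                  sprintf("invalid interval [%d, %d)", s0[bad[1L]],
                          e0[bad[1L]]))
    score <- if (scoreColumn == "signalValue")
        ifelse(nf >= 10L, .asNum(.field(parts, 7L), lineno, "signalValue"),
               .asNum(.field(parts, 5L), lineno, "score"))
    else
        .asNum(.field(parts, 5L), lineno, "score")
    bad <- which(is.na(score) | score < 0)
    if (length(bad))
        .parseErr(lineno[bad[1L]],
                  sprintf("negative or missing peak score '%s'",
                          score[bad[1L]]))
    gr <- .gr0(chrom, s0, e0)
    mcols(gr) <- DataFrame(score = score, source = source,
                           condition = condition)
    gr
}

#' Read BED-like gene, variant or element tables
#'
#' `kind = "gene"`: BED6 (`chrom start end name score strand`); the TSS is
#' derived from the strand (interval start for `+`, `end - 1` for `-`, both
#' 0-based), and the `name` field doubles as gene id and symbol.  A missing
#' or `.` strand is an error because the TSS would be undefined.
#' `kind = "variant"`: BED (position = interval start) or a minimal VCF
#' (`CHROM`/`POS` only, 1-based, converted); records become width-1 ranges.
#' `kind = "element"`: BED4 with the regulatory class in column 4; classes
#' other than promoter/enhancer/cpg_island are kept with a warning as
#' `"other"`.
#'
#' @param path input file.
#' @param kind one of `"gene"`, `"variant"`, `"element"`.
#' @return `GRanges` with kind-specific metadata columns (`gene_id`,
#'   `symbol`, `tss` / `id` / `element_class`).
#' @export
readBedLike <- function(path, kind = c("gene", "variant", "element")) {
    kind <- match.arg(kind)
    if (kind == "variant" && .looksLikeVcf(path))
        return(.readVcfPositions(path))
    dl <- .dataLines(path, dropTrack = TRUE)
    parts <- strsplit(dl$lines, "\t", fixed = TRUE)
    lineno <- dl$lineno
    need <- switch(kind, gene = 6L, variant = 3L, element = 4L)
    nf <- lengths(parts)
    if (any(nf < need))
        .parseErr(lineno[which(nf < need)[1L]],
                  sprintf("expected at least %d fields for kind '%s'",
                          need, kind))
    if (!length(parts)) {
        gr <- GRanges()
        mcols(gr) <- switch(kind,
            gene = DataFrame(gene_id = character(0), symbol = character(0),
                             tss = integer(0)),
            variant = DataFrame(id = character(0)),
            element = DataFrame(element_class = character(0)))
        return(gr)
    }
    chrom <- .field(parts, 1L)
    s0 <- .asInt(.field(parts, 2L), lineno, "start")
    e0 <- .asInt(.field(parts, 3L), lineno, "end")
    if (kind != "variant") {
        bad <- which(e0 <= s0)
        if (length(bad))
            .parseErr(lineno[bad[1L]], "end <= start")
    }
    if (any(s0 < 0L))
        .parseErr(lineno[which(s0 < 0L)[1L]], "negative start")

    if (kind == "gene") {
        name <- .field(parts, 4L)
        strand <- .field(parts, 6L)
        bad <- which(!strand %in% c("+", "-"))
        if (length(bad))
            .parseErr(lineno[bad[1L]],
                      "gene strand must be '+' or '-' (TSS is undefined)")
        tss <- ifelse(strand == "+", s0, e0 - 1L)
        gr <- .gr0(chrom, s0, e0)
        strand(gr) <- strand
        mcols(gr) <- DataFrame(gene_id = name, symbol = name,
                               tss = as.integer(tss))
    } else if (kind == "variant") {
        gr <- .gr0(chrom, s0, s0 + 1L)
        mcols(gr) <- DataFrame(id = .field(parts, 4L))
    } else {
        cls <- .field(parts, 4L)
        known <- c("promoter", "enhancer", "cpg_island")
        if (any(!cls %in% known)) {
            warning("unknown element class(es) ",
                    paste(unique(setdiff(cls, known)), collapse = ", "),
                    "; recorded as 'other'", call. = FALSE)
            cls[!cls %in% known] <- "other"
        }
        gr <- .gr0(chrom, s0, e0)
        mcols(gr) <- DataFrame(element_class = cls)
    }
    gr
}

.looksLikeVcf <- function(path) {
    head1 <- readLines(path, n = 1L)
    grepl("\\.vcf$", path) ||
        (length(head1) && grepl("^##fileformat=VCF", head1))
}

.readVcfPositions <- function(path) {
    dl <- .dataLines(path)
    parts <- strsplit(dl$lines, "\t", fixed = TRUE)
    lineno <- dl$lineno
    if (any(lengths(parts) < 2L))
        .parseErr(lineno[which(lengths(parts) < 2L)[1L]],
                  "expected CHROM and POS fields")
    chrom <- .field(parts, 1L)
    pos1 <- .asInt(.field(parts, 2L), lineno, "POS")
    if (any(pos1 < 1L))
        .parseErr(lineno[which(pos1 < 1L)[1L]], "POS must be >= 1")
    gr <- .gr0(chrom, pos1 - 1L, pos1)
    mcols(gr) <- DataFrame(id = .field(parts, 3L))
    gr
}

#' Read a two-column expression table
#'
#' @param path TSV with columns gene id and FPKM; an optional header row is
#'   detected by a non-numeric second field.
#' @return named numeric vector of FPKM values.
#' @export
readExpressionTable <- function(path) {
    dl <- .dataLines(path)
    lines <- dl$lines
    lineno <- dl$lineno
    if (length(lines)) {
        first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
        if (length(first) >= 2L &&
            is.na(suppressWarnings(as.numeric(first[2L])))) {
            lines <- lines[-1L]
            lineno <- lineno[-1L]
        }
    }
    if (!length(lines)) return(setNames(numeric(0), character(0)))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L))
        .parseErr(lineno[which(lengths(parts) < 2L)[1L]],
                  "expected two tab-separated columns")
    gene <- .field(parts, 1L)
    fpkm <- .asNum(.field(parts, 2L), lineno, "FPKM")
    if (anyDuplicated(gene)) {
        dup <- gene[duplicated(gene)][1L]
        stop("duplicate gene_id '", dup, "' in expression table",
             call. = FALSE)
    }
    bad <- which(is.na(fpkm) | fpkm < 0)
    if (length(bad))
        .parseErr(lineno[bad[1L]], "FPKM must be a nonnegative number")
    setNames(fpkm, gene)
}

#' Write / read the TFCR table
#'
#' Serializes a [TFCRSet-class] to a BED-like TSV (0-based half-open window
#' coordinates; header line starts with `#`): chrom, start, end, tfcr_id,
#' summit, tc, sc, tc_bin, sc_bin, condition, n_contrib.  Unassigned bins
#' are written as `NA`.  `readTfcrTable()` inverts the writer exactly on
#' the serialized record set (the in-memory `contributing` index list is
#' not serialized).
#'
#' @param x a `TFCRSet`.
#' @param path output (input) path.
#' @return `writeTfcrTable` returns `path` invisibly; `readTfcrTable`
#'   returns a `TFCRSet`.
#' @export
writeTfcrTable <- function(x, path) {
    stopifnot(is(x, "TFCRSet"))
    header <- paste(c("#chrom", "start", "end", "tfcr_id", "summit", "tc",
                      "sc", "tc_bin", "sc_bin", "condition", "n_contrib"),
                    collapse = "\t")
    m <- mcols(x)
    rows <- if (length(x)) {
        paste(as.character(seqnames(x)), .start0(x), .end0(x), m$tfcr_id,
              m$summit, m$tc, .fmtNum(m$sc),
              ifelse(is.na(m$tc_bin), "NA", m$tc_bin),
              ifelse(is.na(m$sc_bin), "NA", m$sc_bin),
              m$condition, m$n_contrib, sep = "\t")
    } else character(0)
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c(header, rows), con)
    invisible(path)
}

#' @rdname writeTfcrTable
#' @export
readTfcrTable <- function(path) {
    dl <- .dataLines(path)
    if (!length(dl$lines)) return(TFCRSet())
    parts <- strsplit(dl$lines, "\t", fixed = TRUE)
    lineno <- dl$lineno
    if (any(lengths(parts) < 11L))
        .parseErr(lineno[which(lengths(parts) < 11L)[1L]],
                  "expected 11 tab-separated columns")
    asBin <- function(v) {
        out <- suppressWarnings(as.integer(v))
        out
    }
    s0 <- .asInt(.field(parts, 2L), lineno, "start")
    e0 <- .asInt(.field(parts, 3L), lineno, "end")
    gr <- .gr0(.field(parts, 1L), s0, e0)
    mcols(gr) <- DataFrame(
        tfcr_id = .field(parts, 4L),
        summit = .asInt(.field(parts, 5L), lineno, "summit"),
        tc = .asInt(.field(parts, 6L), lineno, "tc"),
        sc = .asNum(.field(parts, 7L), lineno, "sc"),
        tc_bin = asBin(.field(parts, 8L)),
        sc_bin = asBin(.field(parts, 9L)),
        condition = .field(parts, 10L),
        n_contrib = .asInt(.field(parts, 11L), lineno, "n_contrib"))
    TFCRSet(gr)
}
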