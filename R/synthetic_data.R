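# Seeded synthetic regulatory landscapes with planted ground truth.  The
# generator emulates the statistical structure the analysis assumes:
# TFBS clustered around planted centers with variable TF complexity,
# accessibility scores that saturate in TF count, condition-specific
# cluster gains and losses, expression elevated near high-TC clusters, and
# mutation density increasing with TC.

#' Synthetic landscape configuration
#'
#' Returns a validated configuration list for [generateLandscape()].  The
#' defaults describe a two-chromosome, 3 Mb landscape with 200 planted
#' clusters (100 shared, 50 tumor-only, 50 normal-only), a TF panel of 200
#' factors, and a piecewise-linear accessibility law that saturates at
#' `scSaturationTc` = 50 distinct TFs — the minimal mechanism reproducing a
#' TC-SC correlation that is positive below a breakpoint and flat above it.
#'
#' Design notes: cluster centers sit on a jittered regular lattice so the
#' `minClusterSeparation` guarantee (10x the analysis kernel width by
#' default) holds deterministically; background TFBS are kept
#' `backgroundExclusion` bp away from planted centers and from each other,
#' so each forms an isolated single-site cluster and planted-cluster
#' recovery is identifiable; non-driver genes are kept away from cluster
#' neighborhoods so the candidate screen has a decidable ground truth.
#'
#' @param seed integer RNG seed; the generated landscape is a deterministic
#'   function of the configuration including the seed.
#' @param nChrom,chromLength number and length (bp) of chromosomes.
#' @param nShared,nGain,nLost planted cluster counts by condition
#'   membership (shared = both conditions, gain = tumor-only, lost =
#'   normal-only).
#' @param tfPanelSize number of distinct TF names available.
#' @param clusterTcMean mean extra TFs per cluster; the true TF complexity
#'   is `1 + Poisson(clusterTcMean)`.
#' @param sitesPerTfMean mean binding sites per contributing TF (sites are
#'   `1 + Poisson(sitesPerTfMean - 1)`).
#' @param clusterSpread SD (bp) of site positions around the cluster center.
#' @param backgroundTfbsPerKb genome-wide background TFBS density.
#' @param peakWidthRange accessibility peak width range (bp), uniform.
#' @param scBase,scSlope,scSaturationTc,scNoiseSd accessibility score law:
#'   `score = scBase + scSlope * min(TC_true, scSaturationTc) +
#'   Normal(0, scNoiseSd)`, truncated at 0.
#' @param nGenes total genes to place.
#' @param exprMeanlog,exprSdlog baseline log-normal FPKM parameters.
#' @param exprBoostNearTopClusters added to the log-mean of genes planted
#'   near clusters, scaled by the cluster's relative TF complexity.
#' @param mutationRateBasePerKb,mutationRateTcSlopePerKb variant density:
#'   per-kb rate `base + slope * TC_true` inside cluster neighborhoods,
#'   `base` elsewhere.
#' @param minClusterSeparation minimum distance between planted centers
#'   (bp); must be at least 10x the kernel width of the intended analysis
#'   for clusters to be identifiable.
#' @param backgroundExclusion halo (bp) around planted centers and other
#'   background sites kept free of background TFBS.
#' @param motifWidth width (bp) of generated binding sites.
#' @return a list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed,
                            nChrom = 2L, chromLength = 1500000L,
                            nShared = 100L, nGain = 50L, nLost = 50L,
                            tfPanelSize = 200L,
                            clusterTcMean = 50,
                            sitesPerTfMean = 2,
                            clusterSpread = 75,
                            backgroundTfbsPerKb = 0.05,
                            peakWidthRange = c(200L, 1000L),
                            scBase = 5, scSlope = 1,
                            scSaturationTc = 50, scNoiseSd = 5,
                            nGenes = 300L,
                            exprMeanlog = 0.5, exprSdlog = 1,
                            exprBoostNearTopClusters = 2,
                            mutationRateBasePerKb = 0.5,
                            mutationRateTcSlopePerKb = 0.05,
                            minClusterSeparation = 3000L,
                            backgroundExclusion = 2000L,
                            motifWidth = 10L) {
    cfg <- list(seed = as.integer(seed), nChrom = as.integer(nChrom),
                chromLength = as.integer(chromLength),
                nShared = as.integer(nShared), nGain = as.integer(nGain),
                nLost = as.integer(nLost),
                tfPanelSize = as.integer(tfPanelSize),
                clusterTcMean = clusterTcMean,
                sitesPerTfMean = sitesPerTfMean,
                clusterSpread = clusterSpread,
                backgroundTfbsPerKb = backgroundTfbsPerKb,
                peakWidthRange = as.integer(peakWidthRange),
                scBase = scBase, scSlope = scSlope,
                scSaturationTc = scSaturationTc, scNoiseSd = scNoiseSd,
                nGenes = as.integer(nGenes),
                exprMeanlog = exprMeanlog, exprSdlog = exprSdlog,
                exprBoostNearTopClusters = exprBoostNearTopClusters,
                mutationRateBasePerKb = mutationRateBasePerKb,
                mutationRateTcSlopePerKb = mutationRateTcSlopePerKb,
                minClusterSeparation = as.integer(minClusterSeparation),
                backgroundExclusion = as.integer(backgroundExclusion),
                motifWidth = as.integer(motifWidth))
    counts <- c(cfg$nShared, cfg$nGain, cfg$nLost, cfg$nChrom, cfg$nGenes)
    if (any(counts < 0L)) stop("counts must be nonnegative")
    if (is.na(cfg$seed)) stop("'seed' is required")
    if (cfg$clusterTcMean < 0 || cfg$sitesPerTfMean < 1)
        stop("invalid cluster composition parameters")
    if (length(cfg$peakWidthRange) != 2L ||
        any(cfg$peakWidthRange <= 0L) ||
        cfg$peakWidthRange[1L] > cfg$peakWidthRange[2L])
        stop("'peakWidthRange' must be an increasing positive pair")
    structure(cfg, class = "SyntheticConfig")
}

# Jittered-lattice cluster centers; errors when the requested count cannot
# respect the separation constraint.
.placeCenters <- function(cfg) {
    total <- cfg$nShared + cfg$nGain + cfg$nLost
    perChrom <- diff(round(seq(0, total, length.out = cfg$nChrom + 1L)))
    chromNames <- sprintf("chr%d", seq_len(cfg$nChrom))
    chrom <- character(0)
    center <- numeric(0)
    margin <- cfg$minClusterSeparation
    for (i in seq_len(cfg$nChrom)) {
        m <- perChrom[i]
        if (!m) next
        spacing <- (cfg$chromLength - 2 * margin) / m
        if (spacing < cfg$minClusterSeparation)
            stop("cannot place ", m, " clusters on a ", cfg$chromLength,
                 " bp chromosome with minClusterSeparation = ",
                 cfg$minClusterSeparation)
        jmax <- 0.45 * (spacing - cfg$minClusterSeparation)
        pos <- margin + (seq_len(m) - 0.5) * spacing +
            runif(m, -jmax, jmax)
        chrom <- c(chrom, rep(chromNames[i], m))
        center <- c(center, round(pos))
    }
    data.frame(chrom = chrom, center = as.integer(center),
               stringsAsFactors = FALSE)
}

# Deciles of a predicted corpus using the same rank rule as
# assignDecileBins(), so the truth can anticipate the called bins.
.predictBins <- function(values, chrom, pos) {
    n <- length(values)
    r <- .tiedRank(values, chrom, pos)
    as.integer((10L * (r - 1L)) %/% n)
}

#' Generate a synthetic regulatory landscape with known truth
#'
#' Draws the landscape described by a [syntheticConfig()]: planted TFBS
#' clusters (with per-cluster TF sets and per-TF site counts), background
#' TFBS, one accessibility peak per cluster per visible condition with the
#' saturating score law, genes (cluster-adjacent, background and planted
#' driver genes), expression, regulatory elements and variants.  Driver
#' genes are planted with their TSS within 500 bp of every tumor-only
#' cluster whose anticipated tumor TC and SC decile bins are both 9, with
#' FPKM >= 5, so the end-to-end screen has an exact expected answer.
#'
#' @param config a `SyntheticConfig`.
#' @param dir optional output directory; when given, the full file manifest
#'   (FIMO TSV and narrowPeak per condition, gene BED, expression TSV,
#'   variant BED per condition, element BED, `truth.json`) is written and
#'   recorded in the returned object.  Identical config (including seed)
#'   yields byte-identical files.
#' @return a list of class `SyntheticLandscape` with `GRanges` components
#'   `tfbsTumor`, `tfbsNormal`, `peaksTumor`, `peaksNormal`, `genes`,
#'   `variantsTumor`, `variantsNormal`, `elements`; a named `expression`
#'   vector; the `truth` list (cluster table with memberships, true TC,
#'   planted scores, anticipated tumor bins; `driver_genes`; the config);
#'   and `files` (named paths or `NULL`).
#' @export
generateLandscape <- function(config, dir = NULL) {
    stopifnot(inherits(config, "SyntheticConfig"))
    cfg <- config
    set.seed(cfg$seed)
    panel <- sprintf("TF%03d", seq_len(cfg$tfPanelSize))

    ## --- planted clusters ------------------------------------------------
    centers <- .placeCenters(cfg)
    nClust <- nrow(centers)
    membership <- sample(rep(c("shared", "gain", "lost"),
                             times = c(cfg$nShared, cfg$nGain, cfg$nLost)))
    tcTrue <- 1L + rpois(nClust, cfg$clusterTcMean)
    if (any(tcTrue > cfg$tfPanelSize))
        stop("tfPanelSize too small for the drawn TF complexities")

    siteChrom <- character(0); sitePos <- numeric(0)
    siteTf <- character(0); siteCluster <- integer(0)
    nSites <- integer(nClust)
    for (i in seq_len(nClust)) {
        tfs <- sample(panel, tcTrue[i])
        cnt <- 1L + rpois(tcTrue[i], cfg$sitesPerTfMean - 1)
        tf <- rep(tfs, cnt)
        pos <- round(rnorm(length(tf), centers$center[i],
                           cfg$clusterSpread))
        siteChrom <- c(siteChrom, rep(centers$chrom[i], length(tf)))
        sitePos <- c(sitePos, pos)
        siteTf <- c(siteTf, tf)
        siteCluster <- c(siteCluster, rep(i, length(tf)))
        nSites[i] <- length(tf)
    }

    ## --- background TFBS (per condition) ---------------------------------
    chromNames <- sprintf("chr%d", seq_len(cfg$nChrom))
    totalLen <- cfg$nChrom * as.numeric(cfg$chromLength)
    drawBackground <- function() {
        n <- rpois(1L, cfg$backgroundTfbsPerKb * totalLen / 1000)
        ch <- sample(chromNames, n, replace = TRUE)
        pos <- round(runif(n, cfg$backgroundExclusion,
                           cfg$chromLength - cfg$backgroundExclusion))
        tf <- sample(panel, n, replace = TRUE)
        keep <- rep(TRUE, n)
        for (j in seq_len(n)) {   # 2 kb halo around planted centers
            near <- centers$chrom == ch[j] &
                abs(centers$center - pos[j]) < cfg$backgroundExclusion
            if (any(near)) keep[j] <- FALSE
        }
        ch <- ch[keep]; pos <- pos[keep]; tf <- tf[keep]
        o <- order(ch, pos)
        ch <- ch[o]; pos <- pos[o]; tf <- tf[o]
        keep2 <- rep(TRUE, length(pos))   # pairwise thinning
        last <- -Inf; lastCh <- ""
        for (j in seq_along(pos)) {
            if (ch[j] == lastCh && pos[j] - last < cfg$backgroundExclusion) {
                keep2[j] <- FALSE
            } else {
                last <- pos[j]; lastCh <- ch[j]
            }
        }
        data.frame(chrom = ch[keep2], pos = pos[keep2], tf = tf[keep2],
                   stringsAsFactors = FALSE)
    }
    bgTumor <- drawBackground()
    bgNormal <- drawBackground()

    ## --- accessibility peaks (per condition) ------------------------------
    drawPeaks <- function(visible) {
        idx <- which(membership %in% visible)
        w <- round(runif(length(idx), cfg$peakWidthRange[1L],
                         cfg$peakWidthRange[2L]))
        score <- pmax(0, cfg$scBase +
                          cfg$scSlope * pmin(tcTrue[idx],
                                             cfg$scSaturationTc) +
                          rnorm(length(idx), 0, cfg$scNoiseSd))
        data.frame(chrom = centers$chrom[idx],
                   start0 = centers$center[idx] - w %/% 2L,
                   end0 = centers$center[idx] - w %/% 2L + w,
                   score = score, cluster = idx,
                   stringsAsFactors = FALSE)
    }
    peaksTumorDf <- drawPeaks(c("shared", "gain"))
    peaksNormalDf <- drawPeaks(c("shared", "lost"))

    ## --- anticipated tumor decile bins ------------------------------------
    # Tumor corpus the caller will see: every tumor-visible cluster (TC =
    # true TC, SC = its planted tumor peak score) plus each background site
    # as an isolated TFCR (TC 1, SC 0).  Background sites are excluded from
    # cluster halos, so this anticipation is exact for a recovering caller.
    tumorIdx <- which(membership %in% c("shared", "gain"))
    scTumor <- rep(NA_real_, nClust)
    scTumor[peaksTumorDf$cluster] <- peaksTumorDf$score
    scNormal <- rep(NA_real_, nClust)
    scNormal[peaksNormalDf$cluster] <- peaksNormalDf$score
    corpus <- data.frame(
        chrom = c(centers$chrom[tumorIdx], bgTumor$chrom),
        pos = c(centers$center[tumorIdx], bgTumor$pos),
        tc = c(tcTrue[tumorIdx], rep(1L, nrow(bgTumor))),
        sc = c(scTumor[tumorIdx], rep(0, nrow(bgTumor))))
    tcBinCorpus <- .predictBins(corpus$tc, corpus$chrom, corpus$pos)
    scBinCorpus <- .predictBins(corpus$sc, corpus$chrom, corpus$pos)
    predTcBin <- rep(NA_integer_, nClust)
    predScBin <- rep(NA_integer_, nClust)
    predTcBin[tumorIdx] <- tcBinCorpus[seq_along(tumorIdx)]
    predScBin[tumorIdx] <- scBinCorpus[seq_along(tumorIdx)]

    ## --- genes and expression ---------------------------------------------
    geneChrom <- character(0); geneTss <- numeric(0)
    geneStrand <- character(0); geneLen <- numeric(0)
    geneKind <- character(0); geneCluster <- integer(0)
    for (i in which(membership %in% c("shared", "lost"))) {
        if (runif(1) > 0.8) next
        geneChrom <- c(geneChrom, centers$chrom[i])
        geneTss <- c(geneTss, centers$center[i] +
                         round(runif(1, -1000, 1000)))
        geneStrand <- c(geneStrand, sample(c("+", "-"), 1L))
        geneLen <- c(geneLen, round(runif(1, 500, 3000)))
        geneKind <- c(geneKind, "cluster")
        geneCluster <- c(geneCluster, i)
    }
    driverClusters <- which(membership == "gain" &
                            predTcBin == 9L & predScBin == 9L)
    for (i in driverClusters) {
        geneChrom <- c(geneChrom, centers$chrom[i])
        geneTss <- c(geneTss, centers$center[i] +
                         round(runif(1, -500, 500)))
        geneStrand <- c(geneStrand, sample(c("+", "-"), 1L))
        geneLen <- c(geneLen, round(runif(1, 500, 3000)))
        geneKind <- c(geneKind, "driver")
        geneCluster <- c(geneCluster, i)
    }
    nBg <- max(0L, cfg$nGenes - length(geneTss))
    placed <- 0L
    attempts <- 0L
    while (placed < nBg && attempts < 50L * nBg) {
        attempts <- attempts + 1L
        ch <- sample(chromNames, 1L)
        tss <- round(runif(1, 6000, cfg$chromLength - 6000))
        near <- centers$chrom == ch & abs(centers$center - tss) < 6000
        if (any(near)) next
        geneChrom <- c(geneChrom, ch)
        geneTss <- c(geneTss, tss)
        geneStrand <- c(geneStrand, sample(c("+", "-"), 1L))
        geneLen <- c(geneLen, round(runif(1, 500, 3000)))
        geneKind <- c(geneKind, "background")
        geneCluster <- c(geneCluster, NA_integer_)
        placed <- placed + 1L
    }
    nGene <- length(geneTss)
    geneS0 <- ifelse(geneStrand == "+", geneTss, geneTss + 1 - geneLen)
    geneE0 <- ifelse(geneStrand == "+", geneTss + geneLen, geneTss + 1)
    ord <- order(match(geneChrom, chromNames), geneS0)
    geneChrom <- geneChrom[ord]; geneTss <- geneTss[ord]
    geneStrand <- geneStrand[ord]; geneS0 <- geneS0[ord]
    geneE0 <- geneE0[ord]; geneKind <- geneKind[ord]
    geneCluster <- geneCluster[ord]
    geneId <- sprintf("G%04d", seq_len(nGene))

    relTc <- ifelse(is.na(geneCluster), 0,
                    pmin(tcTrue[ifelse(is.na(geneCluster), 1L,
                                       geneCluster)] /
                             (1 + cfg$clusterTcMean), 1))
    meanlog <- cfg$exprMeanlog + cfg$exprBoostNearTopClusters * relTc
    fpkm <- rlnorm(nGene, meanlog, cfg$exprSdlog)
    isDriver <- geneKind == "driver"
    fpkm[isDriver] <- 5 + rlnorm(sum(isDriver), 1, 0.5)
    fpkm <- round(fpkm, 4)

    ## --- regulatory elements ----------------------------------------------
    elChrom <- geneChrom
    elS0 <- pmax(0, geneTss - 500)
    elE0 <- geneTss + 500
    elClass <- rep("promoter", nGene)
    topClusters <- which(predTcBin == 9L | predScBin == 9L)
    if (length(topClusters)) {
        elChrom <- c(elChrom, centers$chrom[topClusters])
        elS0 <- c(elS0, centers$center[topClusters] - 300)
        elE0 <- c(elE0, centers$center[topClusters] + 300)
        elClass <- c(elClass,
                     rep_len(c("enhancer", "cpg_island"),
                             length(topClusters)))
    }

    ## --- variants (per condition) ------------------------------------------
    clusterHalf <- 800L
    drawVariants <- function(visible) {
        idx <- which(membership %in% visible)
        ch <- character(0); pos <- numeric(0)
        for (i in idx) {
            rate <- cfg$mutationRateBasePerKb +
                cfg$mutationRateTcSlopePerKb * tcTrue[i]
            k <- rpois(1L, rate * 2 * clusterHalf / 1000)
            if (!k) next
            ch <- c(ch, rep(centers$chrom[i], k))
            pos <- c(pos, round(runif(k, centers$center[i] - clusterHalf,
                                      centers$center[i] + clusterHalf)))
        }
        nBgVar <- rpois(1L, cfg$mutationRateBasePerKb * totalLen / 1000)
        bch <- sample(chromNames, nBgVar, replace = TRUE)
        bpos <- round(runif(nBgVar, 0, cfg$chromLength - 1))
        keep <- rep(TRUE, nBgVar)
        for (j in seq_len(nBgVar)) {
            near <- centers$chrom == bch[j] & membership %in% visible &
                abs(centers$center - bpos[j]) < clusterHalf
            if (any(near)) keep[j] <- FALSE
        }
        ch <- c(ch, bch[keep]); pos <- c(pos, bpos[keep])
        o <- order(match(ch, chromNames), pos)
        data.frame(chrom = ch[o], pos = pos[o], stringsAsFactors = FALSE)
    }
    varTumor <- drawVariants(c("shared", "gain"))
    varNormal <- drawVariants(c("shared", "lost"))

    ## --- assemble GRanges --------------------------------------------------
    half <- cfg$motifWidth %/% 2L
    mkTfbs <- function(clusterVisible, bg) {
        sel <- siteCluster %in% which(membership %in% clusterVisible)
        ch <- c(siteChrom[sel], bg$chrom)
        pos <- c(sitePos[sel], bg$pos)
        tf <- c(siteTf[sel], bg$tf)
        cl <- c(siteCluster[sel], rep(NA_integer_, nrow(bg)))
        o <- order(match(ch, chromNames), pos)
        gr <- .gr0(ch[o], pos[o] - half, pos[o] - half + cfg$motifWidth)
        mcols(gr) <- DataFrame(
            tf_name = tf[o],
            motif_id = sub("^TF", "M", tf[o]),
            score = rep(10, length(gr)),
            midpoint = as.integer(pos[o]),
            cluster = cl[o])
        gr
    }
    tfbsTumor <- mkTfbs(c("shared", "gain"), bgTumor)
    tfbsNormal <- mkTfbs(c("shared", "lost"), bgNormal)
    mkPeaks <- function(df, condition) {
        o <- order(match(df$chrom, chromNames), df$start0)
        gr <- .gr0(df$chrom[o], df$start0[o], df$end0[o])
        mcols(gr) <- DataFrame(score = round(df$score[o], 4),
                               source = if (condition == "tumor")
                                   "ATAC" else "DNase",
                               condition = condition)
        gr
    }
    genes <- .gr0(geneChrom, geneS0, geneE0)
    strand(genes) <- geneStrand
    mcols(genes) <- DataFrame(gene_id = geneId, symbol = geneId,
                              tss = as.integer(geneTss))
    elements <- .gr0(elChrom, elS0, elE0)
    mcols(elements) <- DataFrame(element_class = elClass)
    mkVariants <- function(df) {
        gr <- .gr0(df$chrom, df$pos, df$pos + 1)
        mcols(gr) <- DataFrame(id = sprintf("v%05d", seq_len(nrow(df))))
        gr
    }

    truth <- list(
        clusters = data.frame(
            cluster_id = sprintf("cluster_%03d", seq_len(nClust)),
            chrom = centers$chrom, center = centers$center,
            membership = membership, tc_true = tcTrue,
            n_sites = nSites,
            peak_score_tumor = round(scTumor, 4),
            peak_score_normal = round(scNormal, 4),
            pred_tc_bin_tumor = predTcBin,
            pred_sc_bin_tumor = predScBin,
            driver_gene = geneId[match(seq_len(nClust),
                                       ifelse(geneKind == "driver",
                                              geneCluster, NA))],
            stringsAsFactors = FALSE),
        driver_genes = geneId[geneKind == "driver"],
        config = unclass(cfg))

    land <- structure(list(
        tfbsTumor = tfbsTumor, tfbsNormal = tfbsNormal,
        peaksTumor = mkPeaks(peaksTumorDf, "tumor"),
        peaksNormal = mkPeaks(peaksNormalDf, "normal"),
        genes = genes,
        expression = setNames(fpkm, geneId),
        variantsTumor = mkVariants(varTumor),
        variantsNormal = mkVariants(varNormal),
        elements = elements,
        truth = truth, files = NULL), class = "SyntheticLandscape")

    if (!is.null(dir)) land$files <- writeLandscape(land, dir)
    land
}

#' Write a synthetic landscape to disk
#'
#' Emits the standard-format file manifest ([generateLandscape()] formats)
#' into `dir`.  Deterministic: the same landscape writes byte-identical
#' files.
#'
#' @param land a `SyntheticLandscape`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths (invisibly from
#'   `generateLandscape`).
#' @export
writeLandscape <- function(land, dir) {
    stopifnot(inherits(land, "SyntheticLandscape"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    writeFimo <- function(gr, path) {
        header <- paste(c("motif_id", "motif_alt_id", "sequence_name",
                          "start", "stop", "strand", "score", "p-value",
                          "q-value", "matched_sequence"), collapse = "\t")
        rows <- if (length(gr))
            paste(mcols(gr)$motif_id, mcols(gr)$tf_name,
                  as.character(seqnames(gr)),
                  .start0(gr) + 1L, .end0(gr), "+",
                  .fmtNum(mcols(gr)$score), "1e-05", "0.01",
                  strrep("N", width(gr)), sep = "\t")
        else character(0)
        writeLines(c(header, rows), path)
    }
    writePeaks <- function(gr, path) {
        rows <- if (length(gr))
            paste(as.character(seqnames(gr)), .start0(gr), .end0(gr),
                  sprintf("peak_%05d", seq_along(gr)), 0L, ".",
                  .fmtNum(mcols(gr)$score), -1L, -1L, width(gr) %/% 2L,
                  sep = "\t")
        else character(0)
        writeLines(rows, path)
    }
    writeGenes <- function(gr, path) {
        writeLines(paste(as.character(seqnames(gr)), .start0(gr),
                         .end0(gr), mcols(gr)$gene_id, 0L,
                         as.character(strand(gr)), sep = "\t"), path)
    }
    writeVariants <- function(gr, path) {
        writeLines(if (length(gr))
            paste(as.character(seqnames(gr)), .start0(gr), .end0(gr),
                  mcols(gr)$id, sep = "\t") else character(0), path)
    }
    files <- c(
        tfbs_tumor = p("tfbs_tumor.fimo.tsv"),
        tfbs_normal = p("tfbs_normal.fimo.tsv"),
        peaks_tumor = p("peaks_tumor.narrowPeak"),
        peaks_normal = p("peaks_normal.narrowPeak"),
        genes = p("genes.bed"),
        expression = p("expression.tsv"),
        variants_tumor = p("variants_tumor.bed"),
        variants_normal = p("variants_normal.bed"),
        elements = p("elements.bed"),
        truth = p("truth.json"))
    writeFimo(land$tfbsTumor, files[["tfbs_tumor"]])
    writeFimo(land$tfbsNormal, files[["tfbs_normal"]])
    writePeaks(land$peaksTumor, files[["peaks_tumor"]])
    writePeaks(land$peaksNormal, files[["peaks_normal"]])
    writeGenes(land$genes, files[["genes"]])
    writeLines(c("gene_id\tfpkm",
                 paste(names(land$expression),
                       .fmtNum(land$expression), sep = "\t")),
               files[["expression"]])
    writeVariants(land$variantsTumor, files[["variants_tumor"]])
    writeVariants(land$variantsNormal, files[["variants_normal"]])
    writeLines(paste(as.character(seqnames(land$elements)),
                     .start0(land$elements), .end0(land$elements),
                     mcols(land$elements)$element_class, sep = "\t"),
               files[["elements"]])
    jsonlite::write_json(land$truth, files[["truth"]],
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, na = "null")
    files
}

#' Evaluate pipeline recovery against planted truth
#'
#' Matches called summits to planted cluster centers by greedy
#' nearest-first 1-1 matching within `matchTol` bp, per condition a
#' cluster is visible in.  Reports recall (overall and for clusters with
#' at least 3 sites), per-condition precision (fraction of called summits
#' within `matchTol` of any visible center; background-derived summits
#' count as false positives), the exact-TC rate on recovered clusters, and
#' the gain/lost/stable confusion between planted memberships and the
#' labels implied by [classifyDifferential()] on the called sets.
#'
#' @param truth the `truth` element of a `SyntheticLandscape` (or the
#'   landscape itself).
#' @param tumor,normal called [TFCRSet-class]s for the two conditions.
#' @param matchTol matching tolerance in bp (default 300, the kernel
#'   width).
#' @return a list of class `RecoveryReport`: `recall`, `recall_ge3`,
#'   `precision_tumor`, `precision_normal` (NA when that side has no
#'   calls), `tc_exact_rate`, `membership_exact_rate`, `confusion`
#'   (planted x called table), `n_planted`, `n_recovered`, and the
#'   per-cluster `clusters` data.frame.
#' @export
evaluateRecovery <- function(truth, tumor, normal, matchTol = 300) {
    if (inherits(truth, "SyntheticLandscape")) truth <- truth$truth
    cl <- truth$clusters
    n <- nrow(cl)

    matchSide <- function(called, visible) {
        res <- list(cluster = integer(0), tfcr = integer(0))
        vis <- which(cl$membership %in% visible)
        if (!length(called) || !length(vis))
            return(list(match = rep(NA_integer_, n),
                        precision = if (length(called)) 0 else NA_real_))
        sChrom <- as.character(seqnames(called))
        sPos <- summits(called)
        pairs <- do.call(rbind, lapply(vis, function(i) {
            j <- which(sChrom == cl$chrom[i] &
                           abs(sPos - cl$center[i]) <= matchTol)
            if (!length(j)) return(NULL)
            data.frame(cluster = i, tfcr = j,
                       d = abs(sPos[j] - cl$center[i]))
        }))
        match <- rep(NA_integer_, n)
        usedT <- logical(length(called))
        if (!is.null(pairs)) {
            pairs <- pairs[order(pairs$d, pairs$cluster, pairs$tfcr), ,
                           drop = FALSE]
            for (r in seq_len(nrow(pairs))) {
                i <- pairs$cluster[r]; j <- pairs$tfcr[r]
                if (is.na(match[i]) && !usedT[j]) {
                    match[i] <- j
                    usedT[j] <- TRUE
                }
            }
        }
        nearAny <- vapply(seq_along(called), function(j)
            any(cl$chrom[vis] == sChrom[j] &
                    abs(cl$center[vis] - sPos[j]) <= matchTol),
            logical(1))
        list(match = match, precision = mean(nearAny))
    }

    mt <- matchSide(tumor, c("shared", "gain"))
    mn <- matchSide(normal, c("shared", "lost"))
    recovered <- !is.na(mt$match) | !is.na(mn$match)
    ge3 <- cl$n_sites >= 3L
    diff <- classifyDifferential(tumor, normal)
    gainIds <- tfcrId(gainTfcrs(diff))
    lostIds <- tfcrId(lostTfcrs(diff))

    calledLabel <- rep(NA_character_, n)
    for (i in seq_len(n)) {
        tl <- if (!is.na(mt$match[i])) {
            if (tfcrId(tumor)[mt$match[i]] %in% gainIds) "gain" else
                "stable"
        } else NA_character_
        nl <- if (!is.na(mn$match[i])) {
            if (tfcrId(normal)[mn$match[i]] %in% lostIds) "lost" else
                "stable"
        } else NA_character_
        calledLabel[i] <-
            if (is.na(tl) && is.na(nl)) NA_character_
            else if (is.na(nl)) tl
            else if (is.na(tl)) nl
            else if (tl == "stable" && nl == "stable") "stable"
            else "inconsistent"
    }

    tcCalled <- rep(NA_integer_, n)
    tcCalled[!is.na(mt$match)] <-
        tfComplexity(tumor)[mt$match[!is.na(mt$match)]]
    useNormal <- is.na(mt$match) & !is.na(mn$match)
    tcCalled[useNormal] <- tfComplexity(normal)[mn$match[useNormal]]

    clOut <- cbind(cl, recovered = recovered, tc_called = tcCalled,
                   called_label = calledLabel)
    recRate <- function(sel) if (any(sel)) mean(recovered[sel]) else
        NA_real_
    tcExact <- if (any(recovered))
        mean(tcCalled[recovered] == cl$tc_true[recovered]) else NA_real_
    # planted memberships say "shared"; the classifier calls those "stable"
    plantedAsCalled <- ifelse(cl$membership == "shared", "stable",
                              cl$membership)
    membExact <- if (any(recovered))
        mean(calledLabel[recovered] == plantedAsCalled[recovered],
             na.rm = FALSE) else NA_real_
    structure(list(
        recall = mean(recovered),
        recall_ge3 = recRate(ge3),
        precision_tumor = mt$precision,
        precision_normal = mn$precision,
        tc_exact_rate = tcExact,
        membership_exact_rate = membExact,
        confusion = table(planted = cl$membership[recovered],
                          called = calledLabel[recovered],
                          useNA = "ifany"),
        n_planted = n,
        n_recovered = sum(recovered),
        clusters = clOut), class = "RecoveryReport")
}

#' @export
print.RecoveryReport <- function(x, ...) {
    cat("RecoveryReport: ", x$n_recovered, "/", x$n_planted,
        " clusters recovered (recall ", round(x$recall, 3),
        ", >=3-site recall ", round(x$recall_ge3, 3), ")\n",
        "  precision tumor/normal: ", round(x$precision_tumor, 3), " / ",
        round(x$precision_normal, 3), "\n",
        "  exact TC on recovered: ", round(x$tc_exact_rate, 3), "\n",
        "  membership exact: ", round(x$membership_exact_rate, 3),
        "\n", sep = "")
    print(x$confusion)
    invisible(x)
}
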