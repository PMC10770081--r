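# End-to-end orchestration: identify x2 conditions -> bin -> compare ->
# screen -> diagnostics, from a single config, with a run manifest.

.requiredInputs <- c("tfbs_tumor", "tfbs_normal", "peaks_tumor",
                     "peaks_normal", "genes", "expression")
.optionalInputs <- c("variants_tumor", "variants_normal", "elements")

#' Run the full TFCR screen
#'
#' Executes the whole pipeline from one configuration: read inputs,
#' identify TFCRs per condition, assign decile bins per condition,
#' classify gain/lost/stable, score gain-TFCRs, screen candidate genes,
#' and compute the landscape diagnostics (TC-SC correlation split per
#' condition, plus expression/element/mutation summaries when the
#' corresponding inputs are configured).  All stage outputs and a JSON run
#' manifest (package version, parameters, input checksums, per-stage
#' counts) are written to the output directory; re-running the same config
#' into a clean directory reproduces byte-identical outputs.
#'
#' @param config a named list or the path of a YAML file with entries:
#'   `inputs` (paths `tfbs_tumor`, `tfbs_normal`, `peaks_tumor`,
#'   `peaks_normal`, `genes`, `expression`, optional `variants_tumor`,
#'   `variants_normal`, `elements`), `out_dir`, and optional `params`
#'   (fields of [tfcrParams()]), `tc_split_tumor` (default 170),
#'   `tc_split_normal` (default 50), `fpkm_min` (default 5),
#'   `promoter_upstream` (default 2000), `high_expr_cutoff` (default:
#'   top quartile), `min_overlap_frac` (default 0).
#' @return (invisibly) a list with the identified sets, the differential
#'   classification, the candidate table, the diagnostics and the
#'   manifest.  All input paths are validated before any computation; a
#'   stage failure still writes a manifest recording the failure point.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    inputs <- config$inputs
    if (is.null(inputs))
        stop("config must contain an 'inputs' list")
    outDir <- config$out_dir
    if (is.null(outDir)) stop("config must contain 'out_dir'")
    missing <- setdiff(.requiredInputs, names(inputs))
    if (length(missing))
        stop("missing required input(s): ", paste(missing, collapse = ", "))
    paths <- unlist(inputs[names(inputs) %in%
                               c(.requiredInputs, .optionalInputs)])
    absent <- paths[!file.exists(paths)]
    if (length(absent))
        stop("input file(s) not found: ", paste(absent, collapse = ", "))

    prm <- do.call(tfcrParams, as.list(config$params))
    tcSplitTumor <- config$tc_split_tumor %||% 170
    tcSplitNormal <- config$tc_split_normal %||% 50
    fpkmMin <- config$fpkm_min %||% 5
    promUp <- config$promoter_upstream %||% 2000
    minOvFrac <- config$min_overlap_frac %||% 0

    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(
        package = "tfcrscreen",
        version = as.character(packageVersion("tfcrscreen")),
        parameters = list(
            sigma = prm@sigma, grid_step = prm@gridStep,
            contrib_threshold = prm@contribThreshold,
            window_pad = prm@windowPad,
            tc_split_tumor = tcSplitTumor,
            tc_split_normal = tcSplitNormal,
            fpkm_min = fpkmMin, promoter_upstream = promUp,
            min_overlap_frac = minOvFrac),
        inputs = as.list(paths),
        input_md5 = as.list(md5sum(paths)),
        stages = list())
    stage <- NULL
    writeManifest <- function() {
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    on.exit({
        if (!is.null(stage)) {
            manifest$failed_stage <- stage
            writeManifest()
        }
    })

    stage <- "read_inputs"
    tfbsT <- readFimoHits(inputs$tfbs_tumor)
    tfbsN <- readFimoHits(inputs$tfbs_normal)
    peaksT <- readNarrowPeak(inputs$peaks_tumor, source = "ATAC",
                             condition = "tumor")
    peaksN <- readNarrowPeak(inputs$peaks_normal, source = "DNase",
                             condition = "normal")
    genes <- readBedLike(inputs$genes, kind = "gene")
    expr <- readExpressionTable(inputs$expression)
    variantsT <- if (!is.null(inputs$variants_tumor))
        readBedLike(inputs$variants_tumor, kind = "variant")
    variantsN <- if (!is.null(inputs$variants_normal))
        readBedLike(inputs$variants_normal, kind = "variant")
    elements <- if (!is.null(inputs$elements))
        readBedLike(inputs$elements, kind = "element")

    stage <- "identify"
    tumor <- identifyTfcrs(tfbsT, peaksT, prm, condition = "tumor")
    normal <- identifyTfcrs(tfbsN, peaksN, prm, condition = "normal")
    message("identified ", length(tumor), " tumor and ", length(normal),
            " normal TFCRs")

    stage <- "bin"
    tumor <- assignDecileBins(tumor)
    normal <- assignDecileBins(normal)
    writeTfcrTable(tumor, file.path(outDir, "tumor_tfcrs.tsv"))
    writeTfcrTable(normal, file.path(outDir, "normal_tfcrs.tsv"))

    stage <- "compare"
    diff <- classifyDifferential(tumor, normal,
                                 minOverlapFrac = minOvFrac)
    frac <- nonoverlapFractions(diff)
    message(sprintf(
        "gain %d / stable(tumor) %d / lost %d (non-overlap %.0f%% / %.0f%%)",
        length(gainTfcrs(diff)), length(stableTfcrs(diff, "tumor")),
        length(lostTfcrs(diff)), 100 * frac[["tumor"]],
        100 * frac[["normal"]]))

    stage <- "screen"
    candidates <- screenCandidates(diff, genes, expr, fpkmMin = fpkmMin,
                                   promoterUpstream = promUp)
    utils::write.table(candidates,
                       file.path(outDir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "stats"
    corSplit <- list(
        tumor = tcScCorrelationSplit(tumor, tcSplitTumor),
        normal = tcScCorrelationSplit(normal, tcSplitNormal))
    diag <- list()
    writeDiag <- function(df, name) {
        utils::write.table(df, file.path(outDir, paste0(name, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        df
    }
    diag$expression <- writeDiag(
        rbind(cbind(condition = "tumor",
                    expressionEnrichmentByBin(
                        tumor, genes, expr,
                        highExprCutoff = config$high_expr_cutoff,
                        promoterUpstream = promUp)),
              cbind(condition = "normal",
                    expressionEnrichmentByBin(
                        normal, genes, expr,
                        highExprCutoff = config$high_expr_cutoff,
                        promoterUpstream = promUp))),
        "expression_enrichment")
    if (!is.null(elements))
        diag$elements <- writeDiag(
            rbind(cbind(condition = "tumor",
                        elementOverlapByBin(tumor, elements)),
                  cbind(condition = "normal",
                        elementOverlapByBin(normal, elements))),
            "element_overlap")
    if (!is.null(variantsT))
        diag$mutation_tumor <- writeDiag(
            cbind(condition = "tumor",
                  mutationRateByBin(tumor, variantsT)), "mutation_tumor")
    if (!is.null(variantsN))
        diag$mutation_normal <- writeDiag(
            cbind(condition = "normal",
                  mutationRateByBin(normal, variantsN)),
            "mutation_normal")

    stage <- NULL   # success: no failed_stage
    manifest$stages <- list(
        tfbs = list(tumor = length(tfbsT), normal = length(tfbsN)),
        peaks = list(tumor = length(peaksT), normal = length(peaksN)),
        tfcrs = list(tumor = length(tumor), normal = length(normal)),
        differential = list(
            gain = length(gainTfcrs(diff)),
            stable_tumor = length(stableTfcrs(diff, "tumor")),
            lost = length(lostTfcrs(diff)),
            stable_normal = length(stableTfcrs(diff, "normal")),
            nonoverlap_tumor = frac[["tumor"]],
            nonoverlap_normal = frac[["normal"]]),
        candidates = list(n = nrow(candidates),
                          n_selected = sum(candidates$selected)))
    manifest$correlation_split <- lapply(corSplit, function(s)
        s[c("threshold", "r_low", "p_low", "n_low", "r_high", "p_high",
            "n_high")])
    writeManifest()

    invisible(list(tumor = tumor, normal = normal, differential = diff,
                   candidates = candidates,
                   correlation_split = corSplit,
                   diagnostics = diag, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
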