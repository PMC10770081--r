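#' Parameters of the Gaussian-kernel TFCR caller
#'
#' Bundles the tunable constants of TFCR identification.  The defaults encode
#' the published procedure: each TFBS contributes a unit-height Gaussian of
#' width `sigma` = 300 bp centered on its midpoint; sites with kernel
#' intensity above `contribThreshold` = 0.1 at a density summit are its
#' contributors; the TFCR window extends `windowPad` = 150 bp (half the
#' bandwidth) beyond the farthest contributor.
#'
#' @slot sigma numeric(1). Gaussian kernel width parameter in bp (> 0).
#' @slot gridStep integer(1). Spacing of the density evaluation grid in bp.
#' @slot contribThreshold numeric(1). Kernel-intensity cutoff in (0, 1) used
#'   to decide which TFBS contribute to a summit.
#' @slot windowPad integer(1). Pad added to the maximal contributor distance
#'   when forming the TFCR window (bp, >= 0).
#' @slot minSummitDensity numeric(1). Optional minimum density for a summit
#'   to be reported (default 0: every strict local maximum is kept).
#'
#' @seealso [tfcrParams()] for the user constructor.
#' @exportClass TfcrParams
setClass("TfcrParams",
    representation(
        sigma = "numeric",
        gridStep = "integer",
        contribThreshold = "numeric",
        windowPad = "integer",
        minSummitDensity = "numeric"
    )
)

setValidity("TfcrParams", function(object) {
    msg <- character(0)
    if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
        object@sigma <= 0)
        msg <- c(msg, "'sigma' must be a single positive number")
    if (length(object@gridStep) != 1L || is.na(object@gridStep) ||
        object@gridStep < 1L)
        msg <- c(msg, "'gridStep' must be a single integer >= 1")
    if (length(object@contribThreshold) != 1L ||
        !is.finite(object@contribThreshold) ||
        object@contribThreshold <= 0 || object@contribThreshold >= 1)
        msg <- c(msg, "'contribThreshold' must lie strictly in (0, 1)")
    if (length(object@windowPad) != 1L || is.na(object@windowPad) ||
        object@windowPad < 0L)
        msg <- c(msg, "'windowPad' must be a single integer >= 0")
    if (length(object@minSummitDensity) != 1L ||
        !is.finite(object@minSummitDensity) || object@minSummitDensity < 0)
        msg <- c(msg, "'minSummitDensity' must be a single number >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct TFCR caller parameters
#'
#' @param sigma Gaussian kernel width parameter in bp (default 300).  The
#'   kernel is unit-height, `exp(-(x - mu)^2 / (2 * sigma^2))`, so the
#'   contribution threshold is scale-free.
#' @param gridStep density evaluation spacing in bp (default 10).  Summit
#'   coordinates are grid coordinates; at `sigma` = 300 sub-10 bp structure
#'   in the density is negligible.
#' @param contribThreshold kernel intensity above which a TFBS counts as
#'   contributing to a summit (default 0.1).  Equivalent to a distance
#'   cutoff of `sigma * sqrt(2 * log(1 / contribThreshold))` bp.
#' @param windowPad half-bandwidth pad added to the farthest contributor
#'   distance when forming the window (default 150 bp).
#' @param minSummitDensity minimum summit density (default 0).
#' @return A [TfcrParams-class] object.
#' @examples
#' tfcrParams()
#' tfcrParams(gridStep = 1)  # exact per-bp evaluation
#' @export
tfcrParams <- function(sigma = 300, gridStep = 10L, contribThreshold = 0.1,
                       windowPad = 150L, minSummitDensity = 0) {
    new("TfcrParams",
        sigma = as.numeric(sigma),
        gridStep = as.integer(gridStep),
        contribThreshold = as.numeric(contribThreshold),
        windowPad = as.integer(windowPad),
        minSummitDensity = as.numeric(minSummitDensity))
}

#' @describeIn TfcrParams-class maximal distance (bp) at which a TFBS can
#'   contribute to a summit, `sigma * sqrt(2 * log(1/contribThreshold))`.
#' @param object,x a `TfcrParams` object.
#' @export
contributionRadius <- function(x) {
    stopifnot(is(x, "TfcrParams"))
    x@sigma * sqrt(2 * log(1 / x@contribThreshold))
}

setMethod("show", "TfcrParams", function(object) {
    cat("TfcrParams: sigma=", object@sigma,
        " gridStep=", object@gridStep,
        " contribThreshold=", object@contribThreshold,
        " windowPad=", object@windowPad,
        " (contribution radius ", round(contributionRadius(object), 1),
        " bp)\n", sep = "")
})

#' Gaussian TFBS density profile on one chromosome
#'
#' The density at grid point `gridStart + i * gridStep` (0-based bp) is the
#' sum over TFBS of unit-height Gaussians centered at the site midpoints.
#'
#' @slot chrom character(1) chromosome name (length 0 for an empty profile).
#' @slot gridStart numeric(1) first evaluated coordinate (0-based bp).
#' @slot gridStep integer(1) grid spacing (bp).
#' @slot values numeric vector of densities, one per grid point.
#' @exportClass DensityProfile
setClass("DensityProfile",
    representation(
        chrom = "character",
        gridStart = "numeric",
        gridStep = "integer",
        values = "numeric"
    )
)

setValidity("DensityProfile", function(object) {
    if (length(object@values) && any(object@values < 0))
        return("density values must be nonnegative")
    if (length(object@values) && length(object@chrom) != 1L)
        return("nonempty profile needs a single chromosome name")
    TRUE
})

setMethod("show", "DensityProfile", function(object) {
    if (!length(object@values)) {
        cat("DensityProfile: empty\n")
    } else {
        cat("DensityProfile on ", object@chrom, ": ",
            length(object@values), " grid points [",
            object@gridStart, ", ",
            object@gridStart +
                (length(object@values) - 1L) * object@gridStep,
            "] step ", object@gridStep, " bp, max density ",
            signif(max(object@values), 5), "\n", sep = "")
    }
})

#' Grid coordinates of a density profile
#' @param x a [DensityProfile-class].
#' @return numeric vector of 0-based bp coordinates, one per grid value.
#' @export
profilePositions <- function(x) {
    stopifnot(is(x, "DensityProfile"))
    if (!length(x@values)) return(numeric(0))
    x@gridStart + (seq_along(x@values) - 1) * x@gridStep
}

#' Profile density values
#' @param x a [DensityProfile-class].
#' @export
profileValues <- function(x) {
    stopifnot(is(x, "DensityProfile"))
    x@values
}

#' Set of called TFCRs
#'
#' A `TFCRSet` is a `GRanges` of TFCR windows (stored 1-based closed, the
#' GRanges convention; the serialized table uses 0-based half-open BED
#' coordinates) with mandatory metadata columns:
#' \describe{
#'   \item{tfcr_id}{character identifier.}
#'   \item{summit}{integer, density-summit coordinate (0-based bp).}
#'   \item{tc}{integer TF complexity: distinct contributing TF names.}
#'   \item{sc}{numeric chromatin accessibility score (mean overlapping peak
#'     signal; 0 when no peak overlaps the window).}
#'   \item{tc_bin, sc_bin}{integer decile bins 0-9, or NA before binning.}
#'   \item{condition}{"tumor" or "normal".}
#'   \item{n_contrib}{integer count of contributing TFBS.}
#' }
#' An optional `contributing` column (`IntegerList` of indices into the TFBS
#' `GRanges` the set was called from) is present on freshly identified sets
#' and dropped on serialization.
#'
#' @seealso [identifyTfcrs()], [writeTfcrTable()], [assignDecileBins()].
#' @exportClass TFCRSet
setClass("TFCRSet", contains = "GRanges")

.TFCR_MCOLS <- c("tfcr_id", "summit", "tc", "sc", "tc_bin", "sc_bin",
                 "condition", "n_contrib")

setValidity("TFCRSet", function(object) {
    m <- mcols(object)
    missing <- setdiff(.TFCR_MCOLS, colnames(m))
    if (length(missing))
        return(paste0("missing metadata column(s): ",
                      paste(missing, collapse = ", ")))
    if (length(object)) {
        if (!all(m$condition %in% c("tumor", "normal")))
            return("'condition' must be 'tumor' or 'normal'")
        if (any(is.na(m$tc)) || any(m$tc < 1L))
            return("'tc' must be an integer >= 1")
        if (any(is.na(m$sc)) || any(m$sc < 0))
            return("'sc' must be nonnegative")
        bins <- c(m$tc_bin, m$sc_bin)
        if (any(!is.na(bins) & (bins < 0L | bins > 9L)))
            return("decile bins must lie in 0..9 (or NA)")
        if (anyDuplicated(m$tfcr_id))
            return("'tfcr_id' values must be unique")
    }
    TRUE
})

#' @rdname TFCRSet-class
#' @param gr a `GRanges` with the mandatory TFCR metadata columns.
#' @export
TFCRSet <- function(gr = GRanges()) {
    if (!length(gr) && !all(.TFCR_MCOLS %in% colnames(mcols(gr)))) {
        mcols(gr) <- DataFrame(
            tfcr_id = character(0), summit = integer(0), tc = integer(0),
            sc = numeric(0), tc_bin = integer(0), sc_bin = integer(0),
            condition = character(0), n_contrib = integer(0))
    }
    new("TFCRSet", gr)
}

setMethod("show", "TFCRSet", function(object) {
    n <- length(object)
    cond <- unique(tfcrCondition(object))
    cat("TFCRSet with ", n, " TFCR(s)",
        if (length(cond)) paste0(" [", paste(cond, collapse = "+"), "]"),
        "\n", sep = "")
    if (n) {
        cat("  TC: ", paste(range(tfComplexity(object)), collapse = "-"),
            "; SC: ", paste(signif(range(accessibilityScore(object)), 4),
                            collapse = "-"),
            "; bins ", if (all(is.na(decileBin(object, "tc"))))
                "unassigned" else "assigned", "\n", sep = "")
        methods::callNextMethod()
    }
})

#' TFCR accessors
#'
#' Accessor functions for the metadata of a [TFCRSet-class]; use these
#' rather than reaching into `mcols()`.
#'
#' @param x a `TFCRSet`.
#' @return `tfcrId`: character ids; `summits`: integer 0-based summit
#'   coordinates; `tfComplexity`: integer TC; `accessibilityScore`: numeric
#'   SC; `tfcrCondition`: condition labels; `decileBin`: integer bins (NA
#'   before [assignDecileBins()]); `contributingSites`: `IntegerList` of
#'   contributing TFBS indices, or NULL for sets read back from disk.
#' @name tfcr-accessors
NULL

#' @rdname tfcr-accessors
#' @export
tfcrId <- function(x) mcols(x)$tfcr_id

#' @rdname tfcr-accessors
#' @export
summits <- function(x) mcols(x)$summit

#' @rdname tfcr-accessors
#' @export
tfComplexity <- function(x) mcols(x)$tc

#' @rdname tfcr-accessors
#' @export
accessibilityScore <- function(x) mcols(x)$sc

#' @rdname tfcr-accessors
#' @export
tfcrCondition <- function(x) mcols(x)$condition

#' @rdname tfcr-accessors
#' @param axis `"tc"` or `"sc"`.
#' @export
decileBin <- function(x, axis = c("tc", "sc")) {
    axis <- match.arg(axis)
    mcols(x)[[paste0(axis, "_bin")]]
}

#' @rdname tfcr-accessors
#' @export
contributingSites <- function(x) mcols(x)$contributing

#' Tumor/normal differential TFCR classification
#'
#' Result of [classifyDifferential()].  Gain-TFCRs are tumor TFCRs whose
#' window shares no base pair with any normal TFCR window; lost-TFCRs are
#' the normal-only mirror; stable TFCRs are the overlapping members of each
#' side.  `gain` and `stableTumor` partition the tumor set, `lost` and
#' `stableNormal` the normal set.
#'
#' @slot gain,lost,stableTumor,stableNormal [TFCRSet-class] partitions.
#' @slot nonoverlapTumor,nonoverlapNormal numeric(1) fractions in `[0, 1]`
#'   of each condition's TFCRs with no cross-condition overlap.
#' @exportClass DifferentialTfcrs
setClass("DifferentialTfcrs",
    representation(
        gain = "TFCRSet",
        lost = "TFCRSet",
        stableTumor = "TFCRSet",
        stableNormal = "TFCRSet",
        nonoverlapTumor = "numeric",
        nonoverlapNormal = "numeric"
    )
)

setValidity("DifferentialTfcrs", function(object) {
    ok <- function(f) length(f) == 1L && (is.nan(f) || (f >= 0 && f <= 1))
    if (!ok(object@nonoverlapTumor) || !ok(object@nonoverlapNormal))
        return("non-overlap fractions must be single values in [0, 1]")
    TRUE
})

setMethod("show", "DifferentialTfcrs", function(object) {
    cat("DifferentialTfcrs:\n",
        "  gain:          ", length(object@gain), "\n",
        "  stable(tumor): ", length(object@stableTumor), "\n",
        "  lost:          ", length(object@lost), "\n",
        "  stable(normal):", length(object@stableNormal), "\n",
        "  non-overlap: tumor ",
        round(100 * object@nonoverlapTumor, 1), "%, normal ",
        round(100 * object@nonoverlapNormal, 1), "%\n", sep = "")
})

#' Differential set accessors
#' @param x a [DifferentialTfcrs-class] object.
#' @return a [TFCRSet-class] (`gainTfcrs`, `lostTfcrs`, `stableTfcrs`) or a
#'   named numeric of non-overlap fractions (`nonoverlapFractions`).
#' @name differential-accessors
NULL

#' @rdname differential-accessors
#' @export
gainTfcrs <- function(x) x@gain

#' @rdname differential-accessors
#' @export
lostTfcrs <- function(x) x@lost

#' @rdname differential-accessors
#' @param side `"tumor"` or `"normal"`.
#' @export
stableTfcrs <- function(x, side = c("tumor", "normal")) {
    side <- match.arg(side)
    if (side == "tumor") x@stableTumor else x@stableNormal
}

#' @rdname differential-accessors
#' @export
nonoverlapFractions <- function(x) {
    c(tumor = x@nonoverlapTumor, normal = x@nonoverlapNormal)
}
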