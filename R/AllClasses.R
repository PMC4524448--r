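#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
NULL

#' Read-1 tag layout
#'
#' Describes the structure of read 1 in a transcript-counting library:
#' a unique molecular identifier (UMI), an inline sample index, an
#' optional short spacer, and an anchored polyT stretch, in that order,
#' followed by the transcript-derived insert.
#'
#' @slot umiLength integer, UMI length in bases (default 12).
#' @slot indexLength integer, sample index length in bases (default 8).
#' @slot spacer character, fixed bases between index and polyT
#'   (default \code{"CG"}); matched greedily, 0 to \code{nchar(spacer)}
#'   bases are consumed.
#' @slot minPolyT integer, minimum length of the polyT run (default 10).
#' @slot indexWhitelist named character vector mapping sample labels
#'   (names) to index sequences (values); may be empty.
#' @slot maxIndexMismatches integer, maximum Hamming distance for index
#'   assignment (default 0).
#'
#' @exportClass TagLayout
setClass("TagLayout",
    representation(
        umiLength = "integer",
        indexLength = "integer",
        spacer = "character",
        minPolyT = "integer",
        indexWhitelist = "character",
        maxIndexMismatches = "integer"
    )
)

setValidity("TagLayout", function(object) {
    msg <- character()
    if (object@umiLength < 1L) msg <- c(msg, "umiLength must be positive")
    if (object@indexLength < 1L) msg <- c(msg, "indexLength must be positive")
    if (object@minPolyT < 1L) msg <- c(msg, "minPolyT must be positive")
    if (object@maxIndexMismatches < 0L)
        msg <- c(msg, "maxIndexMismatches must be non-negative")
    wl <- object@indexWhitelist
    if (length(wl)) {
        if (is.null(names(wl)) || any(!nzchar(names(wl))))
            msg <- c(msg, "indexWhitelist must be named by sample label")
        if (anyDuplicated(names(wl)))
            msg <- c(msg, "duplicate sample labels in indexWhitelist")
        if (any(nchar(wl) != object@indexLength))
            msg <- c(msg, "whitelist indices must have length indexLength")
        if (length(wl) > 1L) {
            d <- hammingMatrix(wl)
            if (min(d[upper.tri(d)]) <= object@maxIndexMismatches)
                msg <- c(msg, paste0(
                    "whitelist indices must be pairwise > ",
                    object@maxIndexMismatches, " mismatches apart"))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TagLayout
#'
#' @param umiLength UMI length in bases.
#' @param indexLength inline sample index length in bases.
#' @param spacer fixed bases between index and polyT; consumed greedily
#'   (0 up to \code{nchar(spacer)} bases) so earlier primer designs that
#'   lack it still parse.
#' @param minPolyT minimum T-run length; the run tolerates one non-T
#'   base per ten Ts to avoid discarding reads with a single miscall.
#' @param indexWhitelist named character vector: names are sample
#'   labels, values the index sequences.
#' @param maxIndexMismatches maximum Hamming distance for assigning an
#'   observed index to a whitelist entry.
#'
#' @return A \linkS4class{TagLayout} object.
#' @examples
#' tagLayout(indexWhitelist = c(s1 = "AACCGGTT", s2 = "TTGGCCAA"))
#' @export
tagLayout <- function(umiLength = 12L, indexLength = 8L, spacer = "CG",
                      minPolyT = 10L, indexWhitelist = character(),
                      maxIndexMismatches = 0L) {
    new("TagLayout",
        umiLength = as.integer(umiLength),
        indexLength = as.integer(indexLength),
        spacer = as.character(spacer),
        minPolyT = as.integer(minPolyT),
        indexWhitelist = indexWhitelist,
        maxIndexMismatches = as.integer(maxIndexMismatches))
}

setMethod("show", "TagLayout", function(object) {
    cat("TagLayout: UMI", object@umiLength, "b + index",
        object@indexLength, "b + spacer '", object@spacer,
        "' + polyT >=", object@minPolyT, "\n")
    cat("  whitelist:", length(object@indexWhitelist), "samples, <=",
        object@maxIndexMismatches, "index mismatches\n")
})

#' Two-state peak-calling HMM
#'
#' A hidden Markov model over binned read-2 counts with a background
#' and a peak state, Poisson emissions per state, fitted by
#' expectation-maximization.
#'
#' @slot lambda numeric length-2, Poisson means; background first
#'   (\code{lambda[1] < lambda[2]} enforced by state relabeling).
#' @slot transition 2x2 row-stochastic transition matrix
#'   (background, peak).
#' @slot initProb length-2 initial state distribution.
#' @slot logLik final log-likelihood.
#' @slot iterations EM iterations used.
#' @slot converged logical.
#' @slot degenerate logical; TRUE when the track carries no two-state
#'   structure (near-constant counts), in which case no peaks are called.
#'
#' @exportClass PeakModel
setClass("PeakModel",
    representation(
        lambda = "numeric",
        transition = "matrix",
        initProb = "numeric",
        logLik = "numeric",
        iterations = "integer",
        converged = "logical",
        degenerate = "logical"
    )
)

setValidity("PeakModel", function(object) {
    msg <- character()
    if (length(object@lambda) != 2L || any(object@lambda < 0))
        msg <- c(msg, "lambda must be two non-negative means")
    if (!object@degenerate && object@lambda[1] > object@lambda[2])
        msg <- c(msg, "background mean must not exceed peak mean")
    if (!all(dim(object@transition) == c(2L, 2L)) ||
        any(abs(rowSums(object@transition) - 1) > 1e-6))
        msg <- c(msg, "transition must be 2x2 row-stochastic")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PeakModel", function(object) {
    cat("PeakModel (2-state Poisson HMM)\n")
    cat(sprintf("  background mean %.4g, peak mean %.4g\n",
                object@lambda[1], object@lambda[2]))
    cat(sprintf("  logLik %.2f after %d EM iterations (%s)%s\n",
                object@logLik, object@iterations,
                if (object@converged) "converged" else "not converged",
                if (object@degenerate) "; degenerate track" else ""))
})

#' @describeIn PeakModel-class Poisson means (background, peak).
#' @param object A \code{PeakModel}.
#' @export
setGeneric("peakLambda", function(object) standardGeneric("peakLambda"))

#' @rdname PeakModel-class
#' @export
setMethod("peakLambda", "PeakModel", function(object) object@lambda)

#' Region-by-sample transcript-counting experiment
#'
#' A \code{RangedSummarizedExperiment} whose rows are peak regions
#' (optionally carrying the selected transcript-counting 3' end in the
#' row metadata) and whose single \code{"counts"} assay holds
#' non-duplicate read-2 counts per sample.  \code{colData} must carry a
#' \code{condition} column.
#'
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @exportClass TagCountExperiment
setClass("TagCountExperiment", contains = "RangedSummarizedExperiment")

setValidity("TagCountExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        k <- SummarizedExperiment::assay(object, "counts")
        if (any(k < 0) || any(k != round(k)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'condition' column")
    if (length(msg)) msg else TRUE
})

#' Construct a TagCountExperiment
#'
#' @param counts integer matrix, regions x samples.
#' @param regions \code{GRanges} of peak regions, one per row of
#'   \code{counts}; may carry TC 3' end columns in \code{mcols}.
#' @param condition factor or character of per-sample conditions; the
#'   first level is the reference for fold changes.
#' @param sampleNames optional sample labels (default from
#'   \code{colnames(counts)}).
#'
#' @return A \linkS4class{TagCountExperiment}.
#' @export
TagCountExperiment <- function(counts, regions, condition,
                               sampleNames = colnames(counts)) {
    counts <- as.matrix(counts)
    mode(counts) <- "integer"
    if (is.null(sampleNames))
        sampleNames <- paste0("sample", seq_len(ncol(counts)))
    colnames(counts) <- sampleNames
    if (!is.factor(condition)) condition <- factor(condition)
    stopifnot(length(condition) == ncol(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = regions,
        colData = S4Vectors::DataFrame(condition = condition,
                                       row.names = sampleNames))
    new("TagCountExperiment", se)
}

#' @describeIn TagCountExperiment-class per-sample size factors, or
#'   \code{NULL} before \code{\link{medianRatioSizeFactors}} has been
#'   applied.
#' @param object A \code{TagCountExperiment}.
#' @export
setGeneric("tagSizeFactors", function(object) standardGeneric("tagSizeFactors"))

#' @rdname TagCountExperiment-class
#' @export
setMethod("tagSizeFactors", "TagCountExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if ("sizeFactor" %in% colnames(cd)) {
        sf <- cd$sizeFactor
        names(sf) <- rownames(cd)
        sf
    } else NULL
})

setMethod("show", "TagCountExperiment", function(object) {
    callNextMethod()
    cond <- SummarizedExperiment::colData(object)$condition
    cat("conditions:", paste(levels(factor(cond)), table(cond),
                             sep = ":", collapse = " "), "\n")
})
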