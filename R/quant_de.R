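# Region-level quantification and negative-binomial differential
# abundance.
#
# Per-region, per-sample counts are non-duplicate read 2s whose
# leftmost base lies in the region.  Normalisation uses
# median-of-ratios size factors; each region is tested with a
# negative-binomial GLM Wald test on the condition coefficient, with a
# per-region method-of-moments dispersion shrunk toward a fitted
# mean-dispersion trend.  Low-mean regions are removed from multiple
# testing by independent filtering; the remainder are BH-adjusted.

#' Count read 2s per region and sample
#'
#' @param regions \code{GRanges} of regions.
#' @param pairs pair table with \code{sample} labels and duplicate
#'   flags.
#' @param samples optional character vector fixing column order;
#'   defaults to the sorted labels present.
#' @return A \linkS4class{TagCountExperiment} is \emph{not} built here;
#'   the bare integer matrix (regions x samples) is returned so callers
#'   can attach conditions.  Samples with zero total counts trigger a
#'   warning.
#' @export
countBySample <- function(regions, pairs, samples = NULL) {
    use <- pairs$both_mapped & !pairs$duplicate
    p <- pairs[use, , drop = FALSE]
    if (is.null(samples)) samples <- sort(unique(p$sample))
    counts <- matrix(0L, length(regions), length(samples),
                     dimnames = list(NULL, samples))
    if (nrow(p) && length(regions)) {
        hits <- GenomicRanges::findOverlaps(
            GenomicRanges::GRanges(p$r2_rname,
                                   IRanges::IRanges(p$r2_pos, p$r2_pos)),
            regions)
        if (length(hits)) {
            tab <- table(
                factor(S4Vectors::subjectHits(hits),
                       levels = seq_along(regions)),
                factor(p$sample[S4Vectors::queryHits(hits)],
                       levels = samples))
            counts <- matrix(as.integer(tab), nrow = length(regions),
                             dimnames = list(NULL, samples))
        }
    }
    zero <- colSums(counts) == 0L
    if (any(zero))
        warning("samples with zero counts: ",
                paste(samples[zero], collapse = ", "))
    counts
}

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over regions (restricted
#' to regions with all-positive counts) of the ratio of the sample's
#' count to the row geometric mean; factors are then rescaled by their
#' geometric mean so a depth-balanced experiment gets factors near 1.
#' If no region has all-positive counts the median falls back to each
#' sample's positive-count regions.
#'
#' @param counts integer matrix, regions x samples.
#' @return positive numeric vector of per-sample factors.
#' @export
medianRatioSizeFactors <- function(counts) {
    counts <- as.matrix(counts)
    logGeo <- rowMeans(log(counts))
    usable <- is.finite(logGeo)
    sf <- if (any(usable)) {
        apply(counts[usable, , drop = FALSE], 2L, function(k)
            exp(stats::median(log(k) - logGeo[usable])))
    } else {
        # no all-positive region: use each row's geometric mean over its
        # positive entries and take each sample's median over the rows
        # where it has a positive count
        logGeoPos <- apply(counts, 1L, function(k) {
            pos <- k > 0
            if (!any(pos)) NA_real_ else mean(log(k[pos]))
        })
        apply(counts, 2L, function(k) {
            keep <- k > 0 & is.finite(logGeoPos)
            if (!any(keep))
                stop("cannot compute size factors: no usable regions")
            exp(stats::median(log(k[keep]) - logGeoPos[keep]))
        })
    }
    if (any(!is.finite(sf)) || any(sf <= 0))
        stop("cannot compute size factors: degenerate count matrix")
    sf / exp(mean(log(sf)))
}

# Method-of-moments dispersion per region on normalised counts, pooled
# within condition, then shrunk on the log scale toward a fitted
# a0 + a1/mean trend.
estimateDispersions <- function(counts, sizeFactors, condition,
                                shrink = 0.8, minDisp = 1e-8,
                                maxDisp = 10) {
    q <- sweep(as.matrix(counts), 2L, sizeFactors, "/")
    lev <- levels(condition)
    num <- den <- numeric(nrow(q))
    for (l in lev) {
        sub <- q[, condition == l, drop = FALSE]
        if (ncol(sub) < 2L) next
        m <- rowMeans(sub)
        v <- apply(sub, 1L, stats::var)
        w <- ncol(sub) - 1L
        num <- num + w * (v - m)
        den <- den + w * m^2
    }
    raw <- ifelse(den > 0, num / den, NA_real_)
    raw <- pmin(pmax(raw, minDisp), maxDisp)
    baseMean <- rowMeans(q)
    fitIdx <- which(is.finite(raw) & raw > minDisp & baseMean > 0)
    trend <- rep(stats::median(raw[is.finite(raw)], na.rm = TRUE),
                 nrow(q))
    if (length(fitIdx) >= 10L) {
        fit <- try(stats::lm(raw[fitIdx] ~ I(1 / baseMean[fitIdx])),
                   silent = TRUE)
        if (!inherits(fit, "try-error")) {
            a <- stats::coef(fit)
            tr <- a[1L] + a[2L] / pmax(baseMean, 1e-8)
            pos <- is.finite(tr) & tr > 0
            trend[pos] <- tr[pos]
        }
    }
    trend <- pmin(pmax(trend, minDisp), maxDisp)
    disp <- exp(shrink * log(trend) +
                (1 - shrink) * log(pmax(raw, minDisp)))
    disp[!is.finite(disp)] <- trend[!is.finite(disp)]
    pmin(pmax(disp, minDisp), maxDisp)
}

#' Negative-binomial Wald test per region
#'
#' Fits, for each region, a negative-binomial GLM of counts on the
#' two-level condition with log size factors as offset and the shrunken
#' dispersion held fixed, and tests the condition coefficient with a
#' Wald statistic referred to a t distribution on
#' (samples - 2) degrees of freedom — a small-sample calibration in the
#' spirit of quasi-likelihood pipelines.  The log2 fold change is the
#' second condition level over the first.
#'
#' @param counts integer matrix, regions x samples.
#' @param sizeFactors from \code{\link{medianRatioSizeFactors}}.
#' @param condition two-level factor of per-sample conditions.
#' @param shrink dispersion shrinkage weight toward the trend, in
#'   [0, 1] (default 0.8).
#' @return data frame with \code{base_mean}, \code{dispersion},
#'   \code{log2_fold_change}, \code{p_value} (NA for all-zero
#'   regions), plus normalised counts as a \code{norm} matrix
#'   attribute.
#' @export
nbDifferentialTest <- function(counts, sizeFactors, condition,
                               shrink = 0.8) {
    counts <- as.matrix(counts)
    if (!is.factor(condition)) condition <- factor(condition)
    if (nlevels(condition) != 2L)
        stop("exactly two conditions are required")
    if (min(table(condition)) < 2L)
        stop("at least two samples per condition are required")
    if (length(sizeFactors) != ncol(counts))
        stop("one size factor per sample is required")
    disp <- estimateDispersions(counts, sizeFactors, condition,
                                shrink = shrink)
    q <- sweep(counts, 2L, sizeFactors, "/")
    baseMean <- rowMeans(q)
    off <- log(sizeFactors)
    df <- ncol(counts) - 2L
    lfc <- p <- rep(NA_real_, nrow(counts))
    for (i in seq_len(nrow(counts))) {
        k <- counts[i, ]
        if (all(k == 0L)) next
        theta <- 1 / disp[i]
        fit <- try(suppressWarnings(stats::glm(
            k ~ condition + offset(off),
            family = MASS::negative.binomial(theta = theta))),
            silent = TRUE)
        if (inherits(fit, "try-error")) next
        sm <- summary(fit)$coefficients
        if (nrow(sm) < 2L) next
        beta <- sm[2L, 1L]
        se <- sm[2L, 2L]
        if (abs(beta) < 1e-12) beta <- 0   # numerically null fit
        lfc[i] <- beta / log(2)
        if (beta == 0) {
            p[i] <- 1
        } else if (is.finite(se) && se > 0) {
            p[i] <- 2 * stats::pt(-abs(beta / se), df = df)
        } else if (abs(beta) < 1e-12) {
            p[i] <- 1   # perfect null fit: zero residual dispersion
        }
    }
    out <- data.frame(base_mean = baseMean, dispersion = disp,
                      log2_fold_change = lfc, p_value = p)
    attr(out, "norm") <- q
    out
}

#' Independent filtering and BH adjustment
#'
#' Scans a grid of base-mean quantile cutoffs (40 by default), BH-
#' adjusts the p-values of the regions above each cutoff, and keeps the
#' cutoff that maximises rejections at \code{alpha}; ties go to the
#' least filtering.  Regions below the chosen cutoff get a missing
#' adjusted p-value.
#'
#' @param results data frame from \code{\link{nbDifferentialTest}}.
#' @param alpha rejection level used to choose the cutoff (default
#'   0.05).
#' @param gridSize number of quantile cutoffs (default 40).
#' @return \code{results} with an \code{adjusted_p} column
#'   (\code{NA} exactly for filtered or untested regions) and the
#'   chosen cutoff in \code{attr(, "filter_threshold")}.
#' @export
applyIndependentFilter <- function(results, alpha = 0.05,
                                   gridSize = 40L) {
    p <- results$p_value
    bm <- results$base_mean
    tested <- !is.na(p)
    thetas <- unique(stats::quantile(bm[tested],
                                     probs = seq(0, 0.95,
                                                 length.out = gridSize),
                                     names = FALSE))
    best <- -1L
    bestCut <- -Inf
    for (cut in sort(thetas)) {
        keep <- tested & bm >= cut
        if (!any(keep)) next
        rej <- sum(stats::p.adjust(p[keep], method = "BH") <= alpha)
        if (rej > best) {
            best <- rej
            bestCut <- cut
        }
    }
    keep <- tested & bm >= bestCut
    adj <- rep(NA_real_, length(p))
    adj[keep] <- stats::p.adjust(p[keep], method = "BH")
    results$adjusted_p <- adj
    attr(results, "filter_threshold") <- bestCut
    results
}

#' Filter annotated results into the final hit list
#'
#' Keeps rows with adjusted p-value at or below \code{alpha}, absolute
#' fold change at or above \code{minFC} (skipped when \code{minFC} is
#' \code{NULL}), a distance inside the requested proximity window and a
#' consistent region, ordered by ascending adjusted p-value.
#'
#' @param annotated data frame joining \code{\link{annotateEnds}} and
#'   test columns (\code{adjusted_p}, \code{log2_fold_change}).
#' @param alpha adjusted p-value cutoff (default 0.05, inclusive).
#' @param minFC fold-change cutoff on the natural scale (default 2,
#'   inclusive); \code{NULL} disables it.
#' @param window \code{"relaxed"} or \code{"stringent"}.
#' @return the filtered, ordered data frame.
#' @export
callHits <- function(annotated, alpha = 0.05, minFC = 2,
                     window = c("relaxed", "stringent")) {
    window <- match.arg(window)
    keep <- !is.na(annotated$adjusted_p) & annotated$adjusted_p <= alpha
    if (!is.null(minFC))
        keep <- keep & !is.na(annotated$log2_fold_change) &
            2^abs(annotated$log2_fold_change) >= minFC
    keep <- keep & if (window == "stringent") annotated$passes_stringent
                   else annotated$passes_relaxed
    keep <- keep & annotated$passes_region_consistency
    orderGeneList(annotated[keep, , drop = FALSE])
}
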