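# HMM peak calling on binned read-2 coverage.
#
# All read 2s of an experiment (samples pooled) are assigned to fixed
# 100-bp bins by leftmost mapped base, with duplicate-flagged reads and
# reads carrying more than two mismatches ignored.  A two-state hidden
# Markov model (background / peak, Poisson emissions) is fitted by EM,
# bins with posterior peak probability above a threshold are selected,
# and maximal runs of adjacent selected bins are merged into regions.

#' Bin read-2 alignments
#'
#' @param pairs pair table from \code{\link{pairAlignments}} with
#'   duplicate flags set; read-2 anchor columns are used.
#' @param binSize bin width in bases (default 100).
#' @param maxMismatches read 2s with more mismatches are ignored
#'   (default 2).
#' @return named list of integer count vectors, one per reference; bin
#'   \code{i} covers bases \code{(i-1)*binSize+1 .. i*binSize}.
#' @export
binReads <- function(pairs, binSize = 100L, maxMismatches = 2L) {
    use <- pairs$both_mapped & !pairs$duplicate &
        pairs$r2_mismatches <= maxMismatches
    pairs <- pairs[use, , drop = FALSE]
    bin <- (pairs$r2_pos - 1L) %/% binSize + 1L
    out <- lapply(split(bin, pairs$r2_rname), function(b)
        tabulate(b, nbins = max(b)))
    out[order(names(out))]
}

poissonLogEmission <- function(x, lambda) {
    lambda <- max(lambda, 1e-6)
    stats::dpois(x, lambda, log = TRUE)
}

# Forward-backward pass for one count vector under a 2-state Poisson
# HMM, in log space.  Returns per-bin posteriors, expected transition
# counts and the sequence log-likelihood.
forwardBackward <- function(x, lambda, logA, logPi) {
    Tn <- length(x)
    le <- cbind(poissonLogEmission(x, lambda[1]),
                poissonLogEmission(x, lambda[2]))
    la <- matrix(-Inf, Tn, 2L)
    lb <- matrix(0, Tn, 2L)
    la[1L, ] <- logPi + le[1L, ]
    for (t in seq_len(Tn - 1L) + 1L) {
        la[t, 1L] <- logSumExp(la[t - 1L, ] + logA[, 1L]) + le[t, 1L]
        la[t, 2L] <- logSumExp(la[t - 1L, ] + logA[, 2L]) + le[t, 2L]
    }
    ll <- logSumExp(la[Tn, ])
    for (t in rev(seq_len(Tn - 1L))) {
        lb[t, 1L] <- logSumExp(logA[1L, ] + le[t + 1L, ] + lb[t + 1L, ])
        lb[t, 2L] <- logSumExp(logA[2L, ] + le[t + 1L, ] + lb[t + 1L, ])
    }
    lg <- la + lb - ll
    gamma <- pmin(pmax(exp(lg), 0), 1)  # guard float ulps beyond [0,1]
    xi <- matrix(0, 2L, 2L)
    if (Tn > 1L) {
        for (i in 1:2) for (j in 1:2) {
            v <- la[-Tn, i] + logA[i, j] + le[-1L, j] + lb[-1L, j] - ll
            xi[i, j] <- sum(exp(v))
        }
    }
    list(gamma = gamma, xi = xi, logLik = ll, firstGamma = gamma[1L, ])
}

#' Fit the two-state peak model by EM
#'
#' Emission means, transition matrix and initial distribution are
#' estimated by Baum-Welch over all references jointly (each reference
#' is an independent chain).  Initialization is deterministic and
#' data-driven: the background mean starts at the mean of the lower 95%
#' of counts and the peak mean at the mean of the top 5%, with a
#' background-favouring transition prior (background-to-background
#' 0.999, peak-to-peak 0.9).  States are relabeled after fitting so the
#' background mean is the smaller one.  A track whose counts carry no
#' two-state structure (constant counts) yields a degenerate model from
#' which no peaks are called.
#'
#' @param track list of per-reference integer count vectors from
#'   \code{\link{binReads}} (a bare integer vector is accepted).
#' @param maxIterations EM iteration cap (default 200).
#' @param tol absolute log-likelihood convergence tolerance
#'   (default 1e-6).
#' @return A \linkS4class{PeakModel}.
#' @export
fitPeakModel <- function(track, maxIterations = 200L, tol = 1e-6) {
    if (!is.list(track)) track <- list(track)
    x <- unlist(track, use.names = FALSE)
    if (!length(x) || all(x == 0))
        stop("no_signal: all bins are empty")
    if (length(unique(x)) == 1L) {
        return(new("PeakModel", lambda = c(x[1L], x[1L]),
                   transition = matrix(c(0.999, 0.001, 0.1, 0.9), 2L,
                                       byrow = TRUE),
                   initProb = c(0.999, 0.001), logLik = NA_real_,
                   iterations = 0L, converged = TRUE, degenerate = TRUE))
    }
    q95 <- stats::quantile(x, 0.95, names = FALSE)
    lambda <- c(mean(x[x <= q95]), mean(x[x > q95]))
    if (!is.finite(lambda[2]) || lambda[2] <= lambda[1])
        lambda[2] <- lambda[1] * 5 + 1
    A <- matrix(c(0.999, 0.001, 0.1, 0.9), 2L, byrow = TRUE)
    piv <- c(0.999, 0.001)
    ll <- -Inf
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(maxIterations)) {
        logA <- log(A)
        logPi <- log(piv)
        fb <- lapply(track, forwardBackward, lambda = lambda,
                     logA = logA, logPi = logPi)
        newLl <- sum(vapply(fb, `[[`, numeric(1L), "logLik"))
        gamma <- do.call(rbind, lapply(fb, `[[`, "gamma"))
        xi <- Reduce(`+`, lapply(fb, `[[`, "xi"))
        first <- Reduce(`+`, lapply(fb, `[[`, "firstGamma"))
        lambda <- pmax(colSums(gamma * x) / pmax(colSums(gamma), 1e-12),
                       1e-6)
        rs <- rowSums(xi)
        if (all(rs > 0)) A <- xi / rs
        A <- pmin(pmax(A, 1e-9), 1 - 1e-9)
        A <- A / rowSums(A)
        piv <- pmax(first / sum(first), 1e-9)
        piv <- piv / sum(piv)
        if (abs(newLl - ll) < tol) {
            ll <- newLl
            converged <- TRUE
            break
        }
        ll <- newLl
    }
    if (lambda[1] > lambda[2]) {   # relabel: background is the low mean
        lambda <- rev(lambda)
        A <- A[2:1, 2:1]
        piv <- rev(piv)
    }
    new("PeakModel", lambda = lambda, transition = A, initProb = piv,
        logLik = ll, iterations = iter, converged = converged,
        degenerate = FALSE)
}

#' Posterior peak probability per bin
#'
#' @param track list of per-reference count vectors (or one vector).
#' @param model fitted \linkS4class{PeakModel}.
#' @return list of numeric vectors of posterior peak-state
#'   probabilities, parallel to \code{track}.
#' @export
binPosteriors <- function(track, model) {
    if (!is.list(track)) track <- list(track)
    if (model@degenerate)
        return(lapply(track, function(x) rep(0, length(x))))
    logA <- log(model@transition)
    logPi <- log(model@initProb)
    lapply(track, function(x)
        forwardBackward(x, model@lambda, logA, logPi)$gamma[, 2L])
}

#' Call peak regions from a fitted model
#'
#' Bins with posterior peak probability at or above the threshold are
#' selected; maximal runs of adjacent selected bins on one reference
#' are merged into a single region whose \code{peak_probability} is the
#' maximum posterior over its member bins.
#'
#' @param track list of per-reference count vectors from
#'   \code{\link{binReads}}.
#' @param model fitted \linkS4class{PeakModel}.
#' @param threshold posterior selection threshold in (0, 1), default
#'   0.5.
#' @param binSize bin width used to build the track.
#' @return \code{GRanges} of regions (1-based inclusive), sorted and
#'   non-overlapping per reference, with metadata columns
#'   \code{peak_probability}, \code{first_bin} and \code{last_bin}.
#' @export
callRegions <- function(track, model, threshold = 0.5, binSize = 100L) {
    if (!is.list(track)) track <- list(track)
    post <- binPosteriors(track, model)
    out <- lapply(names(track), function(ref) {
        p <- post[[match(ref, names(track))]]
        sel <- which(p >= threshold)
        if (!length(sel)) return(NULL)
        grp <- cumsum(c(1L, diff(sel) != 1L))
        runs <- split(sel, grp)
        data.frame(
            ref = ref,
            first = vapply(runs, min, integer(1L)),
            last = vapply(runs, max, integer(1L)),
            prob = vapply(runs, function(b) max(p[b]), numeric(1L)))
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        return(GenomicRanges::GRanges(
            peak_probability = numeric(), first_bin = integer(),
            last_bin = integer()))
    gr <- GenomicRanges::GRanges(
        seqnames = out$ref,
        ranges = IRanges::IRanges(start = (out$first - 1L) * binSize + 1L,
                                  end = out$last * binSize),
        peak_probability = out$prob,
        first_bin = out$first, last_bin = out$last)
    sort(gr)
}
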