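# Replicates-versus-depth permutation experiment.
#
# Per-condition read pools are downsampled to a common size, the reads
# of each pool are reassigned at random to k pseudo-samples via fake
# sample labels, and the whole pipeline is rerun for every (k,
# repetition) to tabulate how many TC 3' ends show differential
# abundance as the number of replicate pairs grows at constant total
# sequencing.

#' Downsample a pair table
#'
#' Uniform random sample of exactly \code{n} read pairs, both mates
#' kept together (the table is pair-level, so pairing is preserved by
#' construction).
#'
#' @param pairs pair table.
#' @param n pairs to keep; an error if fewer are available.
#' @param seed optional RNG seed.
#' @export
downsamplePairs <- function(pairs, n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (nrow(pairs) < n)
        stop("cannot downsample ", nrow(pairs), " pairs to ", n)
    if (nrow(pairs) == n) return(pairs)
    pairs[sort(sample(nrow(pairs), n)), , drop = FALSE]
}

#' Assign merged reads to pseudo-samples
#'
#' Each pair is assigned independently and uniformly to one of
#' \code{k} pseudo-sample labels (multinomial split, not a balanced
#' partition).
#'
#' @param pairs pair table.
#' @param k number of pseudo-samples (at least 2).
#' @param prefix label prefix.
#' @param seed optional RNG seed.
#' @return \code{pairs} with the \code{sample} column replaced by
#'   pseudo-sample labels \code{<prefix>01..<prefix>k}.
#' @export
assignPseudoSamples <- function(pairs, k, prefix = "p", seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (k < 2L) stop("at least two pseudo-samples are required")
    pairs$sample <- sprintf("%s%02d", prefix,
                            sample.int(k, nrow(pairs), replace = TRUE))
    pairs
}

#' Run the replicates-versus-depth experiment
#'
#' For every combination of pseudo-sample pair count \code{k} and
#' repetition, both condition pools are split into \code{k}
#' pseudo-samples each, duplicates are re-marked within each merged
#' pool, the full pipeline is rerun, and the number of TC 3' ends with
#' an adjusted p-value at or below \code{alpha} under the relaxed
#' proximity window is recorded.
#'
#' @param pairs1,pairs2 pair tables for condition 1 and condition 2
#'   (already merged per condition).
#' @param genome,annotation as in \code{\link{runPipeline}}.
#' @param kRange pseudo-sample pair counts to scan (default 2:11).
#' @param reps repetitions per k (default 10).
#' @param readsPerCondition optional downsampling target per condition
#'   pool, applied once before the scan.
#' @param alpha significance level (default 0.05).
#' @param seed base RNG seed; each (k, repetition) derives its own.
#' @param ... further arguments to \code{\link{runPipeline}}.
#' @return data frame with one row per (k, repetition):
#'   \code{n_significant}, \code{n_regions} and
#'   \code{mean_counts_per_pseudo_sample}.
#' @export
runPermutationExperiment <- function(pairs1, pairs2, genome, annotation,
                                     kRange = 2:11, reps = 10L,
                                     readsPerCondition = NULL,
                                     alpha = 0.05, seed = 1L, ...) {
    if (!is.null(readsPerCondition)) {
        pairs1 <- downsamplePairs(pairs1, readsPerCondition, seed)
        pairs2 <- downsamplePairs(pairs2, readsPerCondition, seed + 1L)
    }
    pairs1 <- markDuplicates(pairs1)
    pairs2 <- markDuplicates(pairs2)
    out <- vector("list", length(kRange) * reps)
    i <- 0L
    for (k in kRange) for (r in seq_len(reps)) {
        i <- i + 1L
        set.seed(seed + 7919L * k + r)
        p1 <- assignPseudoSamples(pairs1, k, prefix = "a")
        p2 <- assignPseudoSamples(pairs2, k, prefix = "b")
        samples <- data.frame(
            sample = c(sprintf("a%02d", seq_len(k)),
                       sprintf("b%02d", seq_len(k))),
            condition = rep(c("cond1", "cond2"), each = k))
        run <- runPipeline(rbind(p1, p2), genome, annotation, samples,
                           alpha = alpha, minFC = NULL,
                           window = "relaxed", ...)
        out[[i]] <- data.frame(
            k = k, repetition = r,
            n_significant = nrow(run$hits),
            n_regions = length(run$regions),
            mean_counts_per_pseudo_sample =
                mean(colSums(SummarizedExperiment::assay(run$tce,
                                                         "counts"))))
    }
    do.call(rbind, out)
}
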