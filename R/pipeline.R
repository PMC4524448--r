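# End-to-end driver: duplicate-marked alignments to the gene-list
# table.

#' Run the full transcript-counting pipeline
#'
#' Takes pre-aligned records, marks UMI-aware duplicates, calls peak
#' regions from pooled read-2 bins, predicts and filters TC 3' ends,
#' counts read 2s per region and sample, tests differential abundance
#' between the two conditions, associates ends with the annotation and
#' assembles the gene-list table.
#'
#' @param alignments either a SAM record data frame from
#'   \code{\link{readSam}} or a pair table from
#'   \code{\link{pairAlignments}}.
#' @param genome named \code{DNAStringSet}.
#' @param annotation data frame as \code{\link{readAnnotation}}.
#' @param samples data frame with \code{sample} and \code{condition};
#'   condition order fixes the fold-change direction (second level
#'   over first).
#' @param sampleMap optional named vector translating read-name index
#'   tokens to sample labels (e.g. a \code{TagLayout} whitelist).
#' @param blacklist transcript IDs excluded from annotation.
#' @param falseEnds known-false 3' end list (see
#'   \code{\link{filterCandidates}}).
#' @param binSize,maxMismatches,threshold peak-calling parameters.
#' @param minSupport minimum reads per TC 3' end.
#' @param alpha adjusted p-value level for independent filtering and
#'   hit calling.
#' @param minFC fold-change cutoff for \code{hits} (\code{NULL}
#'   disables).
#' @param window proximity window for \code{hits}.
#' @return list with \code{pairs}, \code{model}, \code{regions} (with
#'   selected ends), \code{candidates}, \code{tce}
#'   (\linkS4class{TagCountExperiment}), \code{results},
#'   \code{annotated}, \code{geneList} and \code{hits}.
#' @export
runPipeline <- function(alignments, genome, annotation, samples,
                        sampleMap = NULL, blacklist = character(),
                        falseEnds = NULL, binSize = 100L,
                        maxMismatches = 2L, threshold = 0.5,
                        minSupport = 3L, alpha = 0.05, minFC = 2,
                        window = "relaxed") {
    pairs <- if ("r2_pos" %in% colnames(alignments)) alignments
             else pairAlignments(alignments, sampleMap = sampleMap)
    pairs <- markDuplicates(pairs)
    track <- binReads(pairs, binSize = binSize,
                      maxMismatches = maxMismatches)
    model <- fitPeakModel(track)
    regions <- callRegions(track, model, threshold = threshold,
                           binSize = binSize)
    ends <- regionEnds(regions, pairs, genome, minSupport = minSupport,
                       falseEnds = falseEnds)
    counts <- countBySample(ends$regions, pairs,
                            samples = samples$sample)
    condition <- factor(samples$condition,
                        levels = unique(samples$condition))
    sf <- medianRatioSizeFactors(counts)
    results <- nbDifferentialTest(counts, sf, condition)
    results <- applyIndependentFilter(results, alpha = alpha)
    annotated <- annotateEnds(ends$regions, annotation,
                              blacklist = blacklist)
    tce <- TagCountExperiment(counts, ends$regions, condition,
                              sampleNames = samples$sample)
    SummarizedExperiment::colData(tce)$sizeFactor <- sf
    geneList <- buildGeneList(annotated, results, counts,
                              attr(results, "norm"))
    hits <- callHits(geneList, alpha = alpha, minFC = minFC,
                     window = window)
    list(pairs = pairs, model = model, regions = ends$regions,
         candidates = ends$candidates, tce = tce, results = results,
         annotated = annotated, geneList = geneList, hits = hits)
}

#' Assemble the gene-list table
#'
#' Joins per-region annotation, test results and raw/normalised counts
#' into the documented fixed column order.
#'
#' @param annotated data frame from \code{\link{annotateEnds}}.
#' @param results data frame from \code{\link{applyIndependentFilter}}.
#' @param counts,norm raw and normalised count matrices (regions x
#'   samples).
#' @return data frame ordered by ascending adjusted p-value, missing
#'   last.
#' @export
buildGeneList <- function(annotated, results, counts, norm) {
    out <- cbind(annotated[, c("chromosome", "region_start",
                               "region_end", "tc_position", "tc_strand",
                               "tc_support", "transcript_id", "gene_id",
                               "gene_name", "biotype", "distance")],
                 results[, c("log2_fold_change", "p_value",
                             "adjusted_p", "base_mean")],
                 annotated[, c("passes_stringent", "passes_relaxed",
                               "passes_region_consistency")])
    counts <- as.matrix(counts)
    norm <- as.matrix(norm)
    colnames(counts) <- paste0("count_", colnames(counts))
    colnames(norm) <- paste0("norm_", colnames(norm))
    out <- cbind(out, counts, round(norm, 3))
    orderGeneList(out)
}
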