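# Transcript-counting 3' end prediction and artifact filtering.
#
# Read 1 is primed off the polyA tail, so after tag trimming its
# alignment reads antisense into the transcript and the aligned base
# closest to the former polyT junction marks the transcript 3' end:
# a forward read-1 alignment implies a minus-strand transcript ending
# at the alignment's leftmost base, a reverse alignment a plus-strand
# transcript ending at the rightmost base.  Candidate ends are dropped
# when supported by fewer than three read pairs or when the 10 bases
# immediately 3' of the end (in transcript orientation) are A-enriched,
# the signature of internal oligo-dT mispriming.

# The empirically determined A-enrichment patterns; A matches A, B
# matches C, G or T (IUPAC "not A").
POLYA_PATTERNS <- c(
    "AAABAAABBB", "AAABAABABB", "AAABABAABB", "AABAAAABBB",
    "AABAAABABB", "AABABAAABB", "ABAAAAABBB", "ABAAAABABB",
    "ABAAABAABB", "ABAABAAABB", "ABABAAAABB", "AABAABAABB")

polyaPatternRegex <- function(pattern) {
    paste0("^", gsub("B", "[CGT]", gsub("A", "A", pattern, fixed = TRUE),
                     fixed = TRUE), "$")
}

#' Predict transcript 3' ends from read-1 alignments
#'
#' @param pairs pair table from \code{\link{pairAlignments}}.
#' @return \code{pairs} with columns \code{end_reference},
#'   \code{end_position} and \code{end_strand} (transcript strand, the
#'   opposite of the read-1 alignment strand); \code{NA} when read 1 is
#'   unmapped.
#' @export
endPosition <- function(pairs) {
    mapped <- pairs$r1_mapped
    pairs$end_reference <- ifelse(mapped, pairs$reference, NA_character_)
    pairs$end_position <- ifelse(
        !mapped, NA_integer_,
        ifelse(pairs$r1_reverse,
               pairs$r1_pos + pairs$r1_width - 1L,  # '+' transcript
               pairs$r1_pos))                       # '-' transcript
    pairs$end_strand <- ifelse(!mapped, NA_character_,
                               ifelse(pairs$r1_reverse, "+", "-"))
    pairs
}

#' Collect candidate 3' ends per region
#'
#' For every region, the read 2s whose leftmost mapped base lies inside
#' it are identified, each paired read 1 contributes its predicted end,
#' and candidates are the distinct (position, strand) ends with their
#' supporting non-duplicate pair counts.
#'
#' @param regions \code{GRanges} from \code{\link{callRegions}}.
#' @param pairs pair table with duplicate flags and
#'   \code{\link{endPosition}} columns.
#' @return data frame with \code{region_idx} (row in \code{regions}),
#'   \code{reference}, \code{position}, \code{strand}, \code{support}.
#' @export
collectCandidates <- function(regions, pairs) {
    use <- pairs$both_mapped & !pairs$duplicate & pairs$r1_mapped &
        !is.na(pairs$end_position)
    p <- pairs[use, , drop = FALSE]
    empty <- data.frame(region_idx = integer(), reference = character(),
                        position = integer(), strand = character(),
                        support = integer())
    if (!nrow(p) || !length(regions)) return(empty)
    hits <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(p$r2_rname,
                               IRanges::IRanges(p$r2_pos, p$r2_pos)),
        regions)
    if (!length(hits)) return(empty)
    dt <- data.table(region_idx = S4Vectors::subjectHits(hits),
                     reference = p$end_reference[S4Vectors::queryHits(hits)],
                     position = p$end_position[S4Vectors::queryHits(hits)],
                     strand = p$end_strand[S4Vectors::queryHits(hits)])
    out <- dt[, list(support = .N),
              by = c("region_idx", "reference", "position", "strand")]
    out <- as.data.frame(out)
    out[order(out$region_idx, out$position, out$strand), , drop = FALSE]
}

#' Internal-polyA mispriming verdict for a downstream context
#'
#' A 10-base downstream sequence is A-enriched when its first four
#' bases are all A (\code{polyA_start}), when it contains more than six
#' As in total (\code{polyA_total}), or when it matches one of the
#' twelve empirically determined patterns with B read as C, G or T
#' (\code{polyA_pattern}).  \code{N} counts as non-A throughout.
#' Shorter sequences (contig edge) are tested with whichever rules
#' still apply.
#'
#' @param downstream10 character vector of downstream contexts (up to
#'   10 bases, transcript orientation).
#' @return data frame with logical \code{artifact} and \code{reason}
#'   (\code{NA} when not an artifact).
#' @examples
#' polyaArtifact(c("AAAAGCTGCT", "AACAACAACC", "ACGTACGTAC"))
#' @export
polyaArtifact <- function(downstream10) {
    s <- toupper(downstream10)
    nA <- nchar(s) - nchar(gsub("A", "", s, fixed = TRUE))
    start4 <- nchar(s) >= 4L & substr(s, 1L, 4L) == "AAAA"
    total <- nA > 6L
    pat <- rep(FALSE, length(s))
    full <- nchar(s) == 10L
    if (any(full)) {
        for (pattern in POLYA_PATTERNS) {
            pat[full] <- pat[full] | grepl(polyaPatternRegex(pattern),
                                           s[full])
        }
    }
    reason <- rep(NA_character_, length(s))
    reason[pat] <- "polyA_pattern"
    reason[total] <- "polyA_total"
    reason[start4] <- "polyA_start"
    data.frame(artifact = start4 | total | pat, reason = reason)
}

#' Genomic context 3' of a position, in transcript orientation
#'
#' @param genome named \code{DNAStringSet}.
#' @param reference,position,strand parallel vectors describing ends.
#' @param n context length (default 10); truncated at contig edges.
#' @return character vector of downstream sequences.
#' @export
downstreamContext <- function(genome, reference, position, strand,
                              n = 10L) {
    vapply(seq_along(position), function(i) {
        chr <- genome[[reference[i]]]
        len <- length(chr)
        if (strand[i] == "+") {
            from <- position[i] + 1L
            to <- min(position[i] + n, len)
            if (from > to) return("")
            as.character(Biostrings::subseq(chr, from, to))
        } else {
            from <- max(1L, position[i] - n)
            to <- position[i] - 1L
            if (from > to) return("")
            as.character(Biostrings::reverseComplement(
                Biostrings::subseq(chr, from, to)))
        }
    }, character(1L))
}

#' Apply support and mispriming filters to candidate ends
#'
#' Candidates supported by fewer than \code{minSupport} pairs are
#' marked \code{low_support}; the rest are tested with
#' \code{\link{polyaArtifact}} on their downstream genomic context.
#' Positions on a supplied known-false-ends list are marked
#' \code{known_false_end} and excluded from selection.
#'
#' @param candidates data frame from \code{\link{collectCandidates}}.
#' @param genome named \code{DNAStringSet}.
#' @param minSupport minimum supporting read pairs (default 3).
#' @param falseEnds optional data frame with \code{reference},
#'   \code{position}, \code{strand} of ends known not to be true
#'   transcript ends.
#' @return \code{candidates} with \code{downstream10},
#'   \code{artifact} and \code{reason} columns.
#' @export
filterCandidates <- function(candidates, genome, minSupport = 3L,
                             falseEnds = NULL) {
    n <- nrow(candidates)
    candidates$downstream10 <- if (n) {
        downstreamContext(genome, candidates$reference,
                          candidates$position, candidates$strand)
    } else character()
    verdict <- polyaArtifact(candidates$downstream10)
    low <- candidates$support < minSupport
    verdict$reason[low] <- "low_support"
    verdict$artifact <- verdict$artifact | low
    if (!is.null(falseEnds) && nrow(falseEnds) && n) {
        knownKey <- paste(falseEnds$reference, falseEnds$position,
                          falseEnds$strand)
        hit <- paste(candidates$reference, candidates$position,
                     candidates$strand) %in% knownKey
        verdict$artifact[hit] <- TRUE
        verdict$reason[hit] <- "known_false_end"
    }
    candidates$artifact <- verdict$artifact
    candidates$reason <- verdict$reason
    candidates
}

#' Select the representative 3' end of a region
#'
#' The non-artifact candidate with the highest support wins; ties go to
#' the smallest genomic position.  Returns \code{NULL} when every
#' candidate is filtered.
#'
#' @param candidates filtered candidates of one region.
#' @return single-row data frame or \code{NULL}.
#' @export
selectRegionEnd <- function(candidates) {
    ok <- candidates[!candidates$artifact, , drop = FALSE]
    if (!nrow(ok)) return(NULL)
    ok[order(-ok$support, ok$position), , drop = FALSE][1L, , drop = FALSE]
}

#' Predict, filter and select TC 3' ends for all regions
#'
#' @param regions \code{GRanges} from \code{\link{callRegions}}.
#' @param pairs pair table with duplicate flags (end positions are
#'   computed here if absent).
#' @param genome named \code{DNAStringSet}.
#' @inheritParams filterCandidates
#' @return list with \code{regions}: the input \code{GRanges} with
#'   metadata columns \code{tc_position}, \code{tc_strand},
#'   \code{tc_support} (\code{NA} where no end survived), and
#'   \code{candidates}: all candidates with verdicts.
#' @export
regionEnds <- function(regions, pairs, genome, minSupport = 3L,
                       falseEnds = NULL) {
    if (!"end_position" %in% colnames(pairs))
        pairs <- endPosition(pairs)
    cand <- collectCandidates(regions, pairs)
    cand <- filterCandidates(cand, genome, minSupport = minSupport,
                             falseEnds = falseEnds)
    pos <- rep(NA_integer_, length(regions))
    strand <- rep(NA_character_, length(regions))
    support <- rep(NA_integer_, length(regions))
    for (i in unique(cand$region_idx)) {
        sel <- selectRegionEnd(cand[cand$region_idx == i, , drop = FALSE])
        if (!is.null(sel)) {
            pos[i] <- sel$position
            strand[i] <- sel$strand
            support[i] <- sel$support
        }
    }
    S4Vectors::mcols(regions)$tc_position <- pos
    S4Vectors::mcols(regions)$tc_strand <- strand
    S4Vectors::mcols(regions)$tc_support <- support
    list(regions = regions, candidates = cand)
}
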