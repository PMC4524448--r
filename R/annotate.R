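# Association of TC 3' ends with annotated transcript 3' ends.
#
# Each selected end is matched to the nearest annotated transcript 3'
# end on the same chromosome and strand (blacklisted transcripts
# removed first).  The distance is signed in transcript orientation:
# negative means the annotated end lies 5' of the TC end, positive 3'
# of it, so the asymmetric proximity windows read directly as
# "-100 towards the 5', +100 / +5000 towards the 3'".

#' Nearest annotated transcript 3' end
#'
#' @param tcEnds data frame with \code{reference}, \code{position},
#'   \code{strand} (one row per TC 3' end).
#' @param annotation data frame from \code{\link{readAnnotation}}.
#' @param blacklist character vector of transcript IDs to drop before
#'   searching.
#' @return data frame parallel to \code{tcEnds} with
#'   \code{transcript_id}, \code{gene_id}, \code{gene_name},
#'   \code{biotype}, \code{annotated_end} and signed \code{distance};
#'   all \code{NA} when the chromosome/strand has no (non-blacklisted)
#'   transcript.  Equidistant candidates are resolved by
#'   lexicographically smallest transcript ID.
#' @export
nearestAnnotatedEnd <- function(tcEnds, annotation,
                                blacklist = character()) {
    ann <- annotation[!annotation$transcript_id %in% blacklist, ,
                      drop = FALSE]
    n <- nrow(tcEnds)
    out <- data.frame(transcript_id = rep(NA_character_, n),
                      gene_id = NA_character_, gene_name = NA_character_,
                      biotype = NA_character_,
                      annotated_end = NA_integer_,
                      distance = NA_integer_)
    if (!n || !nrow(ann)) return(out)
    key <- paste(tcEnds$reference, tcEnds$strand)
    annKey <- paste(ann$chromosome, ann$strand)
    for (k in unique(key)) {
        sub <- ann[annKey == k, , drop = FALSE]
        rows <- which(key == k)
        if (!nrow(sub)) next
        for (i in rows) {
            d <- abs(sub$three_prime_end - tcEnds$position[i])
            best <- which(d == min(d))
            if (length(best) > 1L)
                best <- best[order(sub$transcript_id[best])][1L]
            out$transcript_id[i] <- sub$transcript_id[best]
            out$gene_id[i] <- sub$gene_id[best]
            out$gene_name[i] <- sub$gene_name[best]
            out$biotype[i] <- sub$biotype[best]
            out$annotated_end[i] <- sub$three_prime_end[best]
            gdist <- sub$three_prime_end[best] - tcEnds$position[i]
            out$distance[i] <- if (tcEnds$strand[i] == "+") gdist else -gdist
        }
    }
    out
}

#' Proximity window test
#'
#' Stringent passes distances in [-100, +100], relaxed in
#' [-100, +5000]; bounds inclusive, distances signed in transcript
#' orientation.
#'
#' @param distance signed distances (NA fails).
#' @param window \code{"stringent"} or \code{"relaxed"}.
#' @export
proximityFilter <- function(distance, window = c("relaxed", "stringent")) {
    window <- match.arg(window)
    upper <- if (window == "stringent") 100L else 5000L
    !is.na(distance) & distance >= -100L & distance <= upper
}

#' Region/end consistency test
#'
#' A region supports its selected TC 3' end only when the region's
#' 3'-most coordinate (in transcript orientation) is not more than
#' \code{maxUpstream} bases upstream of the end; regions containing
#' the end always pass.
#'
#' @param regionStart,regionEnd region bounds (1-based inclusive).
#' @param tcPosition,tcStrand the selected end.
#' @param maxUpstream allowed upstream gap in bases (default 150).
#' @return logical vector.
#' @export
regionConsistency <- function(regionStart, regionEnd, tcPosition,
                              tcStrand, maxUpstream = 150L) {
    edge3 <- ifelse(tcStrand == "+", regionEnd, regionStart)
    upstreamGap <- ifelse(tcStrand == "+", tcPosition - edge3,
                          edge3 - tcPosition)
    !is.na(upstreamGap) & upstreamGap <= maxUpstream
}

#' Annotate selected region ends
#'
#' Joins each region's selected TC 3' end to the nearest annotated
#' same-strand transcript 3' end and evaluates the proximity windows
#' and the region-consistency rule.
#'
#' @param regions \code{GRanges} with \code{tc_position},
#'   \code{tc_strand}, \code{tc_support} metadata (from
#'   \code{\link{regionEnds}}).
#' @param annotation data frame from \code{\link{readAnnotation}}.
#' @param blacklist transcript IDs excluded from association.
#' @param maxUpstream see \code{\link{regionConsistency}}.
#' @return data frame with one row per region carrying region
#'   coordinates, the selected end, annotation fields, signed
#'   \code{distance} and logicals \code{passes_stringent},
#'   \code{passes_relaxed}, \code{passes_region_consistency}.
#' @export
annotateEnds <- function(regions, annotation, blacklist = character(),
                         maxUpstream = 150L) {
    mc <- S4Vectors::mcols(regions)
    out <- data.frame(
        chromosome = as.character(GenomicRanges::seqnames(regions)),
        region_start = GenomicRanges::start(regions),
        region_end = GenomicRanges::end(regions),
        tc_position = mc$tc_position,
        tc_strand = mc$tc_strand,
        tc_support = mc$tc_support)
    has <- !is.na(out$tc_position)
    near <- nearestAnnotatedEnd(
        data.frame(reference = out$chromosome[has],
                   position = out$tc_position[has],
                   strand = out$tc_strand[has]),
        annotation, blacklist)
    for (col in colnames(near)) {
        out[[col]] <- rep(if (is.character(near[[col]])) NA_character_
                          else NA_integer_, nrow(out))
        out[[col]][has] <- near[[col]]
    }
    out$passes_stringent <- proximityFilter(out$distance, "stringent")
    out$passes_relaxed <- proximityFilter(out$distance, "relaxed")
    out$passes_region_consistency <- has & regionConsistency(
        out$region_start, out$region_end, out$tc_position,
        out$tc_strand, maxUpstream)
    out
}
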