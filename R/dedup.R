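# UMI-aware PCR duplicate marking.
#
# Read pairs are potential duplicates when they share outer mapping
# coordinates (leftmost and rightmost mapped base over both mates),
# pair orientation and UMI.  Within each duplicate group one
# representative stays unflagged; group members are exact-UMI matches
# only (no error-network collapsing).

#' @importFrom data.table data.table setkey :=
NULL

#' Build a pair-level alignment table from SAM records
#'
#' Joins read-1 and read-2 records by query name and computes outer
#' coordinates, pair orientation, summed base quality and the UMI and
#' index tokens carried in the read name.  Pairs with an unmapped mate
#' get \code{both_mapped = FALSE} and are never keyed or flagged.
#'
#' @param sam data frame from \code{\link{readSam}}.
#' @param sampleMap optional named character vector translating index
#'   sequences to sample labels; by default the index token itself is
#'   used as the sample label.
#' @return data frame with one row per pair: \code{read_id},
#'   \code{umi}, \code{sample}, \code{reference}, \code{outer_start},
#'   \code{outer_end}, \code{orientation}, \code{qual_sum},
#'   \code{mismatches}, \code{both_mapped}, \code{duplicate}, plus
#'   read-1/read-2 anchor columns used downstream (\code{r1_pos},
#'   \code{r1_width}, \code{r1_reverse}, \code{r1_mapped},
#'   \code{r2_rname}, \code{r2_pos}, \code{r2_mismatches}).
#' @export
pairAlignments <- function(sam, sampleMap = NULL) {
    r1 <- sam[sam$read1, , drop = FALSE]
    r2 <- sam[sam$read2, , drop = FALSE]
    if (anyDuplicated(r1$qname) || anyDuplicated(r2$qname))
        stop("multiple primary alignments per mate are not supported")
    idx <- match(r1$qname, r2$qname)
    if (anyNA(idx)) stop("read 1 without a read 2 record")
    r2 <- r2[idx, , drop = FALSE]

    hasTags <- grepl(TAG_DELIM, r1$qname, fixed = TRUE)
    umi <- character(nrow(r1))
    index <- character(nrow(r1))
    if (any(hasTags)) {
        dec <- decodeTags(r1$qname[hasTags])
        umi[hasTags] <- dec$umi
        index[hasTags] <- dec$index
    }
    sample <- index
    if (!is.null(sampleMap)) {
        hit <- match(index, sampleMap)
        sample <- ifelse(is.na(hit), index, names(sampleMap)[hit])
    }

    w1 <- cigarReferenceWidth(r1$cigar)
    w2 <- cigarReferenceWidth(r2$cigar)
    bothMapped <- !r1$unmapped & !r2$unmapped & r1$rname == r2$rname
    outerStart <- pmin(r1$pos, r2$pos)
    outerEnd <- pmax(r1$pos + w1 - 1L, r2$pos + w2 - 1L)
    data.frame(
        read_id = r1$qname,
        umi = umi,
        sample = sample,
        reference = r1$rname,
        outer_start = ifelse(bothMapped, outerStart, NA_integer_),
        outer_end = ifelse(bothMapped, outerEnd, NA_integer_),
        orientation = paste0(ifelse(r1$reverse, "R", "F"),
                             ifelse(r2$reverse, "R", "F")),
        qual_sum = phredSum(r1$qual) + phredSum(r2$qual),
        mismatches = pmax(ifelse(is.na(r1$nm), 0L, r1$nm),
                          ifelse(is.na(r2$nm), 0L, r2$nm)),
        both_mapped = bothMapped,
        duplicate = r1$duplicate | r2$duplicate,
        r1_pos = r1$pos, r1_width = w1, r1_reverse = r1$reverse,
        r1_mapped = !r1$unmapped,
        r2_rname = r2$rname, r2_pos = r2$pos,
        r2_mismatches = ifelse(is.na(r2$nm), 0L, r2$nm))
}

#' Duplicate-group key of a read pair
#'
#' Key = (reference, outer start, outer end, orientation, UMI); equal
#' keys define one duplicate group.  Pairs with an unmapped mate have
#' no key (\code{NA}).  UMIs containing \code{N} never match another
#' UMI, so such pairs always form singleton groups.
#'
#' @param pairs data frame from \code{\link{pairAlignments}}.
#' @param ignoreUmi drop the UMI from the key (coordinate-only
#'   duplicate marking, for comparison).
#' @return character vector of keys, \code{NA} where unkeyed.
#' @export
duplicateKey <- function(pairs, ignoreUmi = FALSE) {
    umi <- if (ignoreUmi) "" else pairs$umi
    if (!ignoreUmi) {
        hasN <- grepl("N", umi, fixed = TRUE)
        # salt ambiguous UMIs so they can never co-group
        umi[hasN] <- paste0(umi[hasN], "!", seq_along(umi)[hasN])
    }
    key <- paste(pairs$reference, pairs$outer_start, pairs$outer_end,
                 pairs$orientation, umi, sep = "\r")
    key[!pairs$both_mapped] <- NA_character_
    key
}

#' Flag PCR duplicates
#'
#' Within each duplicate group exactly one pair — the one with the
#' highest summed base quality, ties broken by lexicographically
#' smallest read ID — stays unflagged; all others are flagged.
#' Singleton groups and pairs with an unmapped mate are never flagged.
#' Marking is idempotent: flags are recomputed from scratch.
#'
#' @inheritParams duplicateKey
#' @return \code{pairs} with the \code{duplicate} column set.
#' @export
markDuplicates <- function(pairs, ignoreUmi = FALSE) {
    key <- duplicateKey(pairs, ignoreUmi = ignoreUmi)
    dup <- logical(nrow(pairs))
    keyed <- which(!is.na(key))
    if (length(keyed)) {
        dt <- data.table(i = keyed, grp = key[keyed],
                         q = pairs$qual_sum[keyed],
                         id = pairs$read_id[keyed])
        dt[, keep := {
            o <- order(-q, id)
            r <- logical(.N); r[o[1L]] <- TRUE; r
        }, by = grp]
        dup[dt$i] <- !dt$keep
    }
    pairs$duplicate <- dup
    pairs
}

#' Duplicate fraction of a library
#'
#' @param pairs data frame from \code{\link{pairAlignments}} (flags are
#'   recomputed under the requested mode).
#' @param mode \code{"coords_plus_umi"} (UMI-aware) or
#'   \code{"coords_only"}.
#' @return flagged / both-mapped pair count, in [0, 1].
#' @export
duplicateRate <- function(pairs, mode = c("coords_plus_umi", "coords_only")) {
    mode <- match.arg(mode)
    keep <- pairs$both_mapped
    if (!any(keep)) stop("no mapped pairs: duplicate rate undefined")
    marked <- markDuplicates(pairs[keep, , drop = FALSE],
                             ignoreUmi = mode == "coords_only")
    mean(marked$duplicate)
}

#' Copy pair duplicate flags back onto SAM records
#'
#' @param sam data frame from \code{\link{readSam}}.
#' @param pairs flagged pair table from \code{\link{markDuplicates}}.
#' @return \code{sam} with the \code{duplicate} column updated on both
#'   mates of every flagged pair.
#' @export
applyDuplicateFlags <- function(sam, pairs) {
    flagged <- pairs$read_id[pairs$duplicate]
    sam$duplicate <- sam$qname %in% flagged
    sam
}
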