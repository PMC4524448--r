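# Read-1 tag parsing, demultiplexing and read renaming.
#
# Read 1 of a transcript-counting pair begins with a 12-base UMI, an
# 8-base inline sample index, an optional short spacer and an anchored
# polyT run; only the sequence 3' of the polyT derives from the
# transcript.  Pairs whose read 1 does not follow this layout are
# rejected with a reason.

TAG_DELIM <- "#"

polyTRun <- function(seqs, from, minPolyT) {
    # Maximal T-run starting at `from`, allowing one non-T base per ten
    # Ts; an absorbed non-T must be followed by at least one T, so the
    # first insert base is never swallowed.
    tails <- substring(seqs, from)
    m <- regexpr("^T+([^T]T+)*", tails)
    run <- ifelse(m > 0L, attr(m, "match.length"), 0L)
    hit <- which(run > 0L)
    for (i in hit) {
        r <- substr(tails[i], 1L, run[i])
        nonT <- nchar(gsub("T", "", r, fixed = TRUE))
        while (nonT > 0L && nonT > (nchar(r) - nonT) %/% 10L) {
            # drop the trailing [^T]T+ group and retry
            r <- sub("[^T]T+$", "", r)
            nonT <- nonT - 1L
        }
        run[i] <- nchar(r)
    }
    run
}

#' Parse the tag structure of read 1
#'
#' Splits read 1 into UMI, sample index, optional spacer and polyT run,
#' and locates the transcript-derived insert.  Reads that do not fit
#' the layout are flagged \code{rejected} with a reason
#' (\code{too_short}, \code{no_polyT} or \code{empty_insert}).
#'
#' @param sequence,qualities character vectors of read-1 sequences and
#'   quality strings.
#' @param layout a \linkS4class{TagLayout}.
#' @return data frame with columns \code{umi}, \code{index},
#'   \code{insert_seq}, \code{insert_qual}, \code{rejected},
#'   \code{reason}.
#' @examples
#' lay <- tagLayout()
#' r1 <- paste0("ACGTACGTACGT", "AACCGGTT", "CG",
#'              strrep("T", 14), "GATTACAGATTACA")
#' parseRead1(r1, strrep("I", nchar(r1)), lay)
#' @export
parseRead1 <- function(sequence, qualities, layout) {
    sequence <- toupper(sequence)
    n <- length(sequence)
    tagLen <- layout@umiLength + layout@indexLength
    umi <- substr(sequence, 1L, layout@umiLength)
    index <- substr(sequence, layout@umiLength + 1L, tagLen)
    reason <- rep(NA_character_, n)

    tooShort <- nchar(sequence) < tagLen + layout@minPolyT
    reason[tooShort] <- "too_short"

    # greedy spacer match: consume the longest matching spacer prefix
    spacerUsed <- integer(n)
    if (nzchar(layout@spacer)) {
        for (j in seq(nchar(layout@spacer), 1L)) {
            cand <- spacerUsed == 0L & !tooShort &
                substr(sequence, tagLen + 1L, tagLen + j) ==
                    substr(layout@spacer, 1L, j)
            spacerUsed[cand] <- j
        }
    }
    runFrom <- tagLen + spacerUsed + 1L
    run <- integer(n)
    ok <- !tooShort
    run[ok] <- polyTRun(sequence[ok], runFrom[ok], layout@minPolyT)
    noT <- ok & run < layout@minPolyT
    reason[noT] <- "no_polyT"

    insertFrom <- runFrom + run
    empty <- ok & !noT & insertFrom > nchar(sequence)
    reason[empty] <- "empty_insert"

    rejected <- !is.na(reason)
    data.frame(
        umi = umi, index = index,
        insert_seq = ifelse(rejected, "", substring(sequence, insertFrom)),
        insert_qual = ifelse(rejected, "", substring(qualities, insertFrom)),
        rejected = rejected,
        reason = reason)
}

#' Assign a sample label to an observed index sequence
#'
#' Exact whitelist matching by default; with
#' \code{maxIndexMismatches > 0} an index is assigned to the unique
#' whitelist entry within that Hamming distance, and left unassigned
#' when no entry or more than one entry matches.
#'
#' @param index character vector of observed index sequences.
#' @param layout a \linkS4class{TagLayout} with a non-empty whitelist.
#' @return character vector of sample labels, \code{NA} for unassigned.
#' @export
assignSample <- function(index, layout) {
    wl <- layout@indexWhitelist
    if (!length(wl)) stop("layout has an empty index whitelist")
    hit <- match(index, wl)
    label <- names(wl)[hit]
    if (layout@maxIndexMismatches > 0L) {
        todo <- which(is.na(label))
        if (length(todo)) {
            d <- vapply(wl, function(w) hammingToOne(index[todo], w),
                        integer(length(todo)))
            if (length(todo) == 1L) d <- matrix(d, nrow = 1L)
            within <- d <= layout@maxIndexMismatches
            nhit <- rowSums(within)
            uniq <- nhit == 1L
            label[todo[uniq]] <- names(wl)[apply(
                within[uniq, , drop = FALSE], 1L, which)]
        }
    }
    label
}

#' Encode UMI and index into a read name
#'
#' The tokens are appended with a reserved \code{#} delimiter so that
#' downstream duplicate marking can recover the UMI exactly;
#' \code{decodeTags} is the inverse.
#'
#' @param read_id original read IDs (must not contain \code{#}).
#' @param umi,index parsed tag sequences (non-empty).
#' @return character vector of encoded names.
#' @export
renameWithTags <- function(read_id, umi, index) {
    if (any(grepl(TAG_DELIM, read_id, fixed = TRUE)))
        stop("read ID contains the reserved delimiter '", TAG_DELIM, "'")
    if (any(!nzchar(umi)) || any(!nzchar(index)))
        stop("empty UMI or index")
    paste(read_id, umi, index, sep = TAG_DELIM)
}

#' @rdname renameWithTags
#' @param encoded names produced by \code{renameWithTags}.
#' @return \code{decodeTags}: data frame with \code{read_id},
#'   \code{umi}, \code{index}.
#' @export
decodeTags <- function(encoded) {
    parts <- strsplit(encoded, TAG_DELIM, fixed = TRUE)
    if (any(lengths(parts) != 3L))
        stop("malformed tag-encoded read name")
    data.frame(read_id = vapply(parts, `[[`, character(1L), 1L),
               umi = vapply(parts, `[[`, character(1L), 2L),
               index = vapply(parts, `[[`, character(1L), 3L))
}

#' Detag and demultiplex a stream of read pairs
#'
#' Applies \code{\link{parseRead1}} and \code{\link{assignSample}} to
#' every pair, renames accepted reads with their UMI and index, and
#' splits them into per-sample streams.  Every input pair lands in
#' exactly one output stream (a sample or the rejected stream).
#'
#' @param pairs data frame from \code{\link{readFastqPairs}}.
#' @param layout a \linkS4class{TagLayout}.
#' @param trimTo optional fixed length to which both raw reads are
#'   trimmed before parsing (3' trim), e.g. 54.
#' @return list with \code{samples} (named list of per-sample data
#'   frames with columns \code{read_id}, \code{umi}, \code{index},
#'   \code{sequence1}, \code{qualities1}, \code{sequence2},
#'   \code{qualities2}), \code{rejected} (data frame with
#'   \code{pair_id}, \code{reason}) and \code{summary} (named counts
#'   per outcome; sums to the input pair count).
#' @export
detagPairs <- function(pairs, layout, trimTo = NULL) {
    if (!is.null(trimTo)) {
        for (col in c("sequence1", "qualities1", "sequence2", "qualities2"))
            pairs[[col]] <- substr(pairs[[col]], 1L, trimTo)
    }
    parsed <- parseRead1(pairs$sequence1, pairs$qualities1, layout)
    label <- rep(NA_character_, nrow(pairs))
    okParse <- !parsed$rejected
    label[okParse] <- assignSample(parsed$index[okParse], layout)
    reason <- parsed$reason
    reason[okParse & is.na(label)] <- "unassigned_index"
    accepted <- is.na(reason)

    acc <- data.frame(
        read_id = renameWithTags(pairs$pair_id[accepted],
                                 parsed$umi[accepted],
                                 parsed$index[accepted]),
        umi = parsed$umi[accepted],
        index = parsed$index[accepted],
        sample = label[accepted],
        sequence1 = parsed$insert_seq[accepted],
        qualities1 = parsed$insert_qual[accepted],
        sequence2 = pairs$sequence2[accepted],
        qualities2 = pairs$qualities2[accepted])
    samples <- split(acc[, setdiff(colnames(acc), "sample")], acc$sample)

    rejected <- data.frame(pair_id = pairs$pair_id[!accepted],
                           reason = reason[!accepted])
    summary <- c(accepted = sum(accepted),
                 table(factor(reason[!accepted],
                              levels = c("too_short", "no_polyT",
                                         "empty_insert",
                                         "unassigned_index"))))
    list(samples = samples, rejected = rejected, summary = summary)
}
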