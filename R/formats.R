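# Readers and writers for the plain-text formats the pipeline consumes:
# FASTQ, SAM (text dialect), a minimal transcript-annotation table,
# blacklists and the final gene-list table.  All coordinates are 1-based
# inclusive internally (SAM convention); BED-style output converts at
# the writer.

FASTQ_MATE_SUFFIX <- "/[12]$"

readFastqFile <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
        stop("malformed FASTQ (", path, "): ", length(lines),
             " lines is not a multiple of 4")
    if (length(lines) == 0L)
        return(data.frame(read_id = character(), sequence = character(),
                          qualities = character()))
    idx <- seq(1L, length(lines), by = 4L)
    at <- lines[idx]
    plus <- lines[idx + 2L]
    if (any(substr(at, 1L, 1L) != "@") || any(substr(plus, 1L, 1L) != "+"))
        stop("malformed FASTQ 4-line block in ", path)
    seqs <- toupper(lines[idx + 1L])
    quals <- lines[idx + 3L]
    if (any(nchar(seqs) != nchar(quals)))
        stop("sequence/quality length mismatch in ", path)
    ids <- sub("\\s.*$", "", substring(at, 2L))
    data.frame(read_id = ids, sequence = seqs, qualities = quals)
}

#' Read paired FASTQ files in lockstep
#'
#' @param path1,path2 FASTQ files for read 1 and read 2, records in the
#'   same order.
#' @return A data frame with one row per pair: \code{pair_id} (the read
#'   ID with any \code{/1} or \code{/2} mate suffix stripped),
#'   \code{sequence1}, \code{qualities1}, \code{sequence2},
#'   \code{qualities2}.
#' @export
readFastqPairs <- function(path1, path2) {
    r1 <- readFastqFile(path1)
    r2 <- readFastqFile(path2)
    if (nrow(r1) != nrow(r2))
        stop("FASTQ files differ in record count: ", nrow(r1), " vs ",
             nrow(r2))
    id1 <- sub(FASTQ_MATE_SUFFIX, "", r1$read_id)
    id2 <- sub(FASTQ_MATE_SUFFIX, "", r2$read_id)
    if (any(id1 != id2))
        stop("read IDs out of lockstep at record ",
             which(id1 != id2)[1L])
    data.frame(pair_id = id1,
               sequence1 = r1$sequence, qualities1 = r1$qualities,
               sequence2 = r2$sequence, qualities2 = r2$qualities)
}

#' Write a FASTQ file
#'
#' @param ids,sequences,qualities parallel character vectors.
#' @param path output file.
#' @export
writeFastq <- function(ids, sequences, qualities, path) {
    stopifnot(length(ids) == length(sequences),
              length(ids) == length(qualities))
    out <- character(4L * length(ids))
    if (length(ids)) {
        idx <- seq(1L, length(out), by = 4L)
        out[idx] <- paste0("@", ids)
        out[idx + 1L] <- sequences
        out[idx + 2L] <- "+"
        out[idx + 3L] <- qualities
    }
    writeLines(out, path)
}

SAM_COLUMNS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "rnext", "pnext", "tlen", "seq", "qual")

#' Read a SAM file (text dialect)
#'
#' Parses the eleven mandatory columns, extracts the \code{NM} mismatch
#' tag when present, and decodes the flag bits into logical columns
#' (\code{paired}, \code{read1}, \code{read2}, \code{unmapped},
#' \code{mate_unmapped}, \code{reverse}, \code{mate_reverse},
#' \code{duplicate}).  Positions stay 1-based as in the standard.
#'
#' @param path SAM file with header.
#' @return A data frame of records; the header lines are kept in
#'   \code{attr(x, "header")}.
#' @export
readSam <- function(path) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "@")]
    body <- lines[!startsWith(lines, "@")]
    body <- body[nzchar(body)]
    if (!length(body)) {
        out <- data.frame(qname = character(), flag = integer(),
                          rname = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          rnext = character(), pnext = integer(),
                          tlen = integer(), seq = character(),
                          qual = character(), nm = integer())
        out <- decodeSamFlags(out)
        attr(out, "header") <- hdr
        return(out)
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
        stop("SAM record with fewer than 11 mandatory columns at line ",
             which(nf < 11L)[1L])
    get <- function(i) vapply(fields, `[[`, character(1L), i)
    out <- data.frame(
        qname = get(1L), flag = as.integer(get(2L)), rname = get(3L),
        pos = as.integer(get(4L)), mapq = as.integer(get(5L)),
        cigar = get(6L), rnext = get(7L), pnext = as.integer(get(8L)),
        tlen = as.integer(get(9L)), seq = get(10L), qual = get(11L))
    out$nm <- vapply(fields, function(f) {
        tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
        if (length(tag)) as.integer(sub("^NM:i:", "", tag[1L])) else NA_integer_
    }, integer(1L))
    out <- decodeSamFlags(out)
    attr(out, "header") <- hdr
    out
}

decodeSamFlags <- function(sam) {
    f <- sam$flag
    sam$paired <- bitwAnd(f, 1L) > 0L
    sam$unmapped <- bitwAnd(f, 4L) > 0L
    sam$mate_unmapped <- bitwAnd(f, 8L) > 0L
    sam$reverse <- bitwAnd(f, 16L) > 0L
    sam$mate_reverse <- bitwAnd(f, 32L) > 0L
    sam$read1 <- bitwAnd(f, 64L) > 0L
    sam$read2 <- bitwAnd(f, 128L) > 0L
    sam$duplicate <- bitwAnd(f, 1024L) > 0L
    sam
}

encodeSamFlag <- function(paired, unmapped, mate_unmapped, reverse,
                          mate_reverse, read1, read2, duplicate,
                          proper = paired & !unmapped & !mate_unmapped) {
    1L * paired + 2L * proper + 4L * unmapped + 8L * mate_unmapped +
        16L * reverse + 32L * mate_reverse + 64L * read1 +
        128L * read2 + 1024L * duplicate
}

#' Write SAM records
#'
#' The flag column is re-encoded from the logical columns, so duplicate
#' flags set by \code{\link{markDuplicates}} are serialized as the
#' standard SAM duplicate bit.
#'
#' @param sam data frame as returned by \code{\link{readSam}}.
#' @param path output file.
#' @param header optional header lines; defaults to the header the
#'   records were read with.
#' @export
writeSam <- function(sam, path, header = attr(sam, "header")) {
    sam$flag <- encodeSamFlag(sam$paired, sam$unmapped, sam$mate_unmapped,
                              sam$reverse, sam$mate_reverse, sam$read1,
                              sam$read2, sam$duplicate)
    body <- paste(sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                  sam$cigar, sam$rnext, sam$pnext, sam$tlen, sam$seq,
                  sam$qual, sep = "\t")
    has_nm <- !is.na(sam$nm)
    body[has_nm] <- paste0(body[has_nm], "\tNM:i:", sam$nm[has_nm])
    writeLines(c(header, body), path)
}

#' Read a transcript-annotation table
#'
#' A tab-separated table with a header line and columns
#' \code{transcript_id}, \code{gene_id}, \code{gene_name},
#' \code{chromosome}, \code{strand}, \code{three_prime_end} and
#' optionally \code{biotype}.  \code{three_prime_end} is the 1-based
#' genomic coordinate of the transcript 3' terminus (the higher
#' coordinate on \code{+}, the lower on \code{-}).
#'
#' @param path annotation TSV.
#' @return data frame with one row per transcript.
#' @export
readAnnotation <- function(path) {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "gene_id", "gene_name", "chromosome",
              "strand", "three_prime_end")
    miss <- setdiff(need, colnames(ann))
    if (length(miss))
        stop("annotation lacks columns: ", paste(miss, collapse = ", "))
    if (!"biotype" %in% colnames(ann)) ann$biotype <- "protein_coding"
    if (anyDuplicated(ann$transcript_id))
        stop("duplicate transcript IDs in annotation")
    if (!all(ann$strand %in% c("+", "-")))
        stop("annotation strand must be + or -")
    ann$three_prime_end <- as.integer(ann$three_prime_end)
    ann
}

#' Write a transcript-annotation table
#' @param ann data frame as returned by \code{\link{readAnnotation}}.
#' @param path output TSV.
#' @export
writeAnnotation <- function(ann, path) {
    utils::write.table(ann, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Read a transcript blacklist
#'
#' One transcript ID per line; blank lines and \code{#} comments are
#' ignored.  Blacklisted transcripts are excluded before annotation
#' association.
#'
#' @param path text file.
#' @return character vector of transcript IDs.
#' @export
readBlacklist <- function(path) {
    x <- trimws(readLines(path))
    x[nzchar(x) & !startsWith(x, "#")]
}

#' Gene-list column order
#'
#' The fixed leading columns of the output table; per-sample raw counts
#' (\code{count_<sample>}) and normalised counts (\code{norm_<sample>})
#' follow in sample order.
#' @export
geneListColumns <- function() {
    c("chromosome", "region_start", "region_end", "tc_position",
      "tc_strand", "tc_support", "transcript_id", "gene_id",
      "gene_name", "biotype", "distance", "log2_fold_change",
      "p_value", "adjusted_p")
}

orderGeneList <- function(rows) {
    rows[order(rows$adjusted_p, rows$p_value,
               na.last = TRUE, method = "radix"), , drop = FALSE]
}

#' Write the gene-list table
#'
#' Rows are ordered by ascending adjusted p-value with missing values
#' last; missing adjusted p-values (regions removed by independent
#' filtering) are serialized as \code{NA}.  The HTML format is a single
#' \code{<table>} element.
#'
#' @param rows data frame with the columns of
#'   \code{\link{geneListColumns}} plus per-sample count columns.
#' @param path output file.
#' @param format one of \code{"csv"}, \code{"tsv"}, \code{"html"}.
#' @return \code{path}, invisibly.
#' @export
writeGeneList <- function(rows, path, format = c("csv", "tsv", "html")) {
    format <- match.arg(format)
    fixed <- geneListColumns()
    miss <- setdiff(fixed, colnames(rows))
    if (length(miss))
        stop("gene list lacks columns: ", paste(miss, collapse = ", "))
    extra <- setdiff(colnames(rows), fixed)
    extra <- extra[order(!startsWith(extra, "count_"))]
    rows <- orderGeneList(rows[, c(fixed, extra), drop = FALSE])
    if (format == "html") {
        esc <- function(x) {
            x <- gsub("&", "&amp;", x, fixed = TRUE)
            x <- gsub("<", "&lt;", x, fixed = TRUE)
            gsub(">", "&gt;", x, fixed = TRUE)
        }
        cells <- vapply(rows, function(col) esc(as.character(col)),
                        character(nrow(rows)))
        if (nrow(rows) == 1L) cells <- matrix(cells, nrow = 1L)
        head <- paste0("<tr>", paste0("<th>", esc(colnames(rows)), "</th>",
                                      collapse = ""), "</tr>")
        body <- if (nrow(rows)) {
            apply(cells, 1L, function(r)
                paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""),
                       "</tr>"))
        } else character()
        writeLines(c("<table>", head, body, "</table>"), path)
    } else {
        utils::write.table(rows, path,
                           sep = if (format == "csv") "," else "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read back a delimited gene-list table
#' @param path file written by \code{\link{writeGeneList}}.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @export
readGeneList <- function(path, format = c("csv", "tsv")) {
    format <- match.arg(format)
    utils::read.delim(path, sep = if (format == "csv") "," else "\t",
                      stringsAsFactors = FALSE)
}
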