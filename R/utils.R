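# Small shared helpers; internal only.

# Pairwise Hamming distance matrix for equal-length strings.
hammingMatrix <- function(x) {
    n <- length(x)
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    d <- matrix(0L, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
    d
}

# Hamming distances between one query vector and one subject string,
# vectorized over queries.  All strings must share nchar(subject).
hammingToOne <- function(queries, subject) {
    w <- nchar(subject)
    out <- integer(length(queries))
    sub <- strsplit(subject, "", fixed = TRUE)[[1L]]
    for (p in seq_len(w)) {
        out <- out + (substr(queries, p, p) != sub[p])
    }
    out
}

# Reference-consumed width of a CIGAR string (M/D/N/=/X operations).
cigarReferenceWidth <- function(cigar) {
    vapply(cigar, function(cg) {
        if (is.na(cg) || cg == "*") return(0L)
        ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
        toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
        n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
        op <- sub("^\\d+", "", toks)
        sum(n[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1L), USE.NAMES = FALSE)
}

# log(sum(exp(x))) without overflow, for a numeric vector.
logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

# Sum of phred scores encoded in a quality string (offset 33).
phredSum <- function(qual) {
    vapply(qual, function(q) {
        if (is.na(q) || q == "*") return(0L)
        sum(utf8ToInt(q) - 33L)
    }, integer(1L), USE.NAMES = FALSE)
}

# Reverse complement for plain character vectors (delegates to Biostrings).
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA of given lengths from a base alphabet.
randomDna <- function(n, len, bases = c("A", "C", "G", "T"),
                      prob = NULL) {
    vapply(rep_len(len, n), function(l) {
        paste(sample(bases, l, replace = TRUE, prob = prob), collapse = "")
    }, character(1L))
}

# data.table non-standard-evaluation column names
utils::globalVariables(c("grp", "keep", "q", "id"))
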