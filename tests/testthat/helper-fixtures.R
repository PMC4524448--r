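# Fixture builders and independent oracles shared across tests.
# Everything is generated in code; no data files.

# Minimal pair-table row(s) with sensible defaults; any column can be
# overridden.
makePairTable <- function(n = 1L, read_id = sprintf("r%03d", seq_len(n)),
                          umi = strrep("A", 12), sample = "s1",
                          reference = "chr1", outer_start = 100L,
                          outer_end = 300L, orientation = "FR",
                          qual_sum = 1000L, mismatches = 0L,
                          both_mapped = TRUE, duplicate = FALSE,
                          r1_pos = 250L, r1_width = 51L,
                          r1_reverse = TRUE, r1_mapped = TRUE,
                          r2_rname = reference, r2_pos = outer_start,
                          r2_mismatches = 0L) {
    data.frame(read_id = read_id, umi = umi, sample = sample,
               reference = reference, outer_start = outer_start,
               outer_end = outer_end, orientation = orientation,
               qual_sum = qual_sum, mismatches = mismatches,
               both_mapped = both_mapped, duplicate = duplicate,
               r1_pos = r1_pos, r1_width = r1_width,
               r1_reverse = r1_reverse, r1_mapped = r1_mapped,
               r2_rname = r2_rname, r2_pos = r2_pos,
               r2_mismatches = r2_mismatches)
}

# Random pair tables drawing coordinates and UMIs from small pools so
# duplicate groups actually form.
makeRandomPairs <- function(n, seed, nCoordSlots = 20L, nUmis = 8L) {
    set.seed(seed)
    starts <- sample(seq(100L, 5000L, by = 100L), nCoordSlots)
    slot <- sample(nCoordSlots, n, replace = TRUE)
    umis <- vapply(seq_len(nUmis), function(i)
        paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
              collapse = ""), character(1L))
    makePairTable(
        n = n,
        umi = umis[sample(nUmis, n, replace = TRUE)],
        outer_start = starts[slot],
        outer_end = starts[slot] + sample(c(150L, 200L), n, TRUE),
        orientation = sample(c("FR", "RF"), n, replace = TRUE),
        qual_sum = sample(500:1500, n, replace = TRUE),
        r2_pos = starts[slot])
}

# Exhaustive pairwise duplicate oracle: a pair is flagged iff another
# pair shares its key and beats it on (qual_sum, then lexicographic
# read_id).  Independent of the grouped implementation.
oracleDedupFlags <- function(pairs, ignoreUmi = FALSE) {
    n <- nrow(pairs)
    umi <- if (ignoreUmi) rep("", n) else pairs$umi
    key <- paste(pairs$reference, pairs$outer_start, pairs$outer_end,
                 pairs$orientation, umi)
    flag <- logical(n)
    for (i in seq_len(n)) {
        if (!pairs$both_mapped[i]) next
        for (j in seq_len(n)) {
            if (i == j || !pairs$both_mapped[j] || key[i] != key[j]) next
            beats <- pairs$qual_sum[j] > pairs$qual_sum[i] ||
                (pairs$qual_sum[j] == pairs$qual_sum[i] &&
                 pairs$read_id[j] < pairs$read_id[i])
            if (beats) { flag[i] <- TRUE; break }
        }
    }
    flag
}

# Linear-scan nearest-3'-end oracle over the whole annotation.
oracleNearest <- function(reference, position, strand, ann, blacklist = character()) {
    ann <- ann[!ann$transcript_id %in% blacklist, , drop = FALSE]
    ann <- ann[ann$chromosome == reference & ann$strand == strand, ,
               drop = FALSE]
    if (!nrow(ann)) return(NULL)
    d <- abs(ann$three_prime_end - position)
    cand <- ann[d == min(d), , drop = FALSE]
    cand[order(cand$transcript_id), ][1L, ]
}

# Tiny annotation table.
makeAnnotation <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
        data.frame(transcript_id = r[[1]], gene_id = paste0("g_", r[[1]]),
                   gene_name = r[[1]], chromosome = r[[2]],
                   strand = r[[3]],
                   three_prime_end = as.integer(r[[4]]),
                   biotype = "protein_coding")))
}

# A 10-mer with exactly `nA` As scattered over {C,G,T} background; with
# nA <= 3 no A-enrichment rule can apply (patterns need six As, the
# start rule four, the total rule seven).
aPoor10 <- function(nA = sample(0:3, 1L)) {
    s <- sample(c("C", "G", "T"), 10L, replace = TRUE)
    if (nA > 0L) s[sample(10L, nA)] <- "A"
    paste(s, collapse = "")
}
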