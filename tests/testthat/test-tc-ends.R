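test_that("end position and strand follow read-1 orientation", {
    # forward read 1 at [1000..1053]: minus-strand transcript, end 1000
    fwd <- makePairTable(1, r1_pos = 1000L, r1_width = 54L,
                         r1_reverse = FALSE)
    e <- endPosition(fwd)
    expect_equal(e$end_position, 1000L)
    expect_equal(e$end_strand, "-")
    # reverse read 1 at [1000..1053]: plus-strand transcript, end 1053
    rev <- makePairTable(1, r1_pos = 1000L, r1_width = 54L,
                         r1_reverse = TRUE)
    e2 <- endPosition(rev)
    expect_equal(e2$end_position, 1053L)
    expect_equal(e2$end_strand, "+")
    # soft clipping shrinks the aligned span: 10S44M has width 44
    clip <- rev
    clip$r1_width <- 44L
    expect_equal(endPosition(clip)$end_position, 1043L)
    # unmapped read 1 yields no end
    um <- makePairTable(1, r1_mapped = FALSE)
    expect_true(is.na(endPosition(um)$end_position))
})

test_that("candidates aggregate distinct ends with pair support", {
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101L, 400L))
    p <- makePairTable(6,
        r2_pos = c(150L, 160L, 170L, 180L, 190L, 900L),
        r1_pos = c(350L, 350L, 350L, 380L, 380L, 950L),
        r1_width = 40L, r1_reverse = TRUE)
    p$duplicate <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
    cand <- collectCandidates(reg, endPosition(p))
    expect_equal(nrow(cand), 2L)    # read 6 lies outside the region
    expect_equal(cand$support[order(cand$position)], c(3L, 2L))

    # duplicate-flagged pairs do not add support
    p$duplicate[1] <- TRUE
    cand2 <- collectCandidates(reg, endPosition(p))
    expect_equal(sort(cand2$support), c(2L, 2L))

    # region without read-1 mates -> empty
    emptyReg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000L, 5400L))
    expect_equal(nrow(collectCandidates(emptyReg, endPosition(p))), 0L)
})

test_that("A-enrichment rules fire exactly as printed", {
    v <- polyaArtifact(c("AAAAGCTGCT", "AACAACAACC", "ACGTACGTAC",
                         "AABAABAABA"))
    expect_equal(v$artifact, c(TRUE, TRUE, FALSE, TRUE))
    expect_equal(v$reason, c("polyA_start", "polyA_pattern", NA,
                             "polyA_total"))
    # truncated contexts at a contig edge: applicable rules only
    short <- polyaArtifact(c("AAAAG", "AAG", "AAAAAAA"))
    expect_equal(short$artifact, c(TRUE, FALSE, TRUE))
    # N counts as non-A
    expect_false(polyaArtifact("AAANAAAGGG")$artifact)
})

test_that("downstream context is strand-aware and edge-truncated", {
    genome <- Biostrings::DNAStringSet(c(chr1 = "AAACCCGGGTTTACGTACGT"))
    # '+': bases just right of the position
    expect_equal(downstreamContext(genome, "chr1", 5L, "+"), "CGGGTTTACG")
    # '-': reverse complement of the 10 bases just left of it (2..11)
    expect_equal(downstreamContext(genome, "chr1", 12L, "-"),
                 as.character(Biostrings::reverseComplement(
                     Biostrings::DNAStringSet("AACCCGGGTT")))[1])
    # truncation at the right edge
    expect_equal(downstreamContext(genome, "chr1", 18L, "+"), "GT")
    expect_equal(downstreamContext(genome, "chr1", 20L, "+"), "")
})

test_that("support and mispriming filters combine before selection", {
    genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
        strrep("C", 100), "AAAAAAAAAA", strrep("G", 100))))
    cand <- data.frame(region_idx = 1L, reference = "chr1",
                       position = c(10L, 20L, 30L, 100L, 150L),
                       strand = "+",
                       support = c(1L, 2L, 3L, 5L, 7L))
    out <- filterCandidates(cand, genome)
    expect_equal(out$reason[1:2], c("low_support", "low_support"))
    expect_false(out$artifact[3])                     # support 3, C-rich
    expect_equal(out$reason[4], "polyA_start")        # runs into the A block
    expect_false(out$artifact[5])                     # G-rich downstream

    sel <- selectRegionEnd(out)
    expect_equal(sel$position, 150L)                  # best non-artifact

    # highest-support end wins; ties break to the lower coordinate
    two <- data.frame(region_idx = 1L, reference = "chr1",
                      position = c(40L, 30L), strand = "+",
                      support = c(5L, 5L), artifact = FALSE,
                      reason = NA_character_)
    expect_equal(selectRegionEnd(two)$position, 30L)
    expect_null(selectRegionEnd(transform(two, artifact = TRUE)))

    # known-false-ends list removes a candidate from selection
    fe <- data.frame(reference = "chr1", position = 150L, strand = "+")
    out2 <- filterCandidates(cand, genome, falseEnds = fe)
    expect_equal(out2$reason[5], "known_false_end")
    expect_equal(selectRegionEnd(out2)$position, 30L)
})

test_that("every printed pattern instantiation is flagged", {
    # spot-check a randomized subsample of B in {C,G,T} instantiations
    set.seed(99)
    pats <- tagcount:::POLYA_PATTERNS
    for (pat in pats) {
        chars <- strsplit(pat, "")[[1]]
        for (i in 1:20) {
            inst <- paste(ifelse(chars == "A", "A",
                                 sample(c("C", "G", "T"), 10,
                                        replace = TRUE)),
                          collapse = "")
            v <- polyaArtifact(inst)
            expect_true(v$artifact, info = inst)
        }
    }
})
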