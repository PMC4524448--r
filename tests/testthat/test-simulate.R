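test_that("genome and annotation generation is seeded and truth-consistent", {
    cfg <- simConfig(seed = 7, nTranscripts = 12, misprimeCount = 4)
    a <- simulateGenomeAndAnnotation(cfg)
    b <- simulateGenomeAndAnnotation(cfg)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$annotation, b$annotation)

    # transcripts non-overlapping per strand and inside their contig
    tx <- a$transcripts
    for (chr in unique(tx$chromosome)) for (s in c("+", "-")) {
        sub <- tx[tx$chromosome == chr & tx$strand == s, ]
        if (nrow(sub) > 1L) {
            o <- order(sub$tx_start)
            expect_true(all(sub$tx_start[o][-1] > sub$tx_end[o][-nrow(sub)]))
        }
    }
    lens <- Biostrings::width(a$genome)[match(tx$chromosome,
                                              names(a$genome))]
    expect_true(all(tx$tx_end <= lens))

    # true ends have A-poor downstream contexts, misprime sites match
    # the artifact rules
    ctxTrue <- downstreamContext(a$genome, tx$chromosome,
                                 tx$three_prime_end, tx$strand)
    expect_false(any(polyaArtifact(ctxTrue)$artifact))
    mp <- a$misprimes
    ctxMp <- downstreamContext(a$genome, mp$chromosome, mp$position,
                               mp$strand)
    expect_true(all(polyaArtifact(ctxMp)$artifact))

    # empty annotation case
    none <- simulateGenomeAndAnnotation(simConfig(seed = 1,
                                                  nTranscripts = 0,
                                                  misprimeCount = 0))
    expect_equal(nrow(none$annotation), 0L)
})

test_that("simulated reads join the truth table and respect the layout", {
    cfg <- simConfig(seed = 13, nTranscripts = 8, exprMeanlog = log(40),
                     nPerCondition = 2, errorRate = 0,
                     duplicationRate = 0)
    sr <- simulateReads(cfg)
    # every read explained by the truth table, and vice versa
    expect_setequal(sr$fastq$pair_id, sr$truth$read_id)
    expect_equal(sort(unique(sr$sam$qname)),
                 sort(renameWithTags(sr$truth$read_id, sr$truth$umi,
                                     sr$layout@indexWhitelist[sr$truth$sample])))
    # no duplicates requested: all (coords, UMI) keys unique
    pairs <- markDuplicates(pairAlignments(sr$sam))
    expect_equal(sum(pairs$duplicate), 0L)
    # detag accepts everything at zero error rate
    out <- detagPairs(sr$fastq, sr$layout)
    expect_equal(unname(out$summary["accepted"]), nrow(sr$fastq))
    # SAM coordinates are consistent with the FASTQ insert sequences
    sam1 <- sr$sam[sr$sam$read1, ]
    i <- match(decodeTags(sam1$qname)$read_id, sr$fastq$pair_id)
    lay <- sr$layout
    tagLen <- lay@umiLength + lay@indexLength + nchar(lay@spacer) +
        cfg$polyTLength
    insert <- substring(sr$fastq$sequence1[i], tagLen + 1L)
    genomeSeq <- as.character(sr$sim$genome)
    ref <- substr(genomeSeq[sam1$rname], sam1$pos,
                  sam1$pos + cigarReferenceWidth(sam1$cigar) - 1L)
    asSequenced <- ifelse(sam1$reverse,
                          as.character(Biostrings::reverseComplement(
                              Biostrings::DNAStringSet(ref))), ref)
    expect_equal(insert, unname(asSequenced))
})

test_that("per-transcript read totals scale with expression and fold change", {
    cfg <- simConfig(seed = 23, nTranscripts = 10,
                     exprMeanlog = log(200), exprSdlog = 0,
                     nPerCondition = 4, fcFraction = 0.2, fcValue = 4,
                     duplicationRate = 0, misprimeCount = 0,
                     backgroundRate = 0, dispersion = 0.05)
    sr <- simulateReads(cfg)
    tx <- sr$sim$transcripts
    tr <- sr$truth[sr$truth$origin == "transcript", ]
    tot <- table(tr$origin_id, tr$condition)
    ratio <- (tot[, "cond2"] / 4) / (tot[, "cond1"] / 4)
    fc <- tx$fold_change[match(rownames(tot), tx$transcript_id)]
    # changed transcripts stand apart from unchanged ones
    expect_true(all(abs(log2(ratio) - log2(fc)) < 1))
})

test_that("direct count simulation hits its configured moments and seeds", {
    sim <- simulateCounts(nRegions = 1000, nPerCondition = 3,
                          meanlog = log(100), sdlog = 0,
                          dispersion = 0.1, seed = 42)
    expect_equal(mean(sim$counts), 100,
                 tolerance = 3 * sqrt(100 + 0.1 * 100^2) /
                     sqrt(length(sim$counts)) / 100 * 3)
    expect_identical(sim$counts,
                     simulateCounts(nRegions = 1000, nPerCondition = 3,
                                    meanlog = log(100), sdlog = 0,
                                    dispersion = 0.1, seed = 42)$counts)
    # null dataset when no fold change is configured
    expect_true(all(sim$trueLog2FC == 0))
    # spike design shapes
    sp <- simulateSpikeCounts(seed = 3)
    expect_equal(sum(sp$isSpike), 92L)
    expect_equal(ncol(sp$counts), 12L)
    expect_equal(levels(sp$condition), c("x5", "x1", "x0.2", "x0.1"))
})
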