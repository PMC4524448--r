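layoutWith <- function(...) {
    tagLayout(indexWhitelist = c(s1 = "AACCGGTT", s2 = "TTGGCCAA",
                                 s3 = "GGTTAACC"), ...)
}

test_that("read-1 parsing follows the printed tag layout", {
    lay <- layoutWith()
    r1 <- paste0("ACGTACGTACGT", "AACCGGTT", "CG", strrep("T", 14),
                 "GATTACAGATTACA")
    got <- parseRead1(r1, strrep("I", nchar(r1)), lay)
    expect_false(got$rejected)
    expect_equal(got$umi, "ACGTACGTACGT")
    expect_equal(got$index, "AACCGGTT")
    expect_equal(substr(got$insert_seq, 1, 7), "GATTACA")
    expect_equal(nchar(got$insert_qual), nchar(got$insert_seq))

    # spacer is optional: a read without it still parses
    noSpacer <- paste0("ACGTACGTACGT", "AACCGGTT", strrep("T", 14),
                       "GATTACA")
    got2 <- parseRead1(noSpacer, strrep("I", nchar(noSpacer)), lay)
    expect_false(got2$rejected)
    expect_equal(substr(got2$insert_seq, 1, 7), "GATTACA")

    # one miscall inside a long T-run is tolerated
    withErr <- paste0("ACGTACGTACGT", "AACCGGTT", "CG",
                      strrep("T", 7), "G", strrep("T", 6), "CATCAT")
    got3 <- parseRead1(withErr, strrep("I", nchar(withErr)), lay)
    expect_false(got3$rejected)
    expect_equal(got3$insert_seq, "CATCAT")
})

test_that("malformed read 1 is rejected with the right reason", {
    lay <- layoutWith()
    cases <- data.frame(
        seq = c("ACGTACGT",                                    # too short
                paste0("ACGTACGTACGT", "AACCGGTT", "CG",
                       "GATTACAGATTACAGG"),                    # no T run
                paste0("ACGTACGTACGT", "AACCGGTT", "CG",
                       strrep("T", 14))),                      # nothing after
        reason = c("too_short", "no_polyT", "empty_insert"))
    got <- parseRead1(cases$seq, strrep("I", nchar(cases$seq)), lay)
    expect_true(all(got$rejected))
    expect_equal(got$reason, cases$reason)
})

test_that("index assignment is exact by default and Hamming-aware on request", {
    lay <- layoutWith()
    expect_equal(assignSample(c("AACCGGTT", "TTGGCCAA"), lay),
                 c("s1", "s2"))
    # one mismatch: unassigned at the default 0 tolerance
    expect_true(is.na(assignSample("AACCGGTA", lay)))
    lay1 <- layoutWith(maxIndexMismatches = 1L)
    expect_equal(assignSample("AACCGGTA", lay1), "s1")
    # ambiguous within tolerance -> unassigned
    layAmb <- tagLayout(indexWhitelist = c(a = "AAAAAAAA", b = "AAAAAAAT"),
                        maxIndexMismatches = 0L)
    layAmb@maxIndexMismatches <- 1L  # force ambiguity for the test
    expect_true(is.na(assignSample("AAAAAAAC", layAmb)))
})

test_that("tag-encoded read names round-trip and stay injective", {
    enc <- renameWithTags(c("r1", "r1"), c("AAAACCCCGGGG", "TTTTCCCCGGGG"),
                          c("AACCGGTT", "AACCGGTT"))
    expect_equal(length(unique(enc)), 2L)
    dec <- decodeTags(enc)
    expect_equal(dec$read_id, c("r1", "r1"))
    expect_equal(dec$umi, c("AAAACCCCGGGG", "TTTTCCCCGGGG"))
    expect_error(renameWithTags("bad#id", "AAAA", "CCCC"), "delimiter")
    expect_error(renameWithTags("r1", "", "CCCC"), "empty")
})

test_that("detagging conserves every input pair exactly once", {
    lay <- layoutWith()
    good <- function(idx, ins) paste0("ACGTACGTACGT", idx, "CG",
                                      strrep("T", 14), ins)
    pairs <- data.frame(
        pair_id = sprintf("p%02d", 1:12),
        sequence1 = c(rep(good("AACCGGTT", "GATTACAG"), 6),
                      rep(good("TTGGCCAA", "CATCATCA"), 4),
                      "ACGT",                                   # too short
                      good("CCCCCCCC", "GATTACAG")),            # unknown index
        sequence2 = strrep("G", 30), qualities2 = strrep("I", 30))
    pairs$qualities1 <- strrep("I", nchar(pairs$sequence1))
    out <- detagPairs(pairs, lay)
    expect_equal(sum(out$summary), nrow(pairs))
    expect_equal(unname(out$summary["accepted"]), 10L)
    expect_equal(sort(names(out$samples)), c("s1", "s2"))
    expect_equal(nrow(out$samples$s1), 6L)
    expect_equal(nrow(out$samples$s2), 4L)
    expect_equal(sort(out$rejected$reason),
                 sort(c("too_short", "unassigned_index")))
    # determinism
    expect_identical(detagPairs(pairs, lay), out)
    # empty input
    empty <- detagPairs(pairs[0, ], lay)
    expect_equal(sum(empty$summary), 0L)
})

test_that("index assignment on simulated reads is perfect without errors", {
    cfg <- simConfig(seed = 21, nTranscripts = 6,
                     exprMeanlog = log(30), nPerCondition = 2,
                     errorRate = 0, misprimeCount = 0,
                     backgroundRate = 0)
    sr <- simulateReads(cfg)
    out <- detagPairs(sr$fastq, sr$layout)
    expect_equal(unname(out$summary["accepted"]), nrow(sr$fastq))
    got <- do.call(rbind, lapply(names(out$samples), function(s)
        data.frame(read_id = decodeTags(out$samples[[s]]$read_id)$read_id,
                   sample = s)))
    truthMap <- sr$truth$sample[match(got$read_id, sr$truth$read_id)]
    expect_equal(got$sample, truthMap)
})
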