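test_that("nearest annotated end matches a linear-scan oracle", {
    ann <- makeAnnotation(list("t1", "chr1", "+", 900),
                          list("t2", "chr1", "+", 1500),
                          list("t3", "chr1", "-", 1100),
                          list("t4", "chr2", "+", 1000))
    got <- nearestAnnotatedEnd(
        data.frame(reference = "chr1", position = 1000L, strand = "+"),
        ann)
    expect_equal(got$transcript_id, "t1")
    expect_equal(abs(got$distance), 100L)
    # the '+' end at 1000 is 100 bases 3' of the annotated 900 end:
    # annotated end lies 5' of the TC end -> negative distance
    expect_equal(got$distance, -100L)

    # oracle equivalence on random queries
    set.seed(12)
    bigAnn <- do.call(makeAnnotation, lapply(1:40, function(i)
        list(sprintf("tx%02d", i), sample(c("chr1", "chr2"), 1),
             sample(c("+", "-"), 1), sample(1e5, 1))))
    for (i in 1:40) {
        q <- data.frame(reference = sample(c("chr1", "chr2"), 1),
                        position = sample(1e5, 1),
                        strand = sample(c("+", "-"), 1))
        got <- nearestAnnotatedEnd(q, bigAnn)
        want <- oracleNearest(q$reference, q$position, q$strand, bigAnn)
        expect_equal(got$transcript_id, want$transcript_id)
    }
})

test_that("blacklist, missing strand and ties behave deterministically", {
    ann <- makeAnnotation(list("tB", "chr1", "+", 900),
                          list("tA", "chr1", "+", 1100))
    # only transcript blacklisted -> none
    solo <- makeAnnotation(list("tOnly", "chr1", "+", 900))
    got <- nearestAnnotatedEnd(
        data.frame(reference = "chr1", position = 1000L, strand = "+"),
        solo, blacklist = "tOnly")
    expect_true(is.na(got$transcript_id))
    # equidistant -> lexicographically smallest transcript id
    tie <- nearestAnnotatedEnd(
        data.frame(reference = "chr1", position = 1000L, strand = "+"),
        ann)
    expect_equal(tie$transcript_id, "tA")
    # no same-strand transcript on the chromosome -> none
    none <- nearestAnnotatedEnd(
        data.frame(reference = "chr1", position = 1000L, strand = "-"),
        ann)
    expect_true(is.na(none$transcript_id))
})

test_that("distance sign is 5'/3' in transcript orientation on both strands", {
    ann <- makeAnnotation(list("p", "chr1", "+", 1000),
                          list("m", "chr2", "-", 1000))
    # '+' TC end downstream (3') of the annotated end: annotated is 5' -> negative
    dPlus <- nearestAnnotatedEnd(
        data.frame(reference = "chr1", position = 1200L, strand = "+"),
        ann)$distance
    expect_equal(dPlus, -200L)
    # mirrored on '-': genomic left is 3' of the transcript
    dMinus <- nearestAnnotatedEnd(
        data.frame(reference = "chr2", position = 800L, strand = "-"),
        ann)$distance
    expect_equal(dMinus, -200L)
})

test_that("proximity windows classify the printed boundaries", {
    d <- c(-101L, -100L, 0L, 100L, 101L, 5000L, 5001L, NA)
    expect_equal(proximityFilter(d, "stringent"),
                 c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
    expect_equal(proximityFilter(d, "relaxed"),
                 c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("stringent passes are always a subset of relaxed passes", {
    set.seed(3)
    d <- sample(-300:5300, 500, replace = TRUE)
    s <- proximityFilter(d, "stringent")
    r <- proximityFilter(d, "relaxed")
    expect_true(all(r[s]))
})

test_that("region consistency allows at most 150 bases of upstream gap", {
    # '+' strand: region 3' edge is its end coordinate
    expect_true(regionConsistency(1L, 900L, 1000L, "+"))    # 100 upstream
    expect_true(regionConsistency(1L, 850L, 1000L, "+"))    # 150 exactly
    expect_false(regionConsistency(1L, 849L, 1000L, "+"))   # 151: fail
    expect_true(regionConsistency(1L, 1200L, 1000L, "+"))   # contains end
    # mirrored on '-': the 3' edge is the region start
    expect_true(regionConsistency(1150L, 2000L, 1000L, "-"))
    expect_false(regionConsistency(1151L, 2000L, 1000L, "-"))
})

test_that("annotated output never references a blacklisted transcript", {
    cfg <- simConfig(seed = 17, nTranscripts = 8,
                     exprMeanlog = log(60), nPerCondition = 2,
                     misprimeCount = 0)
    sr <- simulateReads(cfg)
    bl <- sr$sim$annotation$transcript_id[1:3]
    run <- runPipeline(sr$sam, sr$sim$genome, sr$sim$annotation,
                       sr$samples, sampleMap = sr$layout@indexWhitelist,
                       blacklist = bl)
    expect_false(any(run$annotated$transcript_id %in% bl, na.rm = TRUE))
})
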