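test_that("per-region counts follow sample labels and duplicate flags", {
    reg <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(101L, 501L),
                                                   c(300L, 700L)))
    p <- makePairTable(9,
        sample = c(rep("a", 4), rep("b", 5)),
        r2_pos = c(150L, 160L, 550L, 900L, 150L, 160L, 170L, 550L, 560L))
    p$duplicate <- c(FALSE, TRUE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE, FALSE)
    k <- countBySample(reg, p)
    expect_equal(unname(k[, "a"]), c(1L, 1L))  # duplicate and outside drop
    expect_equal(unname(k[, "b"]), c(3L, 2L))
    expect_warning(countBySample(reg, p, samples = c("a", "b", "ghost")),
                   "zero counts")
})

test_that("median-of-ratios size factors recover depth scalings", {
    set.seed(4)
    base <- rnbinom(300, mu = 100, size = 10)
    counts <- cbind(a = base, b = 2L * base)   # exact 2x depth
    sf <- medianRatioSizeFactors(counts)
    expect_equal(unname(sf["b"] / sf["a"]), 2, tolerance = 1e-9)
    # identical samples: all factors equal (1 after rescaling)
    eq <- medianRatioSizeFactors(cbind(base, base, base))
    expect_equal(unname(eq), rep(1, 3))
    # simulated depth gradient recovered within 5%
    sim <- simulateCounts(nRegions = 800, nPerCondition = 2,
                          depthFactors = c(0.5, 1, 2, 1), seed = 8)
    sf2 <- medianRatioSizeFactors(sim$counts)
    expect_equal(unname(sf2 / sf2[2]), c(0.5, 1, 2, 1), tolerance = 0.05)
})

test_that("size factors agree with the DESeq2 reference implementation", {
    sim <- simulateCounts(nRegions = 400, nPerCondition = 3,
                          depthFactors = c(0.7, 1, 1.5, 0.9, 1.1, 1),
                          seed = 15)
    mine <- medianRatioSizeFactors(sim$counts)
    ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
    expect_equal(unname(mine / exp(mean(log(mine)))),
                 unname(ref / exp(mean(log(ref)))), tolerance = 1e-12)
})

test_that("the NB test is null-calibrated and recovers fold changes", {
    # null: uniform p-values (KS) and no inflated small-p excess
    null <- simulateCounts(nRegions = 2000, nPerCondition = 6, seed = 2)
    sf <- medianRatioSizeFactors(null$counts)
    res <- nbDifferentialTest(null$counts, sf, null$condition)
    expect_gt(stats::ks.test(res$p_value, "punif")$p.value, 0.01)

    # identical counts across conditions: log2FC 0, p near 1
    flat <- matrix(50L, 5, 6, dimnames = list(NULL, letters[1:6]))
    rf <- nbDifferentialTest(flat, rep(1, 6),
                             factor(rep(c("c1", "c2"), each = 3)))
    expect_equal(rf$log2_fold_change, rep(0, 5), tolerance = 1e-6)
    expect_true(all(rf$p_value > 0.99))

    # 4-fold change, 6 vs 6: mean |log2FC| within 0.3 of 2.  Depth is
    # constant by construction, so unit size factors apply (with every
    # region changed, estimating them would rightly absorb the shift).
    fc <- simulateCounts(nRegions = 100, nPerCondition = 6,
                         log2FC = 2, dispersion = 0.1, seed = 5)
    res2 <- nbDifferentialTest(fc$counts, rep(1, 12), fc$condition)
    expect_equal(mean(res2$log2_fold_change), 2, tolerance = 0.3)

    # all-zero region: missing p
    z <- rbind(flat, 0L)
    rz <- nbDifferentialTest(z, rep(1, 6),
                             factor(rep(c("c1", "c2"), each = 3)))
    expect_true(is.na(rz$p_value[6]))
    # degenerate designs refused
    expect_error(nbDifferentialTest(flat, rep(1, 6), factor(rep("c1", 6))))
    expect_error(nbDifferentialTest(flat, rep(1, 6),
                                    factor(c("a", "a", "a", "a", "a", "b"))))
})

test_that("independent filtering censors low-mean regions and BH is monotone", {
    # BH arithmetic on a fixed example with no filtering pressure
    res <- data.frame(base_mean = c(100, 100, 100),
                      dispersion = 0.1,
                      log2_fold_change = 0,
                      p_value = c(0.01, 0.02, 0.9))
    out <- applyIndependentFilter(res)
    expect_equal(out$adjusted_p, c(0.03, 0.03, 0.9))

    # planted signal at high mean: low-mean regions get censored
    set.seed(6)
    n <- 400
    res2 <- data.frame(
        base_mean = c(runif(n / 2, 0.1, 2), runif(n / 2, 50, 500)),
        dispersion = 0.1, log2_fold_change = 0,
        p_value = c(runif(n / 2), c(runif(40) * 1e-4, runif(n / 2 - 40))))
    out2 <- applyIndependentFilter(res2)
    thr <- attr(out2, "filter_threshold")
    expect_gt(thr, 0)
    expect_true(all(is.na(out2$adjusted_p[out2$base_mean < thr])))
    tested <- !is.na(out2$adjusted_p)
    o <- order(out2$p_value[tested])
    expect_true(all(diff(out2$adjusted_p[tested][o]) >= -1e-12))
    # a filtered region keeps NA even with a small raw p
    small <- which(!tested & out2$p_value < 0.05)
    if (length(small)) expect_true(all(is.na(out2$adjusted_p[small])))
})

test_that("hit calling applies alpha, fold change and window composition", {
    ann <- data.frame(
        adjusted_p = c(0.05, 0.04, 0.04, 0.04, 0.2, NA),
        p_value = c(0.01, 0.01, 0.01, 0.01, 0.1, 0.001),
        log2_fold_change = c(1.5, log2(1.9), 3, 1.2, 2, 5),
        distance = c(0L, 0L, 3000L, 0L, 0L, 0L),
        passes_stringent = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
        passes_relaxed = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
        passes_region_consistency = c(TRUE, TRUE, TRUE, FALSE, TRUE,
                                      TRUE))
    hits <- callHits(ann, alpha = 0.05, minFC = 2, window = "relaxed")
    # row 1: apv exactly 0.05 retained; row 2: FC 1.9 dropped;
    # row 3: relaxed-only distance retained; row 4: inconsistent region
    # dropped; row 5: apv 0.2 dropped; row 6: missing apv dropped
    expect_equal(sort(hits$log2_fold_change), c(1.5, 3))
    strict <- callHits(ann, alpha = 0.05, minFC = 2, window = "stringent")
    expect_equal(strict$log2_fold_change, 1.5)
    noFc <- callHits(ann, alpha = 0.05, minFC = NULL, window = "relaxed")
    expect_equal(nrow(noFc), 3L)
    # ordered by adjusted p ascending
    expect_true(!is.unsorted(hits$adjusted_p))
})

test_that("TagCountExperiment validates counts and carries conditions", {
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 100L))
    tce <- TagCountExperiment(matrix(5L, 1, 4), reg,
                              rep(c("c1", "c2"), each = 2),
                              sampleNames = letters[1:4])
    expect_s4_class(tce, "TagCountExperiment")
    expect_null(tagSizeFactors(tce))
    SummarizedExperiment::colData(tce)$sizeFactor <- rep(1, 4)
    expect_equal(unname(tagSizeFactors(tce)), rep(1, 4))
    expect_error(TagCountExperiment(matrix(-1L, 1, 2), reg,
                                    c("c1", "c2")),
                 "non-negative")
})
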