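sft1 <- function(p1, p2, p3 = 0, pO = 0, n = 20) {
    data.frame(chrom = "c", pos_bp = 0L, p1 = p1, p2 = p2, p3 = p3,
               pO = pO, n1 = n, n2 = n, n3 = n, nO = n)
}

test_that("flanking-window layout drops out-of-range windows whole", {
    full <- layoutFlankingWindows("chr1", 5e6, 5.01e6, 1e7)
    expect_equal(nrow(full), 11L)
    expect_equal(full$window_index, -5:5)
    expect_true(all(full$end_bp - full$start_bp == 1e4))

    nearStart <- layoutFlankingWindows("chr1", 2e4, 3e4, 1e7)
    expect_equal(nrow(nearStart), 8L)      # 2 upstream + self + 5 down
    expect_equal(nearStart$window_index, -2:5)

    whole <- layoutFlankingWindows("chr1", 0, 1e6, 1e6)
    expect_equal(nrow(whole), 1L)
    expect_equal(whole$window_index, 0L)

    expect_error(layoutFlankingWindows("chr1", 5e5, 2e6, 1e6), "outside")
})

test_that("Hudson FST matches direct evaluation of the estimator", {
    ## single site, p = 0.2 vs 0.8, n = 20 haplotypes each
    num <- (0.2 - 0.8)^2 - 0.2 * 0.8 / 19 - 0.8 * 0.2 / 19
    expect_equal(fstWindow(sft1(0.2, 0.8)), num / 0.68,
                 tolerance = 1e-10)
    ## identical frequencies: numerator is the (negative) sampling bias
    ## correction; with p fixed at 0 or 1 FST is undefined (no variation)
    expect_true(is.na(fstWindow(sft1(0, 0))))
    ## fixed difference with huge samples approaches 1
    expect_equal(fstWindow(sft1(0, 1, n = 1e9)), 1, tolerance = 1e-6)
    expect_error(fstComponents(0.5, 0.5, 1, 20), ">= 2")
})

test_that("dXY follows the per-site definition with both scalings", {
    expect_equal(as.numeric(dxyWindow(sft1(0, 1))), 1)
    expect_equal(as.numeric(dxyWindow(sft1(0.5, 0.5))), 0.5)
    expect_equal(as.numeric(dxyWindow(sft1(0, 0))), 0)
    two <- rbind(sft1(0, 1), sft1(0, 1))
    two$pos_bp <- c(0L, 1L)
    scaled <- dxyWindow(two, nTotalSites = 10)
    expect_equal(as.numeric(scaled), 0.2)
    expect_equal(attr(scaled, "scaling"), "all-sites")
    expect_equal(attr(dxyWindow(two), "scaling"), "variant-scaled")
    expect_error(dxyWindow(two, nTotalSites = 1), "smaller")
})

test_that("fd matches direct evaluation at the defining sites", {
    ## p2 = p3 puts the site at the maximal-donor bound: fd = 1
    r1 <- fdWindow(sft1(0, 0.6, p3 = 0.6))
    expect_equal(r1$abba - r1$baba, 0.36, tolerance = 1e-12)
    expect_equal(r1$fd, 1, tolerance = 1e-10)
    ## ABBA = BABA = 0 but denominator 0.25: fd = 0
    r2 <- fdWindow(sft1(0, 0, p3 = 0.5))
    expect_equal(r2$d, 0)
    expect_equal(r2$fd, 0)
    ## windows with D < 0 report fd as missing, never clamped
    r3 <- fdWindow(sft1(0.6, 0, p3 = 0.6))
    expect_lt(r3$d, 0)
    expect_true(is.na(r3$fd))
})

test_that("vectorized estimators agree with an independent per-site oracle", {
    sft <- simulatePopgenSites(1000, gamma = 0.25, seed = 77)
    oracle <- oraclePopgen(sft)
    expect_equal(fstWindow(sft), oracle$fst, tolerance = 1e-10)
    expect_equal(as.numeric(dxyWindow(sft)), oracle$dxy,
                 tolerance = 1e-10)
    expect_equal(fdWindow(sft)$d, oracle$d, tolerance = 1e-10)
})

test_that("simulated statistics stay within their analytic ranges", {
    for (s in 1:5) {
        sft <- simulatePopgenSites(2000, gamma = runif(1), seed = 200 + s)
        d <- sft$p1 * (1 - sft$p2) + sft$p2 * (1 - sft$p1)
        expect_true(all(d >= 0 & d <= 1))
        res <- fdWindow(sft)
        expect_true(res$d >= -1 && res$d <= 1)
        if (!is.na(res$fd)) expect_true(res$fd >= 0 && res$fd <= 1)
    }
})

test_that("fd rises monotonically with the introgression fraction", {
    gammas <- seq(0, 0.5, by = 0.1)
    fds <- vapply(gammas, function(g)
        fdWindow(simulatePopgenSites(10000, gamma = g,
                                     seed = 300 + round(100 * g)))$fd,
        numeric(1))
    expect_gt(stats::cor(gammas, fds, method = "spearman"), 0.9)
})

test_that("candidate stats table covers every laid-out window", {
    sft <- simulatePopgenSites(5000, gamma = 0.2, seed = 91,
                               posStepBp = 100)
    cand <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(200001, 240000))
    st <- popgenCandidateStats(sft, cand, chromLengthBp = c(chr1 = 5e5))
    expect_equal(st$window_index, -5:5)
    expect_true(all(st$n_sites == 400))
    expect_true(all(is.finite(st$fst)))
})
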