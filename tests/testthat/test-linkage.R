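test_that("crossover detection handles clean switches, isolated flips and double switches", {
    pos <- c(100L, 200L, 300L, 400L, 500L)
    ## single clean switch between markers 3 and 4
    xo <- detectCrossovers(toyGenotypes(c("A", "A", "A", "B", "B"), pos))
    expect_length(xo, 1L)
    expect_equal(GenomicRanges::start(xo) - 1L, 300L)
    expect_equal(GenomicRanges::end(xo), 400L)
    ## isolated flip suppressed as genotyping error
    expect_length(
        detectCrossovers(toyGenotypes(c("A", "A", "B", "A", "A"), pos)),
        0L)
    ## both runs meet support: two crossovers
    expect_length(
        detectCrossovers(toyGenotypes(c("A", "B", "B", "A", "A"), pos)),
        2L)
})

test_that("missing calls are skipped and the interval extends across them", {
    pos <- c(100L, 200L, 300L, 400L, 500L)
    xo <- detectCrossovers(toyGenotypes(c("A", "A", "N", "B", "B"), pos))
    expect_length(xo, 1L)
    expect_equal(GenomicRanges::start(xo) - 1L, 200L)
    expect_equal(GenomicRanges::end(xo), 400L)
})

test_that("called crossovers are monotone non-increasing in minSupport", {
    cd <- simulateCross(crossConfig(nOffspring = 80, seed = 3,
                                    genotypeErrorRate = 0.02),
                        genome = c(chr1 = 8e6))
    n <- vapply(1:4, function(ms)
        length(detectCrossovers(cd, minSupport = ms)), numeric(1))
    expect_true(all(diff(n) <= 0))
})

test_that("unordered or duplicated marker positions are rejected", {
    bad <- toyGenotypes(c("A", "B"), c(200L, 100L))
    expect_error(detectCrossovers(bad), "ordered")
    dup <- toyGenotypes(c("A", "B"), c(100L, 100L))
    expect_error(detectCrossovers(dup), "increasing")
})

test_that("detection plus estimation recovers simulated truth exactly on clean data", {
    cd <- simulateCross(crossConfig(nOffspring = 120, seed = 17),
                        genome = c(chr1 = 9e6, chr2 = 6e6))
    xo <- detectCrossovers(cd, minSupport = 1L)
    expect_identical(length(xo), length(truthCrossovers(cd)))
    ## every detected interval contains its truth crossover
    hits <- GenomicRanges::countOverlaps(truthCrossovers(cd), xo)
    expect_true(all(hits >= 1L))
    map <- estimateMap(xo, markers(cd), 120)
    expect_equal(totalCM(map) / 100,
                 length(truthCrossovers(cd)) / 120, tolerance = 1e-12)
})

test_that("map estimation follows the recombination-fraction definition", {
    mk <- data.frame(chrom = "chr1", pos_bp = c(0L, 1000L, 2000L))
    xo <- toyCrossovers("chr1", rep(0L, 10), rep(1000L, 10),
                        sprintf("o%d", 1:10), "sp")
    map <- estimateMap(xo, mk, 100)
    cm <- S4Vectors::mcols(markers(map))$cM
    expect_equal(cm, c(0, 10, 10))   # 10 crossovers / 100 offspring
    expect_equal(totalCM(map), 10)
    ## no crossovers anywhere: flat map
    empty <- estimateMap(xo[0], mk, 100)
    expect_equal(totalCM(empty), 0)
    ## endpoints must be marker positions
    bad <- toyCrossovers("chr1", 10L, 500L, "o1", "sp")
    expect_error(estimateMap(bad, mk, 100), "marker")
})

test_that("mean crossovers per offspring equals map length in Morgans", {
    ## printed-scale arithmetic: 1081.2 cM over 335 offspring -> 10.8
    expect_equal(round(1081.2 / 100, 1), 10.8)
    expect_equal(round(1074.1 / 100, 1), 10.7)
    cd <- simulateCross(crossConfig(nOffspring = 90, seed = 8),
                        genome = c(chr1 = 7e6))
    xo <- detectCrossovers(cd, minSupport = 1L)
    map <- estimateMap(xo, markers(cd), 90)
    m <- meanCrossoversPerOffspring(xo, 90,
                                    offspringIds = offspringInfo(cd)$id)
    expect_equal(m$mean, totalCM(map) / 100, tolerance = 1e-12)
    z <- meanCrossoversPerOffspring(xo[0], 50)
    expect_equal(z$mean, 0)
    expect_equal(z$sd, 0)
})

test_that("map statistics reproduce broad-scale rates and gap summaries", {
    tab <- hmelChromosomeMaps()
    ## chromosome 1: 54.6 cM over 17,206,585 bp -> 3.17 cM/Mb
    expect_equal(round(tab$melpomene_cM[1] / (tab$length_bp[1] / 1e6), 2),
                 3.17)
    ## genome: 1081.2 cM over 272,636,897 bp -> 3.97 cM/Mb
    expect_equal(round(sum(tab$melpomene_cM) /
                       (sum(tab$length_bp) / 1e6), 2), 3.97)
    ## two markers: single gap is mean = median = max
    mk <- data.frame(chrom = "chr1", pos_bp = c(0L, 1000000L))
    map <- estimateMap(toyCrossovers("chr1", 0L, 1000000L, "o1", "s"),
                       mk, 10)
    st <- mapStatistics(map, chromLengthBp = c(chr1 = 1e6))
    expect_equal(st$gap_mean_bp[1], 1e6)
    expect_equal(st$gap_median_bp[1], 1e6)
    expect_equal(st$gap_max_bp[1], 1e6)
    expect_error(mapStatistics(estimateMap(
        toyCrossovers("chr1", 0L, 1L, "o1", "s")[0],
        mk[0, , drop = FALSE], 10)), "empty")
})
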