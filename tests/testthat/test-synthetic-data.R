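test_that("obligate-single model yields ~0.5 crossovers per chromosome", {
    cd <- simulateCross(crossConfig(nOffspring = 1000, seed = 11))
    perOff <- length(truthCrossovers(cd)) / 1000
    ## closed form: 21 chromosomes x P(recombinant chromatid) = 10.5,
    ## allow 3 binomial standard errors
    se <- sqrt(21 * 0.25 / 1000)
    expect_lt(abs(perOff - 10.5), 3 * se)
})

test_that("female meiosis contributes no crossovers", {
    cd <- simulateCross(crossConfig(nOffspring = 100, seed = 2),
                        genome = c(chr1 = 5e6, chr2 = 4e6))
    expect_true(all(truthCrossovers(cd)$parent == "paternal"))
    expect_error(
        methods::validObject(methods::initialize(cd,
            truthCrossovers = {
                tc <- truthCrossovers(cd)
                tc$parent[1] <- "maternal"
                tc
            })),
        "achiasmatic")
})

test_that("simulateCross is deterministic under a fixed seed", {
    cfg <- crossConfig(nOffspring = 50, genotypeErrorRate = 0.01,
                       missingRate = 0.02, seed = 99)
    g <- c(chr1 = 5e6, chr2 = 3e6)
    a <- simulateCross(cfg, g)
    b <- simulateCross(cfg, g)
    expect_identical(genotypeMatrix(a), genotypeMatrix(b))
    expect_identical(truthCrossovers(a), truthCrossovers(b))
    expect_identical(markers(a), markers(b))
})

test_that("full suppression removes crossovers inside the inversion in hybrids", {
    inv <- truthInversions("chr1", 1e6, 3e6, carrier = "cydno",
                           suppression = 1, genome = c(chr1 = 6e6))
    cd <- simulateCross(
        crossConfig("hybrid_backcross", nOffspring = 400, seed = 5),
        genome = c(chr1 = 6e6), inversions = inv)
    tc <- truthCrossovers(cd)
    pos <- GenomicRanges::start(tc) - 1L
    expect_equal(sum(pos >= 1e6 & pos < 3e6), 0L)
    ## but crossovers still occur outside and the obligate count holds
    expect_gt(length(tc), 100)
})

test_that("within-species fathers are homozygous: no suppression applies", {
    inv <- truthInversions("chr1", 1e6, 3e6, carrier = "cydno",
                           suppression = 1, genome = c(chr1 = 6e6))
    cd <- simulateCross(
        crossConfig("within_species_F1", nOffspring = 400, seed = 5,
                    label = "cydno"),
        genome = c(chr1 = 6e6), inversions = inv)
    pos <- GenomicRanges::start(truthCrossovers(cd)) - 1L
    expect_gt(sum(pos >= 1e6 & pos < 3e6), 0L)
})

test_that("truth crossovers equal paternal phase switches before errors", {
    cd <- simulateCross(crossConfig(nOffspring = 60, seed = 13),
                        genome = c(chr1 = 8e6, chr2 = 5e6))
    geno <- genotypeMatrix(cd)
    chrom <- as.character(GenomicRanges::seqnames(markers(cd)))
    tc <- truthCrossovers(cd)
    for (j in seq_len(ncol(geno))) {
        switches <- 0L
        for (ch in unique(chrom)) {
            r <- rle(geno[chrom == ch, j])
            switches <- switches + length(r$lengths) - 1L
        }
        expect_identical(
            switches,
            sum(tc$offspring == colnames(geno)[j]))
    }
})

test_that("increasing suppression monotonically removes inversion crossovers", {
    inv <- function(s) truthInversions("chr1", 1e6, 4e6, "cydno",
                                       suppression = s,
                                       genome = c(chr1 = 8e6))
    counts <- vapply(c(0, 0.5, 1), function(s) {
        cd <- simulateCross(
            crossConfig("hybrid_backcross", nOffspring = 500, seed = 21),
            genome = c(chr1 = 8e6), inversions = inv(s))
        pos <- GenomicRanges::start(truthCrossovers(cd)) - 1L
        sum(pos >= 1e6 & pos < 4e6)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[3], 0)
})

test_that("inversions outside the genome and bad configs are rejected", {
    expect_error(truthInversions("chr1", 1e6, 9e6, "c",
                                 genome = c(chr1 = 6e6)), "outside")
    expect_error(crossConfig(nOffspring = 0), ">= 1")
    expect_error(crossConfig(genotypeErrorRate = 1.5), "rates")
})

test_that("split-read simulator emits truth candidates in both sexes plus FPs", {
    g <- c(chr1 = 1e7)
    tr <- truthInversions("chr1", 2e6, 2.5e6, "cydno", genome = g)
    only <- simulateSplitReadCandidates(tr, fpCount = 0, genome = g,
                                        seed = 1)
    expect_length(only, 2L)
    expect_setequal(only$sex, c("F", "M"))
    expect_true(all(only$species == "cydno" & only$tier == "default"))

    fps <- simulateSplitReadCandidates(NULL, fpCount = 49, genome = g,
                                       seed = 1)
    expect_length(fps, 49L)
    expect_identical(
        simulateSplitReadCandidates(tr, 10, genome = g, seed = 3),
        simulateSplitReadCandidates(tr, 10, genome = g, seed = 3))
})

test_that("trio alignments are collinear without inversions and split at breakpoints", {
    g <- c(chr1 = 2e6)
    aln0 <- simulateTrioAlignments(NULL, g, scaffoldN50Bp = 5e4, seed = 2)
    expect_true(all(aln0$orientation == "forward"))
    expect_identical(aln0,
        simulateTrioAlignments(NULL, g, scaffoldN50Bp = 5e4, seed = 2))

    tr <- truthInversions("chr1", 8e5, 1.2e6, "cydno", genome = g)
    aln <- simulateTrioAlignments(tr, g, scaffoldN50Bp = 5e4, seed = 2)
    carrier <- aln[aln$species == "cydno"]
    expect_gt(sum(carrier$orientation == "reverse"), 0)
    ## non-carrier scaffolds span each breakpoint collinearly
    other <- aln[aln$species == "melpomene" & aln$orientation == "forward"]
    s <- GenomicRanges::start(other) - 1L; e <- GenomicRanges::end(other)
    for (bk in c(8e5, 1.2e6))
        expect_true(any(s < bk & e > bk))
})

test_that("popgen site simulator is deterministic and behaves at the gamma extremes", {
    a <- simulatePopgenSites(500, gamma = 0.3, seed = 31)
    b <- simulatePopgenSites(500, gamma = 0.3, seed = 31)
    expect_identical(a, b)

    ## no introgression: genome-wide fd near zero
    null <- simulatePopgenSites(2e5, gamma = 0, seed = 32)
    fd0 <- fdWindow(null)$fd
    if (!is.na(fd0)) expect_lt(abs(fd0), 0.02)

    ## complete replacement of P2 by P3 frequencies forces fd = 1
    rep2 <- simulatePopgenSites(5000, gamma = 0, seed = 33)
    rep2$p2 <- rep2$p3
    expect_equal(fdWindow(rep2)$fd, 1, tolerance = 1e-12)
})
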