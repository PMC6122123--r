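test_that("recombination filter rejects on same-species containment only", {
    cand <- toyCandidate(startBp = 100000, endBp = 200000, species = "X")
    contained <- toyCrossovers("chr1", 120000, 130000, "o1", "X")
    res <- filterByRecombination(cand, contained)
    expect_length(res$kept, 0L)
    expect_equal(res$rejected$reason, "same_species_recombination")

    otherSpecies <- toyCrossovers("chr1", 120000, 130000, "o1", "Y")
    expect_length(filterByRecombination(cand, otherSpecies)$kept, 1L)

    partial <- toyCrossovers("chr1", 90000, 110000, "o1", "X")
    expect_length(filterByRecombination(cand, partial)$kept, 1L)
})

test_that("trio-span filter applies the strict half-length rule on both sides", {
    cand <- toyCandidate(startBp = 100000, endBp = 110000, species = "X")
    spanning <- trioAlignments("chr1", 94000, 116000, "sc1", "X")
    expect_length(filterByTrioSpan(cand, spanning)$kept, 0L)

    shortLeft <- trioAlignments("chr1", 96000, 116000, "sc1", "X")
    expect_length(filterByTrioSpan(cand, shortLeft)$kept, 1L)
    ## under "either" the 6 kb right extension alone suffices
    expect_length(
        filterByTrioSpan(cand, shortLeft, spanMode = "either")$kept, 0L)

    otherSpecies <- trioAlignments("chr1", 94000, 116000, "sc1", "Y")
    expect_length(filterByTrioSpan(cand, otherSpecies)$kept, 1L)

    inverted <- trioAlignments("chr1", 94000, 116000, "sc1", "X",
                               orientation = "reverse")
    expect_length(filterByTrioSpan(cand, inverted)$kept, 1L)
})

test_that("length filter is strictly below the cutoff", {
    cands <- c(toyCandidate(startBp = 0, endBp = 900),
               toyCandidate(startBp = 5000, endBp = 6000),
               toyCandidate(startBp = 10000, endBp = 30247))
    res <- filterByLength(cands)
    expect_length(res$kept, 2L)
    expect_equal(GenomicRanges::width(res$rejected), 900L)
    ## the 1,000 bp and 20,247 bp candidates survive
    expect_setequal(GenomicRanges::width(res$kept), c(1000L, 20247L))
})

test_that("tentative candidates are rescued only by other samples", {
    def <- toyCandidate(startBp = 10000, endBp = 20000, species = "X",
                        sex = "F")
    tSameRegionOtherSex <- toyCandidate(startBp = 15000, endBp = 25000,
                                        species = "X", sex = "M",
                                        tier = "tentative")
    tIsolated <- toyCandidate(startBp = 500000, endBp = 510000,
                              species = "X", sex = "M",
                              tier = "tentative")
    tSameSample <- toyCandidate(startBp = 15000, endBp = 25000,
                                species = "X", sex = "F",
                                tier = "tentative")
    out <- rescueTentative(def, c(tSameRegionOtherSex, tIsolated,
                                  tSameSample))
    expect_length(out, 2L)
    expect_setequal(out$sex[out$tier == "tentative"], "M")
    expect_identical(rescueTentative(def, def[0]), def)
})

test_that("overlap merging chains transitively but never merges touching intervals", {
    g1 <- mergeGroups(c(toyCandidate(startBp = 1, endBp = 5),
                        toyCandidate(startBp = 4, endBp = 8),
                        toyCandidate(startBp = 10, endBp = 12)))
    expect_length(g1, 2L)
    g2 <- mergeGroups(c(toyCandidate(startBp = 1, endBp = 5),
                        toyCandidate(startBp = 4, endBp = 8),
                        toyCandidate(startBp = 7, endBp = 12)))
    expect_length(g2, 1L)
    expect_equal(GenomicRanges::start(g2) - 1L, 1L)
    expect_equal(GenomicRanges::end(g2), 12L)
    ## book-ended: [1,5) and [5,8) share no bp
    g3 <- mergeGroups(c(toyCandidate(startBp = 1, endBp = 5),
                        toyCandidate(startBp = 5, endBp = 8)))
    expect_length(g3, 2L)
    expect_length(mergeGroups(toyCandidate(startBp = 1, endBp = 2)[0]),
                  0L)
})

test_that("groups never overlap each other", {
    set.seed(14)
    n <- 60
    s <- sample.int(1e6, n)
    cands <- splitReadCandidates("chr1", s, s + sample.int(5e4, n),
                                 species = sample(c("X", "Y"), n, TRUE))
    groups <- mergeGroups(cands)
    if (length(groups) > 1L)
        expect_equal(sum(GenomicRanges::countOverlaps(groups, groups) -
                         1L), 0L)
})

test_that("classification distinguishes the three evidence patterns", {
    mkAln <- function(species, orientations, startsBp, endsBp,
                      scaffold = "sc1")
        trioAlignments("chr1", startsBp, endsBp, scaffold, species,
                       orientation = orientations)
    ## split reads in X plus an X scaffold with forward+reverse flanking
    candX <- toyCandidate(startBp = 50000, endBp = 60000, species = "X")
    invX <- mkAln("X", c("forward", "reverse"), c(40000, 50000),
                  c(50000, 60000))
    gX <- classifyGroups(mergeGroups(candX), candX, invX)
    expect_equal(gX$classification, "split_and_trio")
    expect_equal(gX$species_set, "X")

    ## split reads in both species, no inverted scaffolds
    candXY <- c(candX,
                toyCandidate(startBp = 55000, endBp = 65000,
                             species = "Y"))
    fwdOnly <- mkAln("X", "forward", 40000, 70000)
    gXY <- classifyGroups(mergeGroups(candXY), candXY, fwdOnly)
    expect_equal(gXY$classification, "split_only")
    expect_equal(gXY$species_set, "X,Y")

    ## split reads in X only, inverted scaffolds in both species
    invBoth <- c(mkAln("X", c("forward", "reverse"), c(40000, 50000),
                       c(50000, 60000), "scX"),
                 mkAln("Y", c("forward", "reverse"), c(40000, 50000),
                       c(50000, 60000), "scY"))
    gOne <- classifyGroups(mergeGroups(candX), candX, invBoth)
    expect_equal(gOne$classification, "split_one_trio_both")
    expect_equal(gOne$species_set, "X,Y")
})

test_that("contig-boundary proximity is flagged at the configured distance", {
    cand <- toyCandidate(startBp = 50000, endBp = 60000, species = "X")
    contigs <- data.frame(chrom = "chr1", boundary_bp = 63000)
    g <- classifyGroups(mergeGroups(cand), cand,
                        trioAlignments("chr1", 1, 2, "s", "X")[0],
                        contigs = contigs, nearBp = 5000)
    expect_true(g$near_contig_boundary)
    gFar <- classifyGroups(mergeGroups(cand), cand,
                           trioAlignments("chr1", 1, 2, "s", "X")[0],
                           contigs = contigs, nearBp = 1000)
    expect_false(gFar$near_contig_boundary)
})

test_that("filters are order-independent, idempotent and reasons partition", {
    g <- c(chr1 = 1e7)
    tr <- truthInversions("chr1", 3e6, 3.6e6, "cydno", genome = g)
    cands <- simulateSplitReadCandidates(tr, fpCount = 40, genome = g,
                                         seed = 19)
    cd <- simulateCross(crossConfig(nOffspring = 150, seed = 20,
                                    label = "melpomene"), genome = g)
    xo <- detectCrossovers(cd, minSupport = 1L)
    aln <- simulateTrioAlignments(tr, g, scaffoldN50Bp = 1e5, seed = 21)

    f1 <- filterByRecombination(cands, xo)
    f2 <- filterByTrioSpan(cands, aln)
    f3 <- filterByLength(cands)
    ## each filter is a pure per-candidate predicate: the intersection of
    ## individually kept sets equals sequential application in any order
    seqKept <- filterByLength(filterByTrioSpan(
        filterByRecombination(cands, xo)$kept, aln)$kept)$kept
    revKept <- filterByRecombination(filterByTrioSpan(
        filterByLength(cands)$kept, aln)$kept, xo)$kept
    expect_identical(sort(seqKept), sort(revKept))
    ## idempotence
    expect_identical(filterByLength(f3$kept)$kept, f3$kept)
    ## the sieve report partitions candidates into kept + one reason each
    sv <- runSieve(cands, xo, aln)
    expect_equal(nrow(sv$report), length(cands))
    expect_true(all(sv$report$reason[sv$report$decision == "kept"] == ""))
})

test_that("planted inversions that pass the length rule survive the sieve", {
    g <- c(chr1 = 1.5e7)
    tr <- truthInversions("chr1", 5e6, 5.8e6, "cydno", suppression = 1,
                          genome = g)
    ## carrier-species crossovers come from the hybrid cross, where the
    ## inversion suppresses them inside the interval
    cdH <- simulateCross(crossConfig("hybrid_backcross",
                                     nOffspring = 200, seed = 23,
                                     label = "cydno"),
                         genome = g, inversions = tr)
    xo <- detectCrossovers(cdH, minSupport = 1L)
    cands <- simulateSplitReadCandidates(tr, fpCount = 30, genome = g,
                                         seed = 24)
    aln <- simulateTrioAlignments(tr, g, scaffoldN50Bp = 1e5, seed = 25)
    sv <- runSieve(cands, xo, aln)
    truthHits <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges("chr1",
            IRanges::IRanges(5e6 + 1, 5.8e6)), sv$kept, type = "equal")
    ## both sexes' truth candidates retained
    expect_equal(length(truthHits), 2L)
})
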