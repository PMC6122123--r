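#' Configuration for a simulated mapping cross
#'
#' Bundles the parameters of one simulated cross design. Two designs are
#' supported: \code{"within_species_F1"}, where the father is homozygous for
#' any species-specific inversion (so inversions do not suppress his
#' crossovers), and \code{"hybrid_backcross"}, where the F1 father is
#' heterozygous for every species-specific inversion and crossovers falling
#' inside a planted inversion are suppressed.
#'
#' @param design One of \code{"within_species_F1"}, \code{"hybrid_backcross"}.
#' @param nOffspring Number of offspring (>= 1). Defaults to 300, the
#'   approximate per-group size of the published cross designs.
#' @param nCrosses Number of independent crosses the offspring are divided
#'   into (round-robin).
#' @param markerGapMeanBp Mean inter-marker gap in bp. Gaps are drawn from an
#'   exponential distribution; the default 115,000 matches the published mean
#'   marker spacing.
#' @param genotypeErrorRate Per-call probability of a symmetric A/B flip.
#' @param missingRate Per-call probability of a missing ("N") call.
#' @param maleCrossoverModel \code{"obligate_single"} (one obligate crossover
#'   per paternal bivalent, inherited with probability 1/2, giving ~50 cM
#'   chromosomes) or \code{"poisson"} (Poisson(0.5) crossovers per offspring
#'   chromosome).
#' @param label Group label attached to the offspring (e.g. a species name).
#' @param seed Integer seed; all randomness in \code{\link{simulateCross}}
#'   flows from it.
#'
#' @return A list of class \code{"CrossConfig"}.
#' @examples
#' crossConfig("within_species_F1", nOffspring = 50, seed = 1)
#' @export
crossConfig <- function(design = c("within_species_F1", "hybrid_backcross"),
                        nOffspring = 300L,
                        nCrosses = 1L,
                        markerGapMeanBp = 115000,
                        genotypeErrorRate = 0,
                        missingRate = 0,
                        maleCrossoverModel = c("obligate_single", "poisson"),
                        label = NULL,
                        seed = NULL) {
    design <- match.arg(design)
    maleCrossoverModel <- match.arg(maleCrossoverModel)
    nOffspring <- as.integer(nOffspring)
    if (is.na(nOffspring) || nOffspring < 1L)
        stop("'nOffspring' must be >= 1")
    if (nCrosses < 1L) stop("'nCrosses' must be >= 1")
    if (markerGapMeanBp <= 0) stop("'markerGapMeanBp' must be positive")
    for (r in c(genotypeErrorRate, missingRate))
        if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
    if (is.null(label))
        label <- if (design == "hybrid_backcross") "hybrid" else "parental"
    structure(list(design = design, nOffspring = nOffspring,
                   nCrosses = as.integer(nCrosses),
                   markerGapMeanBp = markerGapMeanBp,
                   genotypeErrorRate = genotypeErrorRate,
                   missingRate = missingRate,
                   maleCrossoverModel = maleCrossoverModel,
                   label = label, seed = seed),
              class = "CrossConfig")
}

#' Planted ground-truth inversions
#'
#' Builds a GRanges of inversions to plant in a simulation, each carried by
#' one species and suppressing crossovers in heterozygotes (hybrid F1
#' fathers) with the given probability.
#'
#' @param chrom Chromosome names.
#' @param startBp,endBp 0-based half-open interval bounds (bp).
#' @param carrier Carrier species label per inversion.
#' @param suppression Probability that a crossover falling inside the
#'   interval is suppressed in a heterozygote (default 1).
#' @param genome A \linkS4class{Seqinfo} (or named length vector) the
#'   inversions must lie within.
#'
#' @return A GRanges with metadata columns \code{carrier}, \code{suppression}.
#' @examples
#' truthInversions("chr1", 2e6, 4e6, carrier = "cydno",
#'                 genome = hmelGenome())
#' @export
truthInversions <- function(chrom, startBp, endBp, carrier,
                            suppression = 1, genome = hmelGenome()) {
    genome <- .asSeqinfo(genome)
    n <- length(chrom)
    sl <- GenomeInfoDb::seqlengths(genome)
    if (!all(chrom %in% names(sl)) || any(is.na(sl[chrom])) ||
        any(endBp > sl[chrom]) || any(startBp < 0))
        stop("inversion outside chromosome bounds")
    gr <- .grFromHalfOpen(chrom, startBp, endBp, seqinfo = genome)
    if (any(suppression < 0 | suppression > 1))
        stop("'suppression' must lie in [0, 1]")
    S4Vectors::mcols(gr)$carrier <- rep_len(carrier, n)
    S4Vectors::mcols(gr)$suppression <- rep_len(suppression, n)
    gr
}

## Draw exponential inter-marker gaps along one chromosome, anchoring a
## marker at each chromosome end so the map spans the physical sequence.
.drawMarkers <- function(lengthBp, gapMeanBp) {
    nGuess <- max(10L, ceiling(lengthBp / gapMeanBp * 2))
    pos <- cumsum(ceiling(stats::rexp(nGuess, rate = 1 / gapMeanBp)))
    while (length(pos) && pos[length(pos)] < lengthBp)
        pos <- c(pos, pos[length(pos)] +
                 cumsum(ceiling(stats::rexp(nGuess, rate = 1 / gapMeanBp))))
    sort(unique(c(1, pos[pos < lengthBp], lengthBp)))
}

#' Simulate a mapping cross with known crossovers
#'
#' Simulates ordered markers and per-offspring paternal-phase genotypes for
#' a cross on a given genome. Female meiosis is achiasmatic, so only the
#' paternal gamete recombines: under the obligate-single model each paternal
#' bivalent carries exactly one crossover and each offspring inherits a
#' recombined chromatid with probability 1/2, i.e. every offspring
#' chromosome carries 0 or 1 crossover with equal probability (a ~50 cM map
#' per chromosome). Crossover positions are uniform on physical length;
#' positions falling inside a planted inversion for which the father is
#' heterozygous (hybrid backcross design only) are suppressed with the
#' inversion's suppression probability and redrawn, preserving the obligate
#' count. Genotypes are derived from the true phase, then perturbed by
#' independent symmetric errors and missingness.
#'
#' @param config A \code{\link{crossConfig}} object.
#' @param genome A \linkS4class{Seqinfo} or named vector of chromosome
#'   lengths (default: the 21 published chromosome lengths).
#' @param inversions Optional GRanges from \code{\link{truthInversions}}.
#'
#' @return A \linkS4class{CrossDataset}.
#' @examples
#' cd <- simulateCross(crossConfig(nOffspring = 20, seed = 1),
#'                     genome = c(chr1 = 5e6))
#' cd
#' @export
simulateCross <- function(config, genome = hmelGenome(), inversions = NULL) {
    if (!inherits(config, "CrossConfig"))
        stop("'config' must be created by crossConfig()")
    genome <- .asSeqinfo(genome)
    sl <- GenomeInfoDb::seqlengths(genome)
    if (!is.null(inversions) && length(inversions)) {
        invChrom <- as.character(GenomeInfoDb::seqnames(inversions))
        if (!all(invChrom %in% names(sl)) ||
            any(GenomicRanges::end(inversions) > sl[invChrom]))
            stop("inversion outside genome")
    }
    .setSeed(config$seed)
    n <- config$nOffspring
    het <- config$design == "hybrid_backcross"

    ids <- sprintf("O%04d", seq_len(n))
    offDf <- S4Vectors::DataFrame(
        id = ids,
        group = rep(config$label, n),
        cross = rep_len(seq_len(config$nCrosses), n),
        sex = sample(c("F", "M"), n, replace = TRUE))

    markerChrom <- character()
    markerPos <- integer()
    genoList <- list()
    xoChrom <- character(); xoPos <- integer(); xoOff <- character()

    for (chrom in names(sl)) {
        L <- sl[[chrom]]
        pos <- .drawMarkers(L, config$markerGapMeanBp)
        nm <- length(pos)

        ## heterozygous inversions on this chromosome (hybrid design only)
        invS <- invE <- numeric(0); invP <- numeric(0)
        if (het && !is.null(inversions) && length(inversions)) {
            onc <- inversions[as.character(
                GenomeInfoDb::seqnames(inversions)) == chrom]
            if (length(onc)) {
                invS <- .hoStart(onc); invE <- .hoEnd(onc)
                invP <- S4Vectors::mcols(onc)$suppression
            }
        }

        nxo <- switch(config$maleCrossoverModel,
            obligate_single = stats::rbinom(n, 1L, 0.5),
            poisson = stats::rpois(n, 0.5))
        phase0 <- sample(c("A", "B"), n, replace = TRUE)

        geno <- matrix(NA_character_, nrow = nm, ncol = n)
        for (j in seq_len(n)) {
            xs <- numeric(0)
            for (k in seq_len(nxo[j])) {
                repeat {
                    x <- stats::runif(1, 0, L)
                    if (length(invS)) {
                        inside <- which(x >= invS & x < invE)
                        if (length(inside) &&
                            stats::runif(1) < max(invP[inside]))
                            next  # suppressed in heterokaryotype: redraw
                    }
                    break
                }
                xs <- c(xs, x)
            }
            xs <- sort(xs)
            ## phase flips at each crossover; markers at pos >= x switch
            flips <- findInterval(pos, xs)
            ph <- ifelse(flips %% 2L == 0L, phase0[j],
                         ifelse(phase0[j] == "A", "B", "A"))
            geno[, j] <- ph
            if (length(xs)) {
                xoChrom <- c(xoChrom, rep(chrom, length(xs)))
                xoPos <- c(xoPos, as.integer(ceiling(xs)))
                xoOff <- c(xoOff, rep(ids[j], length(xs)))
            }
        }
        markerChrom <- c(markerChrom, rep(chrom, nm))
        markerPos <- c(markerPos, pos)
        genoList[[chrom]] <- geno
    }

    geno <- do.call(rbind, genoList)
    ## error and missingness injection, independent per call
    if (config$genotypeErrorRate > 0) {
        flip <- matrix(stats::runif(length(geno)) <
                       config$genotypeErrorRate, nrow = nrow(geno))
        geno[flip] <- ifelse(geno[flip] == "A", "B", "A")
    }
    if (config$missingRate > 0) {
        miss <- matrix(stats::runif(length(geno)) <
                       config$missingRate, nrow = nrow(geno))
        geno[miss] <- "N"
    }
    dimnames(geno) <- list(NULL, ids)

    mk <- GenomicRanges::GRanges(markerChrom,
        IRanges::IRanges(start = markerPos, width = 1L), seqinfo = genome)
    tc <- GenomicRanges::GRanges(xoChrom,
        IRanges::IRanges(start = pmax(1L, xoPos), width = 1L),
        seqinfo = genome)
    S4Vectors::mcols(tc)$offspring <- xoOff
    S4Vectors::mcols(tc)$parent <- rep("paternal", length(tc))

    methods::new("CrossDataset", genome = genome, markers = mk,
                 genotypes = geno, truthCrossovers = sort(tc),
                 offspring = offDf, config = unclass(config))
}
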