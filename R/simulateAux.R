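#' Build a split-read candidate set
#'
#' Constructor for split-read inversion candidates as a GRanges with the
#' metadata the sieve expects: \code{species}, \code{sex},
#' \code{supportReads} and \code{tier} (\code{"default"} for candidates
#' meeting the caller's standard read support, \code{"tentative"} for
#' low-support calls eligible only for rescue).
#'
#' @param chrom,startBp,endBp Candidate intervals (bp, 0-based half-open).
#' @param species,sex Sample labels per candidate.
#' @param supportReads Supporting read count (>= 1).
#' @param tier \code{"default"} or \code{"tentative"}.
#' @param genome Optional \linkS4class{Seqinfo} or named length vector.
#' @return A GRanges.
#' @export
splitReadCandidates <- function(chrom, startBp, endBp, species, sex = "F",
                                supportReads = 3L, tier = "default",
                                genome = NULL) {
    si <- if (is.null(genome)) NULL else .asSeqinfo(genome)
    gr <- .grFromHalfOpen(chrom, startBp, endBp, seqinfo = si)
    n <- length(gr)
    if (any(supportReads < 1L)) stop("'supportReads' must be >= 1")
    if (!all(tier %in% c("default", "tentative")))
        stop("'tier' must be 'default' or 'tentative'")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        species = rep_len(species, n), sex = rep_len(sex, n),
        supportReads = as.integer(rep_len(supportReads, n)),
        tier = rep_len(tier, n))
    gr
}

#' Simulate split-read inversion candidates
#'
#' Emulates the output of a split-read structural-variant caller: every true
#' inversion yields one default-tier candidate in each sex of its carrier
#' species, and \code{fpCount} spurious candidates are placed uniformly on
#' the genome with exponentially distributed lengths, random species/sex and
#' a mix of default and tentative support tiers.
#'
#' @param truth GRanges of planted inversions (see
#'   \code{\link{truthInversions}}); may be empty.
#' @param fpCount Number of false-positive candidates (>= 0).
#' @param fpLengthMeanBp Mean false-positive length (bp).
#' @param genome \linkS4class{Seqinfo} or named length vector.
#' @param speciesNames Species labels used for false positives.
#' @param seed Integer seed.
#' @return A GRanges of candidates (see \code{\link{splitReadCandidates}}).
#' @examples
#' tr <- truthInversions("chr1", 2e6, 2.5e6, "cydno", genome = hmelGenome())
#' simulateSplitReadCandidates(tr, fpCount = 10, seed = 1)
#' @export
simulateSplitReadCandidates <- function(truth, fpCount = 0L,
                                        fpLengthMeanBp = 10000,
                                        genome = hmelGenome(),
                                        speciesNames = c("melpomene",
                                                         "cydno"),
                                        seed = NULL) {
    if (fpCount < 0L) stop("'fpCount' must be >= 0")
    genome <- .asSeqinfo(genome)
    sl <- GenomeInfoDb::seqlengths(genome)
    .setSeed(seed)

    chrom <- character(); s <- integer(); e <- integer()
    sp <- character(); sex <- character(); reads <- integer()
    tier <- character()

    if (!is.null(truth) && length(truth)) {
        for (i in seq_along(truth)) {
            for (sx in c("F", "M")) {
                chrom <- c(chrom, as.character(
                    GenomeInfoDb::seqnames(truth))[i])
                s <- c(s, .hoStart(truth)[i])
                e <- c(e, .hoEnd(truth)[i])
                sp <- c(sp, S4Vectors::mcols(truth)$carrier[i])
                sex <- c(sex, sx)
                reads <- c(reads, sample(3:12, 1L))
                tier <- c(tier, "default")
            }
        }
    }
    if (fpCount > 0L) {
        fpChrom <- sample(names(sl), fpCount, replace = TRUE,
                          prob = as.numeric(sl))
        fpLen <- pmax(200L, as.integer(ceiling(
            stats::rexp(fpCount, rate = 1 / fpLengthMeanBp))))
        fpLen <- pmin(fpLen, as.integer(sl[fpChrom]))
        fpStart <- as.integer(floor(stats::runif(fpCount, 0,
            as.numeric(sl[fpChrom]) - fpLen)))
        fpTier <- sample(c("default", "tentative"), fpCount,
                         replace = TRUE, prob = c(0.7, 0.3))
        chrom <- c(chrom, fpChrom)
        s <- c(s, fpStart); e <- c(e, fpStart + fpLen)
        sp <- c(sp, sample(speciesNames, fpCount, replace = TRUE))
        sex <- c(sex, sample(c("F", "M"), fpCount, replace = TRUE))
        reads <- c(reads, ifelse(fpTier == "default",
                                 sample(3:8, fpCount, replace = TRUE), 2L))
        tier <- c(tier, fpTier)
    }
    if (!length(chrom))
        return(GenomicRanges::GRanges(seqinfo = genome))
    splitReadCandidates(chrom, s, e, sp, sex, reads, tier, genome = genome)
}

#' Simulate trio-assembly scaffold alignments
#'
#' Tiles each species' haplotype with scaffolds (exponential lengths scaled
#' so the length-weighted median approximates the requested N50) and emits
#' coords-style alignments to the reference. A scaffold of the carrier
#' species crossing a planted inversion is split at the breakpoints into
#' forward segments outside and reverse segments inside the inversion;
#' scaffolds of the non-carrier species align collinearly (forward) across
#' the same interval.
#'
#' @param truth GRanges of planted inversions; may be empty or NULL.
#' @param genome \linkS4class{Seqinfo} or named length vector.
#' @param scaffoldN50Bp Target scaffold N50 (bp); default 20,000, on the
#'   order of published short-read trio assemblies.
#' @param speciesNames Species to tile (both carriers and non-carriers).
#' @param sexes Sexes to tile per species.
#' @param seed Integer seed.
#' @return A GRanges of alignments with metadata columns \code{scaffold},
#'   \code{species}, \code{sex}, \code{orientation}, \code{identity}.
#' @examples
#' tr <- truthInversions("chr1", 2e6, 2.1e6, "cydno", genome = hmelGenome())
#' aln <- simulateTrioAlignments(tr, hmelGenome(), seed = 1)
#' table(aln$orientation)
#' @export
simulateTrioAlignments <- function(truth = NULL, genome = hmelGenome(),
                                   scaffoldN50Bp = 20000,
                                   speciesNames = c("melpomene", "cydno"),
                                   sexes = c("F", "M"), seed = NULL) {
    if (scaffoldN50Bp <= 0) stop("'scaffoldN50Bp' must be positive")
    genome <- .asSeqinfo(genome)
    sl <- GenomeInfoDb::seqlengths(genome)
    .setSeed(seed)
    ## for exponential lengths the length-weighted median (N50) is about
    ## 1.68x the mean, so scale the mean down accordingly
    meanLen <- scaffoldN50Bp / 1.678

    out <- list()
    for (spn in speciesNames) {
        bks <- list()
        if (!is.null(truth) && length(truth)) {
            carried <- truth[S4Vectors::mcols(truth)$carrier == spn]
            bks <- split(data.frame(s = .hoStart(carried),
                                    e = .hoEnd(carried)),
                         as.character(GenomeInfoDb::seqnames(carried)))
        }
        for (sx in sexes) {
            for (chrom in names(sl)) {
                L <- as.numeric(sl[[chrom]])
                lens <- ceiling(stats::rexp(ceiling(L / meanLen * 1.5) + 5,
                                            rate = 1 / meanLen)) + 500
                ends <- cumsum(lens)
                ends <- c(ends[ends < L], L)
                starts <- c(0, utils::head(ends, -1L))
                nsc <- length(starts)
                scf <- sprintf("%s_%s_%s_s%05d", spn, sx, chrom,
                               seq_len(nsc))
                inv <- bks[[chrom]]
                for (i in seq_len(nsc)) {
                    segS <- starts[i]; segE <- ends[i]
                    cuts <- numeric(0)
                    if (!is.null(inv) && nrow(inv)) {
                        cuts <- sort(unique(c(inv$s, inv$e)))
                        cuts <- cuts[cuts > segS & cuts < segE]
                    }
                    bounds <- c(segS, cuts, segE)
                    for (k in seq_len(length(bounds) - 1L)) {
                        a <- bounds[k]; b <- bounds[k + 1L]
                        mid <- (a + b) / 2
                        inside <- !is.null(inv) && nrow(inv) &&
                            any(mid >= inv$s & mid < inv$e)
                        out[[length(out) + 1L]] <- data.frame(
                            chrom = chrom, s = a, e = b, scaffold = scf[i],
                            species = spn, sex = sx,
                            orientation = if (inside) "reverse"
                                          else "forward",
                            identity = round(stats::runif(1, 98.5, 99.9),
                                             2))
                    }
                }
            }
        }
    }
    df <- do.call(rbind, out)
    trioAlignments(df$chrom, df$s, df$e, df$scaffold, df$species, df$sex,
                   df$orientation, df$identity, genome = genome)
}

#' Build a trio scaffold alignment set
#'
#' Constructor for coords-style alignments of trio-assembly scaffolds to the
#' reference, as a GRanges with metadata \code{scaffold}, \code{species},
#' \code{sex}, \code{orientation} (\code{"forward"}/\code{"reverse"}) and
#' percent \code{identity}.
#'
#' @param chrom,startBp,endBp Reference intervals (bp, 0-based half-open).
#' @param scaffold,species,sex,orientation,identity Per-alignment metadata.
#' @param genome Optional \linkS4class{Seqinfo} or named length vector.
#' @return A GRanges.
#' @export
trioAlignments <- function(chrom, startBp, endBp, scaffold, species,
                           sex = "F", orientation = "forward",
                           identity = 99, genome = NULL) {
    si <- if (is.null(genome)) NULL else .asSeqinfo(genome)
    gr <- .grFromHalfOpen(chrom, startBp, endBp, seqinfo = si)
    n <- length(gr)
    if (!all(orientation %in% c("forward", "reverse")))
        stop("'orientation' must be 'forward' or 'reverse'")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        scaffold = rep_len(scaffold, n), species = rep_len(species, n),
        sex = rep_len(sex, n), orientation = rep_len(orientation, n),
        identity = rep_len(identity, n))
    gr
}

## Balding-Nichols style drift: beta-distributed offspring frequency with
## mean p and drift parameter F in (0, 1). Fixed alleles stay fixed.
.driftFreq <- function(p, F) {
    out <- p
    seg <- p > 0 & p < 1
    if (any(seg)) {
        a <- p[seg] * (1 - F) / F
        b <- (1 - p[seg]) * (1 - F) / F
        out[seg] <- stats::rbeta(sum(seg), a, b)
    }
    out
}

#' Simulate four-population derived-allele frequencies
#'
#' Generates per-site derived-allele frequencies for populations P1, P2
#' (sister populations), P3 (donor) and O (outgroup) under a simple drift
#' model: an ancestral frequency drifts independently into two species
#' branches, P1 and P2 descend from one branch and P3 from the other, and a
#' fraction \code{gamma} of P2's sites instead draw their frequency from the
#' P3 branch (introgression). The outgroup is fixed ancestral at most sites.
#' Observed frequencies are binomial samples of \code{nHap} haplotypes.
#'
#' @param nSites Number of sites.
#' @param gamma Introgression fraction in [0, 1] (P3 into P2).
#' @param nHap Haplotypes sampled per population.
#' @param chrom Chromosome label for the sites.
#' @param posStepBp Spacing between consecutive site positions (bp).
#' @param driftSpecies,driftPop Drift parameters for the species split and
#'   the within-species population draws.
#' @param seed Integer seed.
#' @return A data.frame (site-frequency table) with columns \code{chrom},
#'   \code{pos_bp}, \code{p1}, \code{p2}, \code{p3}, \code{pO}, \code{n1},
#'   \code{n2}, \code{n3}, \code{nO}.
#' @examples
#' sft <- simulatePopgenSites(1000, gamma = 0.2, seed = 1)
#' head(sft)
#' @export
simulatePopgenSites <- function(nSites, gamma = 0, nHap = 8L,
                                chrom = "chr1", posStepBp = 100L,
                                driftSpecies = 0.15, driftPop = 0.05,
                                seed = NULL) {
    if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]")
    if (nSites < 1L) stop("'nSites' must be >= 1")
    if (nHap < 2L) stop("'nHap' must be >= 2")
    .setSeed(seed)
    pAnc <- stats::rbeta(nSites, 0.5, 0.5)
    pSpA <- .driftFreq(pAnc, driftSpecies)   # branch carrying P1 and P2
    pSpB <- .driftFreq(pAnc, driftSpecies)   # branch carrying P3
    p1 <- .driftFreq(pSpA, driftPop)
    p2 <- .driftFreq(pSpA, driftPop)
    p3 <- .driftFreq(pSpB, driftPop)
    intro <- stats::runif(nSites) < gamma
    if (any(intro)) p2[intro] <- .driftFreq(pSpB[intro], driftPop)
    pO <- ifelse(stats::runif(nSites) < 0.95, 0,
                 .driftFreq(pAnc, driftPop) * 0.2)
    obs <- function(p) stats::rbinom(nSites, nHap, p) / nHap
    data.frame(chrom = chrom,
               pos_bp = seq(0L, by = as.integer(posStepBp),
                            length.out = nSites),
               p1 = obs(p1), p2 = obs(p2), p3 = obs(p3), pO = obs(pO),
               n1 = nHap, n2 = nHap, n3 = nHap, nO = nHap)
}
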