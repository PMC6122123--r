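#' Tile a genome into sliding windows
#'
#' Emits windows of \code{sizeBp} starting every \code{stepBp} along each
#' chromosome: all full windows whose end fits inside the chromosome, plus
#' one final truncated window when the last full window does not reach the
#' chromosome end exactly. A chromosome no longer than one window yields a
#' single window. With the default 1 Mb / 100 kb layout the 21 published
#' chromosome lengths tile into exactly 2,549 windows.
#'
#' @param genome \linkS4class{Seqinfo} or named vector of lengths (bp).
#' @param sizeBp Window size (bp), default 1 Mb.
#' @param stepBp Step between window starts (bp), default 100 kb; must
#'   satisfy \code{0 < stepBp <= sizeBp}.
#'
#' @return A GRanges of windows (0-based half-open intervals stored 1-based
#'   closed) with a metadata column \code{index} (global window number).
#' @examples
#' length(tileWindows(hmelGenome()))  # 2549
#' @export
tileWindows <- function(genome, sizeBp = 1e6, stepBp = 1e5) {
    if (stepBp <= 0 || sizeBp <= 0 || stepBp > sizeBp)
        stop("need 0 < stepBp <= sizeBp")
    genome <- .asSeqinfo(genome)
    sl <- GenomeInfoDb::seqlengths(genome)
    chroms <- character(); ws <- numeric(); we <- numeric()
    for (ch in names(sl)) {
        L <- as.numeric(sl[[ch]])
        if (L <= sizeBp) {
            starts <- 0
            ends <- L
        } else {
            nFull <- floor((L - sizeBp) / stepBp) + 1
            starts <- (seq_len(nFull) - 1) * stepBp
            ends <- starts + sizeBp
            if (ends[nFull] < L) {          # trailing truncated window
                starts <- c(starts, nFull * stepBp)
                ends <- c(ends, L)
            }
        }
        chroms <- c(chroms, rep(ch, length(starts)))
        ws <- c(ws, starts); we <- c(we, ends)
    }
    gr <- .grFromHalfOpen(chroms, ws, we, seqinfo = genome)
    S4Vectors::mcols(gr)$index <- seq_along(gr)
    gr
}

## Offspring x window crossover-mass matrix. Row order follows
## 'offspringIds'; mass is pro-rated by overlap fraction of each
## crossover's localization interval.
.massMatrix <- function(crossovers, windows, offspringIds) {
    M <- matrix(0, nrow = length(offspringIds), ncol = length(windows),
                dimnames = list(offspringIds, NULL))
    if (!length(crossovers)) return(M)
    hits <- GenomicRanges::findOverlaps(crossovers, windows)
    if (!length(hits)) return(M)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- .overlapLen(.hoStart(crossovers)[qi], .hoEnd(crossovers)[qi],
                      .hoStart(windows)[si], .hoEnd(windows)[si])
    frac <- ov / (GenomicRanges::width(crossovers)[qi])
    rowIdx <- match(S4Vectors::mcols(crossovers)$offspring[qi],
                    offspringIds)
    if (anyNA(rowIdx))
        stop("crossover for an offspring not listed in 'offspringIds'")
    for (k in seq_along(qi))
        M[rowIdx[k], si[k]] <- M[rowIdx[k], si[k]] + frac[k]
    M
}

.offspringIdsFor <- function(crossovers, offspringIds, nOffspring) {
    if (!is.null(offspringIds)) return(as.character(offspringIds))
    seen <- unique(S4Vectors::mcols(crossovers)$offspring)
    if (length(seen) > nOffspring)
        stop("more offspring with crossovers than 'nOffspring'")
    c(seen, sprintf(".noxo%04d", seq_len(nOffspring - length(seen))))
}

#' Windowed recombination rates
#'
#' Computes per-window crossover mass, genetic length and recombination
#' rate. Each crossover contributes to a window the fraction of its
#' localization interval overlapping the window, so total mass over a
#' non-overlapping tiling equals the crossover count (no double counting
#' and no midpoint collapse). Window cM is 100 x mass / nOffspring and the
#' rate divides by the window's actual span in Mb (relevant for truncated
#' trailing windows).
#'
#' @param crossovers GRanges from \code{\link{detectCrossovers}}.
#' @param windows GRanges from \code{\link{tileWindows}}.
#' @param nOffspring Number of offspring.
#'
#' @return A data.frame: \code{index}, \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{mass}, \code{cM}, \code{rate_cM_Mb}.
#' @export
windowRates <- function(crossovers, windows, nOffspring) {
    nOffspring <- as.integer(nOffspring)
    if (is.na(nOffspring) || nOffspring < 1L)
        stop("'nOffspring' must be >= 1")
    xoChrom <- as.character(GenomeInfoDb::seqnames(crossovers))
    if (length(crossovers) &&
        !all(xoChrom %in% as.character(GenomeInfoDb::seqnames(windows))))
        stop("crossover on a chromosome with no windows")
    mass <- numeric(length(windows))
    if (length(crossovers)) {
        hits <- GenomicRanges::findOverlaps(crossovers, windows)
        qi <- S4Vectors::queryHits(hits)
        si <- S4Vectors::subjectHits(hits)
        ov <- .overlapLen(.hoStart(crossovers)[qi], .hoEnd(crossovers)[qi],
                          .hoStart(windows)[si], .hoEnd(windows)[si])
        frac <- ov / GenomicRanges::width(crossovers)[qi]
        agg <- tapply(frac, si, sum)
        mass[as.integer(names(agg))] <- agg
    }
    cm <- 100 * mass / nOffspring
    span <- GenomicRanges::width(windows) / 1e6
    data.frame(index = S4Vectors::mcols(windows)$index,
               chrom = as.character(GenomeInfoDb::seqnames(windows)),
               start_bp = .hoStart(windows), end_bp = .hoEnd(windows),
               mass = mass, cM = cm, rate_cM_Mb = cm / span)
}

#' Bootstrap confidence intervals for windowed rates
#'
#' Resamples offspring (not crossovers) with replacement, recomputes the
#' window genetic lengths for each replicate, and reports empirical
#' quantile confidence bounds per window, in both cM and cM/Mb.
#'
#' @param crossovers GRanges from \code{\link{detectCrossovers}}.
#' @param windows GRanges from \code{\link{tileWindows}}.
#' @param nOffspring Number of offspring.
#' @param nBoot Number of bootstrap replicates (default 1,000; the
#'   published analysis used 10,000).
#' @param level Confidence level (default 0.95: 2.5/97.5 percent
#'   quantiles).
#' @param offspringIds Optional ids of all offspring (so zero-crossover
#'   offspring are resampled too); inferred when omitted.
#' @param seed Integer seed.
#'
#' @return The \code{\link{windowRates}} data.frame with added columns
#'   \code{ci_low_cM}, \code{ci_high_cM}, \code{ci_low_rate},
#'   \code{ci_high_rate}.
#' @export
bootstrapCI <- function(crossovers, windows, nOffspring, nBoot = 1000L,
                        level = 0.95, offspringIds = NULL, seed = NULL) {
    if (nBoot < 1L) stop("'nBoot' must be >= 1")
    .setSeed(seed)
    base <- windowRates(crossovers, windows, nOffspring)
    ids <- .offspringIdsFor(crossovers, offspringIds, nOffspring)
    M <- .massMatrix(crossovers, windows, ids)
    n <- length(ids)
    qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    reps <- matrix(0, nrow = nBoot, ncol = ncol(M))
    for (b in seq_len(nBoot)) {
        w <- tabulate(sample.int(n, n, replace = TRUE), n)
        reps[b, ] <- 100 * as.numeric(w %*% M) / n
    }
    ci <- apply(reps, 2L, stats::quantile, probs = qs, names = FALSE)
    span <- GenomicRanges::width(windows) / 1e6
    base$ci_low_cM <- ci[1L, ]
    base$ci_high_cM <- ci[2L, ]
    base$ci_low_rate <- ci[1L, ] / span
    base$ci_high_rate <- ci[2L, ] / span
    base
}
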