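#' Detect crossovers from ordered paternal-phase genotypes
#'
#' Scans each offspring's ordered phase calls along each chromosome and
#' calls a crossover at every phase switch corroborated by at least
#' \code{minSupport} consecutive informative markers of the new phase.
#' Shorter runs are treated as genotyping error and do not change the
#' current phase; missing calls (\code{"N"}) are skipped, so a crossover
#' interval can extend across them. Each crossover is localized to the
#' half-open physical interval between the last informative marker of the
#' old phase and the first informative marker of the new phase.
#'
#' With \code{minSupport = 1} every phase switch is called, which recovers
#' simulated truth exactly on error-free data; the default
#' \code{minSupport = 2} suppresses single-marker flips, the dominant error
#' mode.
#'
#' @param x A \linkS4class{CrossDataset}, or a list with elements
#'   \code{markers} (data.frame \code{chrom}, \code{pos_bp}),
#'   \code{genotypes} (markers x offspring character matrix) and
#'   \code{offspring} (data.frame with \code{id}, \code{group}).
#' @param minSupport Minimum consecutive markers corroborating a new phase
#'   (>= 1).
#'
#' @return A GRanges of crossover localization intervals (half-open
#'   \code{[left_bp, right_bp)} stored 1-based closed, so \code{width()} is
#'   the physical interval length) with metadata columns \code{offspring}
#'   and \code{group}.
#' @examples
#' cd <- simulateCross(crossConfig(nOffspring = 20, seed = 1),
#'                     genome = c(chr1 = 5e6))
#' detectCrossovers(cd)
#' @export
detectCrossovers <- function(x, minSupport = 2L) {
    if (minSupport < 1L) stop("'minSupport' must be >= 1")
    if (methods::is(x, "CrossDataset")) {
        chrom <- as.character(GenomeInfoDb::seqnames(markers(x)))
        pos <- GenomicRanges::start(markers(x))
        geno <- genotypeMatrix(x)
        off <- as.data.frame(offspringInfo(x))
        si <- GenomeInfoDb::seqinfo(x)
    } else {
        chrom <- as.character(x$markers$chrom)
        pos <- as.integer(x$markers$pos_bp)
        geno <- x$genotypes
        off <- as.data.frame(x$offspring)
        si <- NULL
    }
    ord <- order(match(chrom, unique(chrom)), pos)
    if (any(diff(ord) != 1L)) stop("markers must be ordered by position")
    for (ch in unique(chrom)) {
        p <- pos[chrom == ch]
        if (anyDuplicated(p) || is.unsorted(p, strictly = TRUE))
            stop("marker positions must be strictly increasing within ",
                 "chromosome '", ch, "'")
    }

    res <- list()
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        p <- pos[idx]
        for (j in seq_len(ncol(geno))) {
            calls <- geno[idx, j]
            inf <- calls != "N"
            if (sum(inf) < 2L) next
            ph <- calls[inf]
            pp <- p[inf]
            r <- rle(ph)
            nr <- length(r$lengths)
            if (nr < 2L) next
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            cur <- r$values[1L]
            lastIdxOfCur <- ends[1L]
            for (k in 2L:nr) {
                if (r$values[k] != cur && r$lengths[k] >= minSupport) {
                    res[[length(res) + 1L]] <- list(
                        chrom = ch,
                        left = pp[lastIdxOfCur],
                        right = pp[starts[k]],
                        offspring = off$id[j],
                        group = off$group[j])
                    cur <- r$values[k]
                    lastIdxOfCur <- ends[k]
                } else if (r$values[k] == cur) {
                    lastIdxOfCur <- ends[k]
                }
                ## runs of the other phase shorter than minSupport are
                ## ignored as genotyping error
            }
        }
    }
    if (!length(res)) {
        gr <- if (is.null(si)) GenomicRanges::GRanges() else
            GenomicRanges::GRanges(seqinfo = si)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            offspring = character(0), group = character(0))
        return(gr)
    }
    d <- do.call(rbind, lapply(res, as.data.frame))
    gr <- .grFromHalfOpen(d$chrom, d$left, d$right, seqinfo = si)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        offspring = as.character(d$offspring),
        group = as.character(d$group))
    sort(gr)
}

## Pro-rate crossover mass over bins on one chromosome. Each crossover
## contributes to a bin the fraction of its localization interval that the
## bin overlaps, so mass sums to exactly 1 per crossover over any
## non-overlapping tiling that covers it.
.proRateMass <- function(xoS, xoE, binS, binE) {
    mass <- numeric(length(binS))
    if (!length(xoS)) return(mass)
    for (i in seq_along(xoS)) {
        ov <- .overlapLen(xoS[i], xoE[i], binS, binE)
        mass <- mass + ov / (xoE[i] - xoS[i])
    }
    mass
}

#' Estimate a genetic map from crossover intervals
#'
#' Assigns centiMorgan positions to markers from the recombination fraction
#' alone: the cM increment between adjacent markers is 100 times the number
#' of offspring with a crossover localized to that interval divided by the
#' number of offspring; no mapping function is applied. A crossover whose
#' localization interval spans several marker intervals (because of missing
#' calls) is pro-rated across them by physical overlap, so the total map
#' length is exactly 100 times the mean crossovers per offspring.
#'
#' @param crossovers GRanges from \code{\link{detectCrossovers}}.
#' @param markers Marker positions: a width-1 GRanges, or a data.frame with
#'   \code{chrom}, \code{pos_bp}.
#' @param nOffspring Number of offspring the crossovers came from (>= 1).
#'
#' @return A \linkS4class{GeneticMap}.
#' @examples
#' cd <- simulateCross(crossConfig(nOffspring = 100, seed = 1),
#'                     genome = c(chr1 = 5e6))
#' xo <- detectCrossovers(cd, minSupport = 1)
#' estimateMap(xo, markers(cd), nOffspring = 100)
#' @export
estimateMap <- function(crossovers, markers, nOffspring) {
    nOffspring <- as.integer(nOffspring)
    if (is.na(nOffspring) || nOffspring < 1L)
        stop("'nOffspring' must be >= 1")
    if (methods::is(markers, "GRanges")) {
        mchrom <- as.character(GenomeInfoDb::seqnames(markers))
        mpos <- GenomicRanges::start(markers)
        si <- GenomeInfoDb::seqinfo(markers)
    } else {
        mchrom <- as.character(markers$chrom)
        mpos <- as.integer(markers$pos_bp)
        si <- NULL
    }
    xchrom <- as.character(GenomeInfoDb::seqnames(crossovers))
    xS <- .hoStart(crossovers)
    xE <- .hoEnd(crossovers)

    outChrom <- character(); outPos <- integer(); outCM <- numeric()
    for (ch in unique(mchrom)) {
        p <- sort(mpos[mchrom == ch])
        sel <- xchrom == ch
        if (any(sel)) {
            if (!all(xS[sel] %in% p) || !all(xE[sel] %in% p))
                stop("crossover interval endpoints must be marker ",
                     "positions on chromosome '", ch, "'")
        }
        if (length(p) >= 2L) {
            binS <- utils::head(p, -1L)
            binE <- utils::tail(p, -1L)
            mass <- .proRateMass(xS[sel], xE[sel], binS, binE)
            cm <- c(0, cumsum(100 * mass / nOffspring))
        } else {
            cm <- rep(0, length(p))
        }
        outChrom <- c(outChrom, rep(ch, length(p)))
        outPos <- c(outPos, p)
        outCM <- c(outCM, cm)
    }
    gr <- GenomicRanges::GRanges(outChrom,
        IRanges::IRanges(start = outPos, width = 1L))
    if (!is.null(si))
        suppressWarnings(GenomeInfoDb::seqinfo(gr) <- si[
            GenomeInfoDb::seqlevels(gr)])
    S4Vectors::mcols(gr)$cM <- outCM
    methods::new("GeneticMap", markers = gr, nOffspring = nOffspring)
}

#' Per-chromosome map summary statistics
#'
#' Total genetic length, broad-scale recombination rate (cM/Mb, reported to
#' two decimals) and inter-marker gap summaries for a genetic map. Rates
#' use the physical chromosome lengths where known (from the map's seqinfo
#' or \code{chromLengthBp}), falling back to the marker span.
#'
#' @param map A \linkS4class{GeneticMap}.
#' @param chromLengthBp Optional named vector of chromosome lengths (bp).
#'
#' @return A data.frame with one row per chromosome plus a \code{"genome"}
#'   total row: \code{chrom}, \code{n_markers}, \code{length_bp},
#'   \code{total_cM}, \code{rate_cM_Mb}, \code{gap_mean_bp},
#'   \code{gap_median_bp}, \code{gap_max_bp}.
#' @export
mapStatistics <- function(map, chromLengthBp = NULL) {
    m <- markers(map)
    if (!length(m)) stop("empty map")
    chrom <- as.character(GenomeInfoDb::seqnames(m))
    pos <- GenomicRanges::start(m)
    cm <- S4Vectors::mcols(m)$cM
    sl <- GenomeInfoDb::seqlengths(m)
    rows <- lapply(unique(chrom), function(ch) {
        sel <- chrom == ch
        p <- pos[sel]
        L <- if (!is.null(chromLengthBp) && ch %in% names(chromLengthBp))
            as.numeric(chromLengthBp[ch])
        else if (ch %in% names(sl) && !is.na(sl[ch])) as.numeric(sl[ch])
        else max(p)
        gaps <- diff(sort(p))
        tot <- max(cm[sel]) - min(cm[sel])
        data.frame(chrom = ch, n_markers = sum(sel), length_bp = L,
                   total_cM = tot,
                   rate_cM_Mb = round(tot / (L / 1e6), 2),
                   gap_mean_bp = if (length(gaps)) mean(gaps) else NA_real_,
                   gap_median_bp = if (length(gaps))
                       stats::median(gaps) else NA_real_,
                   gap_max_bp = if (length(gaps)) max(gaps) else NA_real_)
    })
    out <- do.call(rbind, rows)
    gtot <- sum(out$total_cM); gL <- sum(out$length_bp)
    gaps <- unlist(lapply(unique(chrom), function(ch)
        diff(sort(pos[chrom == ch]))))
    rbind(out, data.frame(chrom = "genome", n_markers = length(m),
                          length_bp = gL, total_cM = gtot,
                          rate_cM_Mb = round(gtot / (gL / 1e6), 2),
                          gap_mean_bp = if (length(gaps)) mean(gaps)
                                        else NA_real_,
                          gap_median_bp = if (length(gaps))
                              stats::median(gaps) else NA_real_,
                          gap_max_bp = if (length(gaps)) max(gaps)
                                       else NA_real_))
}

#' Mean crossovers per offspring
#'
#' Mean and standard deviation of the per-offspring crossover count. By
#' construction the mean equals the total map length in Morgans
#' (total cM / 100). Offspring with no crossovers contribute zeros; supply
#' \code{offspringIds} (or rely on \code{nOffspring} minus the observed
#' ids) so they are counted.
#'
#' @param crossovers GRanges from \code{\link{detectCrossovers}}.
#' @param nOffspring Total number of offspring.
#' @param offspringIds Optional character vector of all offspring ids.
#'
#' @return A list with \code{mean} and \code{sd} (crossovers/offspring).
#' @export
meanCrossoversPerOffspring <- function(crossovers, nOffspring,
                                       offspringIds = NULL) {
    nOffspring <- as.integer(nOffspring)
    if (is.na(nOffspring) || nOffspring < 1L)
        stop("'nOffspring' must be >= 1")
    ids <- S4Vectors::mcols(crossovers)$offspring
    if (!is.null(offspringIds)) {
        counts <- as.numeric(table(factor(ids, levels = offspringIds)))
        if (length(offspringIds) != nOffspring)
            stop("'offspringIds' length must equal 'nOffspring'")
    } else {
        counts <- as.numeric(table(ids))
        nZero <- nOffspring - length(counts)
        if (nZero < 0)
            stop("more offspring with crossovers than 'nOffspring'")
        counts <- c(counts, rep(0, nZero))
    }
    list(mean = sum(counts) / nOffspring,
         sd = if (nOffspring > 1L) stats::sd(counts) else 0)
}
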