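## Validate a site-frequency table and optionally restrict to a window
## (half-open [startBp, endBp) on one chromosome).
.sftCheck <- function(sft, window = NULL) {
    need <- c("chrom", "pos_bp", "p1", "p2", "p3", "pO",
              "n1", "n2", "n3", "nO")
    if (!all(need %in% names(sft)))
        stop("site-frequency table needs columns: ",
             paste(need, collapse = ", "))
    for (p in c("p1", "p2", "p3", "pO"))
        if (any(sft[[p]] < 0 | sft[[p]] > 1, na.rm = TRUE))
            stop("frequencies must lie in [0, 1]")
    if (!is.null(window)) {
        sft <- sft[sft$chrom == window$chrom &
                   sft$pos_bp >= window$start_bp &
                   sft$pos_bp < window$end_bp, , drop = FALSE]
    }
    sft
}

.asWindow <- function(window) {
    if (is.null(window)) return(NULL)
    if (methods::is(window, "GRanges")) {
        stopifnot(length(window) == 1L)
        return(list(chrom = as.character(GenomeInfoDb::seqnames(window)),
                    start_bp = .hoStart(window), end_bp = .hoEnd(window)))
    }
    as.list(window[c("chrom", "start_bp", "end_bp")])
}

#' Lay out equal-sized windows around a candidate interval
#'
#' Builds up to 11 contiguous windows, each the size of the candidate: the
#' candidate itself (index 0), up to five upstream (-5..-1) and up to five
#' downstream (1..5). Windows that would extend beyond either chromosome
#' end are dropped, not truncated, so all windows stay comparable in size.
#'
#' @param chrom Chromosome of the candidate.
#' @param startBp,endBp Candidate interval (bp, 0-based half-open).
#' @param chromLengthBp Length of the chromosome (bp).
#' @param nFlank Flanking windows per side (default 5).
#'
#' @return A data.frame: \code{chrom}, \code{start_bp}, \code{end_bp},
#'   \code{window_index}.
#' @examples
#' layoutFlankingWindows("chr1", 5e6, 5.01e6, 1e7)   # 11 windows
#' layoutFlankingWindows("chr1", 2e4, 3e4, 1e7)      # 8 windows
#' @export
layoutFlankingWindows <- function(chrom, startBp, endBp, chromLengthBp,
                                  nFlank = 5L) {
    if (startBp < 0 || endBp <= startBp || endBp > chromLengthBp)
        stop("candidate outside chromosome")
    L <- endBp - startBp
    idx <- seq.int(-nFlank, nFlank)
    ws <- startBp + idx * L
    we <- ws + L
    keep <- ws >= 0 & we <= chromLengthBp
    data.frame(chrom = chrom, start_bp = ws[keep], end_bp = we[keep],
               window_index = idx[keep])
}

#' Per-site Hudson FST components
#'
#' Numerator and denominator of the Hudson-type FST estimator with
#' sample-size correction, per site: numerator
#' (p_a - p_b)^2 - p_a(1-p_a)/(n_a - 1) - p_b(1-p_b)/(n_b - 1),
#' denominator p_a(1-p_b) + p_b(1-p_a). Window FST is the ratio of sums
#' (ratio of averages), the standard combination across sites.
#'
#' @param pA,pB Allele frequencies in the two populations.
#' @param nA,nB Haplotype sample sizes (must be >= 2).
#' @return A list with vectors \code{num} and \code{den}.
#' @export
fstComponents <- function(pA, pB, nA, nB) {
    if (any(nA < 2) || any(nB < 2))
        stop("sample sizes must be >= 2 for the variance correction")
    num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) -
        pB * (1 - pB) / (nB - 1)
    den <- pA * (1 - pB) + pB * (1 - pA)
    list(num = num, den = den)
}

#' Window FST between two populations
#'
#' @param sft Site-frequency table (see
#'   \code{\link{simulatePopgenSites}}).
#' @param window Optional window (GRanges of length 1 or a list/row with
#'   \code{chrom}, \code{start_bp}, \code{end_bp}); all sites when NULL.
#' @param popA,popB Column prefixes of the two populations (default
#'   \code{"p1"} vs \code{"p2"}).
#' @return Window FST (ratio of summed components), or \code{NA} when no
#'   site varies.
#' @examples
#' sft <- simulatePopgenSites(500, seed = 1)
#' fstWindow(sft)
#' @export
fstWindow <- function(sft, window = NULL, popA = "p1", popB = "p2") {
    sft <- .sftCheck(sft, .asWindow(window))
    if (!nrow(sft)) return(NA_real_)
    nA <- sft[[sub("^p", "n", popA)]]
    nB <- sft[[sub("^p", "n", popB)]]
    comp <- fstComponents(sft[[popA]], sft[[popB]], nA, nB)
    den <- sum(comp$den)
    if (den == 0) return(NA_real_)
    sum(comp$num) / den
}

#' Window dXY between two populations
#'
#' Mean per-site raw divergence d = p_a(1-p_b) + p_b(1-p_a). When the
#' table holds variant sites only, pass the total number of sites in the
#' window (monomorphic included) as \code{nTotalSites} for proper per-site
#' scaling; otherwise the value is scaled over the variant sites present
#' and flagged \code{"variant-scaled"} in the \code{scaling} attribute.
#'
#' @inheritParams fstWindow
#' @param nTotalSites Optional total site count in the window.
#' @return Window dXY (substitutions/site) with a \code{scaling}
#'   attribute, or \code{NA} for an empty window.
#' @export
dxyWindow <- function(sft, window = NULL, popA = "p1", popB = "p2",
                      nTotalSites = NULL) {
    sft <- .sftCheck(sft, .asWindow(window))
    if (!nrow(sft)) return(NA_real_)
    d <- sft[[popA]] * (1 - sft[[popB]]) + sft[[popB]] * (1 - sft[[popA]])
    if (!is.null(nTotalSites)) {
        if (nTotalSites < nrow(sft))
            stop("'nTotalSites' smaller than number of variant sites")
        out <- sum(d) / nTotalSites
        attr(out, "scaling") <- "all-sites"
    } else {
        out <- mean(d)
        attr(out, "scaling") <- "variant-scaled"
    }
    out
}

#' Window D statistic and fd admixture fraction
#'
#' ABBA-BABA statistics from population allele frequencies: per site,
#' ABBA = (1-p1) p2 p3 (1-pO) and BABA = p1 (1-p2) p3 (1-pO). D is the
#' normalized difference of sums. The fd estimator rescales the
#' ABBA-BABA excess by a hypothetical maximal donor: the denominator
#' replaces both p2 and p3 by pD = max(p2, p3) site-wise. fd estimates
#' the local admixture proportion and is reported only where D >= 0; for
#' D < 0 windows it is returned as \code{NA} (undefined, never clamped).
#'
#' @inheritParams fstWindow
#' @return A list: \code{abba}, \code{baba} (sums), \code{d}, \code{fd},
#'   \code{fd_denominator} (the maximal-donor denominator, useful for
#'   sign-preserving null checks), \code{n_sites}.
#' @examples
#' sft <- data.frame(chrom = "c", pos_bp = 0, p1 = 0, p2 = 0.6,
#'                   p3 = 0.6, pO = 0, n1 = 8, n2 = 8, n3 = 8, nO = 8)
#' fdWindow(sft)$fd   # 1: p2 == p3 forces the maximal-donor bound
#' @export
fdWindow <- function(sft, window = NULL) {
    sft <- .sftCheck(sft, .asWindow(window))
    if (!nrow(sft))
        return(list(abba = NA_real_, baba = NA_real_, d = NA_real_,
                    fd = NA_real_, fd_denominator = NA_real_,
                    n_sites = 0L))
    p1 <- sft$p1; p2 <- sft$p2; p3 <- sft$p3; pO <- sft$pO
    abba <- (1 - p1) * p2 * p3 * (1 - pO)
    baba <- p1 * (1 - p2) * p3 * (1 - pO)
    sA <- sum(abba); sB <- sum(baba)
    d <- if (sA + sB == 0) 0 else (sA - sB) / (sA + sB)
    pD <- pmax(p2, p3)
    abbaD <- (1 - p1) * pD * pD * (1 - pO)
    babaD <- p1 * (1 - pD) * pD * (1 - pO)
    den <- sum(abbaD) - sum(babaD)
    fd <- if (d < 0 || den == 0) NA_real_ else (sA - sB) / den
    list(abba = sA, baba = sB, d = d, fd = fd, fd_denominator = den,
         n_sites = nrow(sft))
}

#' Introgression statistics around candidate inversions
#'
#' For each candidate interval, lays out equal-sized flanking windows
#' (\code{\link{layoutFlankingWindows}}) and computes FST (P1 vs P2), dXY,
#' D and fd per window.
#'
#' @param sft Site-frequency table.
#' @param candidates GRanges of candidate intervals.
#' @param chromLengthBp Named vector of chromosome lengths (bp); taken
#'   from the candidates' seqinfo when omitted.
#' @param nFlank Flanking windows per side (default 5).
#'
#' @return A data.frame with one row per candidate x window:
#'   \code{candidate}, \code{chrom}, \code{start_bp}, \code{end_bp},
#'   \code{window_index}, \code{fst}, \code{dxy}, \code{d}, \code{fd},
#'   \code{n_sites}.
#' @export
popgenCandidateStats <- function(sft, candidates, chromLengthBp = NULL,
                                 nFlank = 5L) {
    if (is.null(chromLengthBp)) {
        chromLengthBp <- GenomeInfoDb::seqlengths(candidates)
        if (any(is.na(chromLengthBp)))
            stop("supply 'chromLengthBp' or candidates with seqlengths")
    }
    out <- list()
    for (i in seq_along(candidates)) {
        ch <- as.character(GenomeInfoDb::seqnames(candidates))[i]
        wins <- layoutFlankingWindows(ch, .hoStart(candidates)[i],
                                      .hoEnd(candidates)[i],
                                      chromLengthBp[[ch]], nFlank)
        for (k in seq_len(nrow(wins))) {
            w <- wins[k, ]
            fdres <- fdWindow(sft, w)
            out[[length(out) + 1L]] <- data.frame(
                candidate = i, chrom = ch,
                start_bp = w$start_bp, end_bp = w$end_bp,
                window_index = w$window_index,
                fst = fstWindow(sft, w),
                dxy = as.numeric(dxyWindow(sft, w)),
                d = fdres$d, fd = fdres$fd, n_sites = fdres$n_sites)
        }
    }
    do.call(rbind, out)
}
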