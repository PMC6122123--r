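## One-sided KS statistic D+ = max_x [ECDF_b(x) - ECDF_a(x)], testing
## whether sample b is stochastically smaller than sample a. Fast integer
## path via tabulate when both samples are small non-negative integers.
.ksDplus <- function(a, b) {
    if (is.integer(a) && is.integer(b) && min(a, b) >= 0L) {
        K <- max(a, b) + 1L
        Fa <- cumsum(tabulate(a + 1L, K)) / length(a)
        Fb <- cumsum(tabulate(b + 1L, K)) / length(b)
        return(max(Fb - Fa))
    }
    xs <- sort(unique(c(a, b)))
    Fa <- findInterval(xs, sort(a)) / length(a)
    Fb <- findInterval(xs, sort(b)) / length(b)
    max(Fb - Fa)
}

#' Bootstrapped one-tailed Kolmogorov-Smirnov test
#'
#' Tests whether per-offspring crossover counts in group b are
#' stochastically smaller than in group a (reduced recombination), using
#' the one-sided statistic D+ = max over x of ECDF_b(x) - ECDF_a(x) and a
#' bootstrap null suitable for discrete data with ties: both samples are
#' redrawn with replacement from the pooled sample at their original sizes,
#' and the p-value is the proportion of replicates with a statistic at
#' least as large as observed, with a +1 continuity correction so p is
#' never exactly zero.
#'
#' @param countsA Non-negative integer crossover counts, reference group.
#' @param countsB Non-negative integer crossover counts, group tested for
#'   reduction.
#' @param nBoot Bootstrap replicates (default 10,000, as published).
#' @param seed Integer seed.
#'
#' @return An object of class \code{"htest"} with \code{statistic} (D+)
#'   and \code{p.value}.
#' @examples
#' a <- rbinom(300, 2, 0.5)
#' ksBootOneTailed(a, pmax(a - 1L, 0L), nBoot = 500, seed = 1)
#' @export
ksBootOneTailed <- function(countsA, countsB, nBoot = 10000L, seed = NULL) {
    if (!length(countsA) || !length(countsB))
        stop("both samples must be non-empty")
    if (any(countsA < 0) || any(countsB < 0) ||
        any(countsA != round(countsA)) || any(countsB != round(countsB)))
        stop("counts must be non-negative integers")
    if (nBoot < 1L) stop("'nBoot' must be >= 1")
    .setSeed(seed)
    a <- as.integer(countsA); b <- as.integer(countsB)
    na <- length(a); nb <- length(b)
    obs <- .ksDplus(a, b)
    pool <- c(a, b)
    hits <- 0L
    for (i in seq_len(nBoot)) {
        idx <- sample.int(na + nb, na + nb, replace = TRUE)
        if (.ksDplus(pool[idx[seq_len(na)]],
                     pool[idx[(na + 1L):(na + nb)]]) >= obs)
            hits <- hits + 1L
    }
    p <- (1 + hits) / (nBoot + 1)
    structure(list(statistic = c(`D+` = obs), p.value = p,
                   alternative = "group b stochastically smaller",
                   method = paste("Bootstrapped one-tailed KS test",
                                  sprintf("(%d bootstrap samples)", nBoot)),
                   data.name = paste(deparse(substitute(countsA)), "vs",
                                     deparse(substitute(countsB)))),
              class = "htest")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up FDR adjustment with significance flags at the given
#' level.
#'
#' @param pValues Vector of p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return A data.frame with \code{p}, \code{q} (BH-adjusted) and
#'   \code{significant} (\code{q <= alpha}).
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.5))
#' @export
bhFdr <- function(pValues, alpha = 0.05) {
    if (any(is.na(pValues)) || any(pValues < 0 | pValues > 1))
        stop("p-values must lie in [0, 1]")
    q <- stats::p.adjust(pValues, method = "BH")
    data.frame(p = pValues, q = q, significant = q <= alpha)
}

#' Window-scale permutation test for rate differences
#'
#' Compares windowed recombination between two groups by permuting group
#' labels across offspring: each offspring carries all of its crossovers,
#' labels are reshuffled globally, and the per-window statistic is the
#' difference in window genetic length (cM, group a minus group b). The
#' per-window p-value is (1 + number of permutations as or more extreme) /
#' (nPerm + 1), two-sided by default or one-sided (\code{tail = "less"},
#' testing for reduction in group b). Benjamini-Hochberg q-values are
#' computed across all windows.
#'
#' @param crossovers GRanges with \code{offspring} metadata, both groups
#'   pooled.
#' @param windows GRanges from \code{\link{tileWindows}}.
#' @param groups Named character vector mapping every offspring id (with or
#'   without crossovers) to one of exactly two group labels.
#' @param nPerm Number of permutations (default 2,000 for desk-scale runs;
#'   the published analysis used 270,000).
#' @param reference Group label to use as group a (the minuend of the
#'   statistic); defaults to the alphabetically first label.
#' @param tail \code{"two_sided"} or \code{"less"} (one-sided: is the
#'   non-reference group reduced relative to the reference?).
#' @param alpha FDR level for the significance flags.
#' @param seed Integer seed.
#'
#' @return A data.frame per window: \code{index}, \code{chrom},
#'   \code{start_bp}, \code{end_bp}, \code{comparison},
#'   \code{statistic_cM}, \code{p}, \code{q}, \code{significant}.
#' @export
permutationWindowTest <- function(crossovers, windows, groups,
                                  nPerm = 2000L, reference = NULL,
                                  tail = c("two_sided", "less"),
                                  alpha = 0.05, seed = NULL) {
    tail <- match.arg(tail)
    if (nPerm < 1L) stop("'nPerm' must be >= 1")
    lv <- sort(unique(groups))
    if (length(lv) != 2L) stop("exactly two groups are required")
    if (!is.null(reference)) {
        if (!reference %in% lv) stop("'reference' is not a group label")
        lv <- c(reference, setdiff(lv, reference))
    }
    .setSeed(seed)
    ids <- names(groups)
    M <- .massMatrix(crossovers, windows, ids)
    n <- length(ids)
    isA <- groups == lv[1L]
    nA <- sum(isA); nB <- n - nA
    cmOf <- function(sel) 100 * as.numeric(
        colSums(M[sel, , drop = FALSE])) / sum(sel)
    tot <- colSums(M)
    obs <- cmOf(isA) - cmOf(!isA)

    extreme <- integer(ncol(M))
    for (i in seq_len(nPerm)) {
        permA <- sample.int(n, nA)
        tA <- colSums(M[permA, , drop = FALSE])
        stat <- 100 * (tA / nA - (tot - tA) / nB)
        extreme <- extreme + if (tail == "two_sided")
            (abs(stat) >= abs(obs)) else (stat >= obs)
    }
    ## tail "less": small observed diff (b reduced => obs large positive?)
    ## statistic is a - b, so reduction in b gives large positive obs; the
    ## one-sided test counts permutations with stat >= obs.
    p <- (1 + extreme) / (nPerm + 1)
    fdr <- bhFdr(p, alpha)
    data.frame(index = S4Vectors::mcols(windows)$index,
               chrom = as.character(GenomeInfoDb::seqnames(windows)),
               start_bp = .hoStart(windows), end_bp = .hoEnd(windows),
               comparison = paste(lv[1L], "vs", lv[2L]),
               statistic_cM = obs, p = p, q = fdr$q,
               significant = fdr$significant)
}
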