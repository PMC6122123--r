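#' Would a linkage map detect an inversion at this interval?
#'
#' A flipped segment is visible in a Marey map only if the flip would
#' reorder the map. Under the default criterion \code{"two_informative"}
#' the interval must contain at least two markers at distinct genetic (cM)
#' positions; markers at identical cM are unordered by the map, so
#' reversing them changes nothing. The looser \code{"two_markers"}
#' criterion requires only two markers regardless of cM.
#'
#' @param map A \linkS4class{GeneticMap}.
#' @param chrom Chromosome of the interval.
#' @param startBp,endBp Interval bounds (bp, 0-based half-open).
#' @param criterion \code{"two_informative"} (default) or
#'   \code{"two_markers"}.
#'
#' @return \code{TRUE} if the inversion would be detectable from the map.
#' @export
isDetectable <- function(map, chrom, startBp, endBp,
                         criterion = c("two_informative", "two_markers")) {
    criterion <- match.arg(criterion)
    if (startBp < 0 || endBp <= startBp)
        stop("need 0 <= startBp < endBp")
    m <- markers(map)
    sl <- GenomeInfoDb::seqlengths(m)
    if (chrom %in% names(sl) && !is.na(sl[chrom]) && endBp > sl[chrom])
        stop("interval outside chromosome")
    onc <- as.character(GenomeInfoDb::seqnames(m)) == chrom
    pos <- GenomicRanges::start(m)[onc]
    cm <- S4Vectors::mcols(m)$cM[onc]
    inside <- pos >= startBp & pos < endBp
    if (sum(inside) < 2L) return(FALSE)
    if (criterion == "two_markers") return(TRUE)
    length(unique(cm[inside])) >= 2L
}

#' Power to detect random inversions of given sizes
#'
#' For each size, places \code{nSim} inversions uniformly at random across
#' the genome (chromosome chosen proportional to its length, start uniform;
#' placements that would cross a chromosome end are redrawn) and reports
#' the fraction detectable from the map under the chosen criterion.
#'
#' @param map A \linkS4class{GeneticMap} whose markers carry seqlengths
#'   (or supply \code{chromLengthBp}).
#' @param sizesBp Inversion sizes to assess (bp).
#' @param nSim Placements per size.
#' @param criterion See \code{\link{isDetectable}}.
#' @param chromLengthBp Optional named vector of chromosome lengths.
#' @param seed Integer seed.
#'
#' @return A data.frame: \code{size_bp}, \code{power}, \code{n_sim},
#'   \code{criterion}.
#' @examples
#' cd <- simulateCross(crossConfig(nOffspring = 100, seed = 1),
#'                     genome = c(chr1 = 1e7))
#' map <- estimateMap(detectCrossovers(cd), markers(cd), 100)
#' powerCurve(map, c(1e5, 5e5), nSim = 200, seed = 1)
#' @export
powerCurve <- function(map, sizesBp, nSim = 1000L,
                       criterion = c("two_informative", "two_markers"),
                       chromLengthBp = NULL, seed = NULL) {
    criterion <- match.arg(criterion)
    if (any(sizesBp <= 0)) stop("sizes must be positive")
    if (nSim < 1L) stop("'nSim' must be >= 1")
    m <- markers(map)
    sl <- GenomeInfoDb::seqlengths(m)
    if (!is.null(chromLengthBp)) sl <- chromLengthBp
    sl <- sl[!is.na(sl)]
    if (!length(sl)) stop("no chromosome lengths available")
    .setSeed(seed)

    ## cache marker positions / cM per chromosome once
    chrOf <- as.character(GenomeInfoDb::seqnames(m))
    cmAll <- S4Vectors::mcols(m)$cM
    if (is.null(cmAll)) cmAll <- numeric(length(m))
    posBy <- split(GenomicRanges::start(m), chrOf)
    cmBy <- split(cmAll, chrOf)

    rows <- lapply(sizesBp, function(sz) {
        if (all(sl < sz))
            stop("inversion size exceeds every chromosome length")
        hit <- 0L
        for (i in seq_len(nSim)) {
            repeat {      # redraw placements crossing a chromosome end
                ch <- sample(names(sl), 1L, prob = as.numeric(sl))
                if (sl[[ch]] >= sz) break
            }
            s <- floor(stats::runif(1, 0, as.numeric(sl[[ch]]) - sz + 1))
            pos <- posBy[[ch]]
            if (is.null(pos)) next
            inside <- pos >= s & pos < s + sz
            det <- if (sum(inside) < 2L) FALSE
                   else if (criterion == "two_markers") TRUE
                   else length(unique(cmBy[[ch]][inside])) >= 2L
            if (det) hit <- hit + 1L
        }
        data.frame(size_bp = sz, power = hit / nSim, n_sim = nSim,
                   criterion = criterion)
    })
    do.call(rbind, rows)
}
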