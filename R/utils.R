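# Internal helpers shared across modules.
#
# Coordinate convention: all on-disk tables and user-facing bp arguments are
# 0-based half-open [start_bp, end_bp). GRanges objects are 1-based closed,
# so a half-open interval maps to start = start_bp + 1, end = end_bp; width()
# then equals the physical length end_bp - start_bp exactly.

.grFromHalfOpen <- function(chrom, startBp, endBp, seqinfo = NULL, ...) {
    if (any(startBp < 0) || any(endBp <= startBp))
        stop("intervals must satisfy 0 <= start_bp < end_bp")
    if (is.null(seqinfo)) {
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = startBp + 1L, end = endBp), ...)
    } else {
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(start = startBp + 1L, end = endBp),
            seqinfo = seqinfo, ...)
    }
}

.hoStart <- function(gr) GenomicRanges::start(gr) - 1L
.hoEnd <- function(gr) GenomicRanges::end(gr)

## Overlap length of half-open [s1,e1) and [s2,e2), vectorised.
.overlapLen <- function(s1, e1, s2, e2) {
    pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

.setSeed <- function(seed) {
    if (!is.null(seed)) {
        if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
            stop("'seed' must be a single integer")
        set.seed(as.integer(seed))
    }
    invisible(NULL)
}

## Coerce a genome given as Seqinfo or named integer vector to Seqinfo.
.asSeqinfo <- function(genome) {
    if (methods::is(genome, "Seqinfo")) return(genome)
    if (is.numeric(genome) && !is.null(names(genome))) {
        if (any(genome <= 0)) stop("chromosome lengths must be positive")
        if (anyDuplicated(names(genome)))
            stop("chromosome names must be unique")
        return(GenomeInfoDb::Seqinfo(seqnames = names(genome),
                                     seqlengths = as.integer(genome)))
    }
    stop("'genome' must be a Seqinfo object or a named vector of lengths")
}

.seqlen <- function(genome, chrom) {
    sl <- GenomeInfoDb::seqlengths(genome)
    if (!chrom %in% names(sl)) stop("unknown chromosome: ", chrom)
    unname(sl[chrom])
}
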