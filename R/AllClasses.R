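#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

#' CrossDataset: a simulated or loaded mapping cross
#'
#' Container for one mapping-cross dataset: ordered markers, per-offspring
#' paternal-phase genotype calls, the offspring table and (for simulated
#' data) the ground-truth crossover positions. Because female Lepidoptera
#' meiosis is achiasmatic, all crossovers are paternal; the genotype matrix
#' holds the paternal phase call at each marker in each offspring
#' (\code{"A"}, \code{"B"} or \code{"N"} for missing).
#'
#' @slot genome A \linkS4class{Seqinfo} with chromosome lengths.
#' @slot markers A \linkS4class{GRanges} of width-1 marker positions,
#'   ordered within each chromosome.
#' @slot genotypes A character matrix (markers x offspring) of phase calls.
#' @slot truthCrossovers A \linkS4class{GRanges} of width-1 true crossover
#'   positions with metadata columns \code{offspring} and \code{parent}
#'   (always \code{"paternal"}; the class validity enforces the achiasmatic
#'   female invariant). Empty for real data.
#' @slot offspring A \linkS4class{DataFrame} with one row per offspring:
#'   \code{id}, \code{group} (species or cross label), \code{cross},
#'   \code{sex}.
#' @slot config A list recording the simulation configuration (may be empty).
#'
#' @seealso \code{\link{simulateCross}}, \code{\link{detectCrossovers}}
#' @name CrossDataset-class
#' @aliases CrossDataset
#' @exportClass CrossDataset
setClass("CrossDataset",
    representation(
        genome = "Seqinfo",
        markers = "GRanges",
        genotypes = "matrix",
        truthCrossovers = "GRanges",
        offspring = "DataFrame",
        config = "list"
    )
)

setValidity("CrossDataset", function(object) {
    msg <- character()
    if (nrow(object@genotypes) != length(object@markers))
        msg <- c(msg, "genotype rows must match number of markers")
    if (ncol(object@genotypes) != nrow(object@offspring))
        msg <- c(msg, "genotype columns must match number of offspring")
    vals <- unique(as.vector(object@genotypes))
    if (length(vals) && !all(vals %in% c("A", "B", "N")))
        msg <- c(msg, "genotype calls must be 'A', 'B' or 'N'")
    if (length(object@markers) &&
        S4Vectors::isSorted(object@markers) == FALSE)
        msg <- c(msg, "markers must be sorted by position within chromosome")
    tc <- object@truthCrossovers
    if (length(tc)) {
        if (!all(c("offspring", "parent") %in% names(S4Vectors::mcols(tc))))
            msg <- c(msg, "truthCrossovers needs 'offspring' and 'parent'")
        else if (any(S4Vectors::mcols(tc)$parent != "paternal"))
            msg <- c(msg,
                "maternal meiosis is achiasmatic: all crossovers paternal")
        sl <- GenomeInfoDb::seqlengths(object@genome)
        onChrom <- as.character(GenomeInfoDb::seqnames(tc))
        if (!all(onChrom %in% names(sl)))
            msg <- c(msg, "truth crossover on unknown chromosome")
        else if (any(GenomicRanges::end(tc) > sl[onChrom]))
            msg <- c(msg, "truth crossover beyond chromosome end")
    }
    if (length(msg)) msg else TRUE
})

#' GeneticMap: markers with physical and genetic coordinates
#'
#' A genetic map for one cross or pooled group: ordered markers carrying a
#' cumulative centiMorgan position per chromosome, estimated from
#' recombination fractions alone (no mapping function; appropriate for
#' fine-scale maps).
#'
#' @slot markers A \linkS4class{GRanges} of width-1 marker positions with a
#'   numeric metadata column \code{cM}, non-decreasing within chromosome.
#' @slot nOffspring Number of offspring the map was estimated from.
#'
#' @seealso \code{\link{estimateMap}}, \code{\link{mapStatistics}}
#' @name GeneticMap-class
#' @aliases GeneticMap
#' @exportClass GeneticMap
setClass("GeneticMap",
    representation(
        markers = "GRanges",
        nOffspring = "integer"
    )
)

setValidity("GeneticMap", function(object) {
    msg <- character()
    if (length(object@nOffspring) != 1L || object@nOffspring < 1L)
        msg <- c(msg, "nOffspring must be a single integer >= 1")
    m <- object@markers
    if (length(m)) {
        if (!"cM" %in% names(S4Vectors::mcols(m)))
            msg <- c(msg, "markers need a 'cM' metadata column")
        else {
            bychr <- split(S4Vectors::mcols(m)$cM,
                           as.character(GenomeInfoDb::seqnames(m)))
            if (!all(vapply(bychr, function(x) !is.unsorted(x), logical(1))))
                msg <- c(msg, "cM must be non-decreasing within chromosome")
        }
    }
    if (length(msg)) msg else TRUE
})

## ---- Generics ----

#' @rdname CrossDataset-class
#' @param x,object A \code{CrossDataset} or \code{GeneticMap}.
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname CrossDataset-class
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname CrossDataset-class
#' @export
setGeneric("truthCrossovers", function(x) standardGeneric("truthCrossovers"))

#' @rdname CrossDataset-class
#' @export
setGeneric("offspringInfo", function(x) standardGeneric("offspringInfo"))

#' @rdname GeneticMap-class
#' @param x,object A \code{GeneticMap}.
#' @export
setGeneric("nOffspring", function(x) standardGeneric("nOffspring"))

#' @rdname GeneticMap-class
#' @export
setGeneric("totalCM", function(x) standardGeneric("totalCM"))

## ---- Accessors ----

#' @rdname CrossDataset-class
#' @export
setMethod("markers", "CrossDataset", function(x) x@markers)

#' @rdname CrossDataset-class
#' @export
setMethod("genotypeMatrix", "CrossDataset", function(x) x@genotypes)

#' @rdname CrossDataset-class
#' @export
setMethod("truthCrossovers", "CrossDataset", function(x) x@truthCrossovers)

#' @rdname CrossDataset-class
#' @export
setMethod("offspringInfo", "CrossDataset", function(x) x@offspring)

#' @rdname CrossDataset-class
#' @importFrom GenomeInfoDb seqinfo
#' @export
setMethod("seqinfo", "CrossDataset", function(x) x@genome)

#' @rdname GeneticMap-class
#' @export
setMethod("markers", "GeneticMap", function(x) x@markers)

#' @rdname GeneticMap-class
#' @export
setMethod("nOffspring", "GeneticMap", function(x) x@nOffspring)

#' @rdname GeneticMap-class
#' @export
setMethod("seqinfo", "GeneticMap", function(x) GenomeInfoDb::seqinfo(x@markers))

## Total genetic length: sum over chromosomes of the terminal cM value.
#' @rdname GeneticMap-class
#' @export
setMethod("totalCM", "GeneticMap", function(x) {
    m <- x@markers
    if (!length(m)) return(0)
    bychr <- split(S4Vectors::mcols(m)$cM,
                   as.character(GenomeInfoDb::seqnames(m)))
    sum(vapply(bychr, function(v) max(v) - min(v), numeric(1)))
})

## ---- show ----

#' @rdname CrossDataset-class
#' @export
setMethod("show", "CrossDataset", function(object) {
    cat("CrossDataset with", length(object@markers), "markers,",
        nrow(object@offspring), "offspring on",
        length(GenomeInfoDb::seqnames(object@genome)), "chromosomes\n")
    if (length(object@config))
        cat("  design:", object@config$design,
            "| groups:", paste(unique(object@offspring$group),
                               collapse = ", "), "\n")
    cat("  truth crossovers:", length(object@truthCrossovers), "\n")
})

#' @rdname GeneticMap-class
#' @export
setMethod("show", "GeneticMap", function(object) {
    cat("GeneticMap:", length(object@markers), "markers on",
        length(unique(GenomeInfoDb::seqnames(object@markers))),
        "chromosomes;", sprintf("%.1f cM total", totalCM(object)),
        "from", object@nOffspring, "offspring\n")
})
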