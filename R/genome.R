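#' Published Heliconius melpomene chromosome lengths
#'
#' The 21 chromosome lengths of the ordered Hmel2 assembly (272,636,897 bp
#' total), as a \linkS4class{Seqinfo} object. This is the default genome for
#' the simulators and for window tiling.
#'
#' @return A \linkS4class{Seqinfo} with 21 chromosomes.
#' @examples
#' hmelGenome()
#' @export
hmelGenome <- function() {
    tab <- hmelChromosomeMaps()
    GenomeInfoDb::Seqinfo(seqnames = tab$chrom,
                          seqlengths = tab$length_bp,
                          genome = "Hmel2.ordered")
}

#' Published per-chromosome physical and genetic map lengths
#'
#' Physical length (bp) and paternal genetic length (cM) for each of the 21
#' chromosomes, for H. melpomene, H. cydno and their hybrids, shipped as a
#' plain-text table with the package. Useful for recomputing broad-scale
#' recombination rates and as realistic chromosome sizes for simulation.
#'
#' @return A data.frame with columns \code{chrom}, \code{length_bp},
#'   \code{melpomene_cM}, \code{cydno_cM}, \code{hybrid_cM}.
#' @examples
#' tab <- hmelChromosomeMaps()
#' round(tab$melpomene_cM / (tab$length_bp / 1e6), 2)  # cM/Mb per chromosome
#' @export
hmelChromosomeMaps <- function() {
    f <- system.file("extdata", "hmel2_chromosome_maps.tsv",
                     package = "recombinv", mustWork = TRUE)
    utils::read.delim(f, stringsAsFactors = FALSE)
}

#' Published cross sizes and total map lengths
#'
#' Per-cross offspring counts and total paternal map lengths (cM) for the
#' three H. melpomene F1 crosses, three H. cydno F1 crosses and four hybrid
#' backcross grandparent groups.
#'
#' @return A data.frame with columns \code{species}, \code{cross},
#'   \code{offspring}, \code{map_cM}.
#' @examples
#' agg <- aggregate(offspring ~ species, hmelCrossSummary(), sum)
#' sum(agg$offspring)  # 963 offspring in total
#' @export
hmelCrossSummary <- function() {
    f <- system.file("extdata", "hmel2_cross_summary.tsv",
                     package = "recombinv", mustWork = TRUE)
    utils::read.delim(f, stringsAsFactors = FALSE)
}
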