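# Plain-text interchange formats. All interval tables on disk are 0-based
# half-open; marker and site positions are written as stored.

.writeTsv <- function(df, file) {
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Write / read a marker-genotype table
#'
#' TSV with columns \code{chrom}, \code{pos_bp} and one column per
#' offspring holding phase calls A/B/N.
#'
#' @param x A \linkS4class{CrossDataset}.
#' @param file Path to write to / read from.
#' @param groups Optional named vector mapping offspring ids to group
#'   labels when reading (defaults to one group \code{"all"}).
#' @return \code{writeGenotypeTable} returns the path invisibly;
#'   \code{readGenotypeTable} returns a list usable by
#'   \code{\link{detectCrossovers}} (elements \code{markers},
#'   \code{genotypes}, \code{offspring}).
#' @export
writeGenotypeTable <- function(x, file) {
    stopifnot(methods::is(x, "CrossDataset"))
    df <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(markers(x))),
        pos_bp = GenomicRanges::start(markers(x)))
    geno <- genotypeMatrix(x)
    for (j in seq_len(ncol(geno))) df[[colnames(geno)[j]]] <- geno[, j]
    .writeTsv(df, file)
}

#' @rdname writeGenotypeTable
#' @export
readGenotypeTable <- function(file, groups = NULL) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (!all(c("chrom", "pos_bp") %in% names(df)))
        stop("genotype table needs 'chrom' and 'pos_bp' columns")
    ids <- setdiff(names(df), c("chrom", "pos_bp"))
    geno <- as.matrix(df[, ids, drop = FALSE])
    grp <- if (is.null(groups)) rep("all", length(ids))
           else unname(groups[ids])
    list(markers = df[, c("chrom", "pos_bp")],
         genotypes = geno,
         offspring = data.frame(id = ids, group = grp))
}

#' Write / read crossover intervals as BED
#'
#' BED-like TSV (0-based half-open): \code{chrom}, \code{start_bp},
#' \code{end_bp}, \code{offspring}, \code{group}.
#'
#' @param crossovers GRanges from \code{\link{detectCrossovers}}.
#' @param file Path.
#' @param genome Optional \linkS4class{Seqinfo} attached on read.
#' @export
writeCrossoverBed <- function(crossovers, file) {
    .writeTsv(data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(crossovers)),
        start_bp = .hoStart(crossovers), end_bp = .hoEnd(crossovers),
        offspring = S4Vectors::mcols(crossovers)$offspring,
        group = S4Vectors::mcols(crossovers)$group), file)
}

#' @rdname writeCrossoverBed
#' @export
readCrossoverBed <- function(file, genome = NULL) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    si <- if (is.null(genome)) NULL else .asSeqinfo(genome)
    gr <- .grFromHalfOpen(df$chrom, df$start_bp, df$end_bp, seqinfo = si)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        offspring = as.character(df$offspring),
        group = as.character(df$group))
    gr
}

#' Write / read a genetic map table
#'
#' TSV with \code{chrom}, \code{pos_bp}, \code{cM} per marker.
#'
#' @param map A \linkS4class{GeneticMap}.
#' @param file Path.
#' @param nOffspring Offspring count to attach when reading.
#' @param genome Optional \linkS4class{Seqinfo} attached on read.
#' @export
writeMapTable <- function(map, file) {
    m <- markers(map)
    .writeTsv(data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(m)),
        pos_bp = GenomicRanges::start(m),
        cM = S4Vectors::mcols(m)$cM), file)
}

#' @rdname writeMapTable
#' @export
readMapTable <- function(file, nOffspring, genome = NULL) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = df$pos_bp, width = 1L))
    if (!is.null(genome)) {
        si <- .asSeqinfo(genome)
        suppressWarnings(GenomeInfoDb::seqinfo(gr) <-
            si[GenomeInfoDb::seqlevels(gr)])
    }
    S4Vectors::mcols(gr)$cM <- df$cM
    methods::new("GeneticMap", markers = gr,
                 nOffspring = as.integer(nOffspring))
}

#' Write / read split-read candidates
#'
#' BEDPE-derived TSV collapsed to the spanned interval: \code{chrom},
#' \code{start_bp}, \code{end_bp}, \code{species}, \code{sex},
#' \code{support_reads}, \code{tier}.
#'
#' @param candidates GRanges of candidates.
#' @param file Path.
#' @param genome Optional \linkS4class{Seqinfo}.
#' @export
writeCandidateTable <- function(candidates, file) {
    mc <- S4Vectors::mcols(candidates)
    .writeTsv(data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(candidates)),
        start_bp = .hoStart(candidates), end_bp = .hoEnd(candidates),
        species = mc$species, sex = mc$sex,
        support_reads = mc$supportReads, tier = mc$tier), file)
}

#' @rdname writeCandidateTable
#' @export
readCandidateTable <- function(file, genome = NULL) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    splitReadCandidates(df$chrom, df$start_bp, df$end_bp, df$species,
                        df$sex, df$support_reads, df$tier,
                        genome = genome)
}

#' Write / read trio scaffold alignments
#'
#' Coords-style TSV: \code{chrom}, \code{ref_start_bp},
#' \code{ref_end_bp}, \code{orientation}, \code{identity},
#' \code{scaffold}, \code{species}, \code{sex}.
#'
#' @param alignments GRanges from \code{\link{trioAlignments}}.
#' @param file Path.
#' @param genome Optional \linkS4class{Seqinfo}.
#' @export
writeAlignmentTable <- function(alignments, file) {
    mc <- S4Vectors::mcols(alignments)
    .writeTsv(data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(alignments)),
        ref_start_bp = .hoStart(alignments),
        ref_end_bp = .hoEnd(alignments),
        orientation = mc$orientation, identity = mc$identity,
        scaffold = mc$scaffold, species = mc$species, sex = mc$sex),
        file)
}

#' @rdname writeAlignmentTable
#' @export
readAlignmentTable <- function(file, genome = NULL) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    trioAlignments(df$chrom, df$ref_start_bp, df$ref_end_bp,
                   df$scaffold, df$species, df$sex, df$orientation,
                   df$identity, genome = genome)
}

#' Write / read a site-frequency table
#'
#' TSV with \code{chrom}, \code{pos_bp}, frequencies \code{p1..pO} and
#' haplotype counts \code{n1..nO}.
#'
#' @param sft Site-frequency data.frame.
#' @param file Path.
#' @export
writeSiteFrequencyTable <- function(sft, file) {
    .writeTsv(.sftCheck(sft), file)
}

#' @rdname writeSiteFrequencyTable
#' @export
readSiteFrequencyTable <- function(file) {
    .sftCheck(utils::read.delim(file, stringsAsFactors = FALSE))
}

#' Read a contig layout table
#'
#' TSV with \code{chrom} and \code{boundary_bp} (0-based positions of
#' contig ends on the chromosome).
#'
#' @param file Path.
#' @return A data.frame with \code{chrom}, \code{boundary_bp}.
#' @export
readContigLayout <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (!all(c("chrom", "boundary_bp") %in% names(df)))
        stop("contig layout needs 'chrom' and 'boundary_bp' columns")
    df
}

#' Write windowed rates
#'
#' TSV mirror of the \code{\link{windowRates}} /
#' \code{\link{bootstrapCI}} output.
#'
#' @param rates Data.frame from \code{\link{windowRates}} or
#'   \code{\link{bootstrapCI}}.
#' @param file Path.
#' @export
writeWindowRates <- function(rates, file) {
    .writeTsv(rates, file)
}
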