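# Small fixtures built in code, shared across test files.

# One-offspring genotype input for detectCrossovers(): phases is a character
# vector of A/B/N calls, positions the marker bp on a single chromosome.
toyGenotypes <- function(phases, positions = seq_along(phases) * 1000L,
                         chrom = "chr1", id = "o1", group = "sp") {
    list(markers = data.frame(chrom = chrom, pos_bp = positions),
         genotypes = matrix(phases, ncol = 1L,
                            dimnames = list(NULL, id)),
         offspring = data.frame(id = id, group = group))
}

# Crossover GRanges built directly from half-open intervals.
toyCrossovers <- function(chrom, leftBp, rightBp, offspring, group) {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = leftBp + 1L, end = rightBp))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        offspring = offspring, group = group)
    gr
}

toyCandidate <- function(chrom = "chr1", startBp, endBp,
                         species = "cydno", sex = "F",
                         tier = "default") {
    splitReadCandidates(chrom, startBp, endBp, species, sex,
                        supportReads = 3L, tier = tier)
}

# Independent oracle for the popgen estimators: a plain per-site loop over
# the defining sums, deliberately kept separate from the package's
# vectorized implementation.
oraclePopgen <- function(sft) {
    num <- den <- dsum <- abba <- baba <- 0
    for (i in seq_len(nrow(sft))) {
        pa <- sft$p1[i]; pb <- sft$p2[i]
        na <- sft$n1[i]; nb <- sft$n2[i]
        num <- num + (pa - pb)^2 - pa * (1 - pa) / (na - 1) -
            pb * (1 - pb) / (nb - 1)
        den <- den + pa * (1 - pb) + pb * (1 - pa)
        dsum <- dsum + pa * (1 - pb) + pb * (1 - pa)
        p3 <- sft$p3[i]; po <- sft$pO[i]
        abba <- abba + (1 - pa) * pb * p3 * (1 - po)
        baba <- baba + pa * (1 - pb) * p3 * (1 - po)
    }
    list(fst = num / den, dxy = dsum / nrow(sft),
         d = (abba - baba) / (abba + baba))
}
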