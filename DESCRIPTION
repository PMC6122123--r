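Package: recombinv
Title: Recombination Landscapes and Inversion Candidates from Hybrid Crosses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to ask whether two hybridizing species are separated by
    chromosomal inversions or by reduced hybrid recombination. Implements
    crossover detection from ordered parental-phase genotypes, genetic-map
    estimation from recombination fractions, sliding-window recombination
    rates with bootstrap confidence intervals, bootstrapped one-tailed
    Kolmogorov-Smirnov and label-permutation comparisons of recombination
    between groups, a random-inversion detection-power simulation, a
    multi-filter sieve for split-read inversion candidates with evidence
    classification against trio-assembly alignments, and windowed
    introgression statistics (Hudson FST, dXY, Patterson's D and fd) around
    candidate intervals. A synthetic-data module simulates crosses with
    achiasmatic female meiosis, obligate single male crossovers and planted
    inversions, plus split-read candidates, trio scaffold alignments and
    four-population site frequencies, so the whole pipeline is exercisable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Genetics, Recombination, StructuralVariation, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
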