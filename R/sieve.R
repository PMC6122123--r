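#' Reject candidates containing a same-species recombination
#'
#' A split-read inversion candidate is refuted by the linkage maps when at
#' least one crossover of the same species is entirely contained within the
#' candidate interval: a crossover inside the interval means the markers
#' there recombine freely in that species, which an inversion (relative to
#' the reference) would prevent. Containment, not mere overlap, triggers
#' rejection; a crossover interval that only partially overlaps the
#' candidate may localize the exchange outside it.
#'
#' @param candidates GRanges from \code{\link{splitReadCandidates}}.
#' @param crossovers GRanges with a \code{group} metadata column holding
#'   species labels comparable to the candidates' \code{species}.
#'
#' @return A list with \code{kept} and \code{rejected} GRanges; rejected
#'   candidates carry a \code{reason} column.
#' @export
filterByRecombination <- function(candidates, crossovers) {
    if (!length(candidates)) {
        rejected <- candidates
        S4Vectors::mcols(rejected)$reason <- character(0)
        return(list(kept = candidates, rejected = rejected))
    }
    if (length(crossovers) &&
        is.null(S4Vectors::mcols(crossovers)$group))
        stop("crossovers must carry species labels in 'group'")
    rej <- rep(FALSE, length(candidates))
    if (length(crossovers)) {
        hits <- GenomicRanges::findOverlaps(crossovers, candidates,
                                            type = "within")
        ok <- S4Vectors::mcols(crossovers)$group[
                  S4Vectors::queryHits(hits)] ==
              S4Vectors::mcols(candidates)$species[
                  S4Vectors::subjectHits(hits)]
        rej[unique(S4Vectors::subjectHits(hits)[ok])] <- TRUE
    }
    kept <- candidates[!rej]
    rejected <- candidates[rej]
    S4Vectors::mcols(rejected)$reason <-
        rep("same_species_recombination", length(rejected))
    list(kept = kept, rejected = rejected)
}

#' Reject candidates spanned collinearly by a same-species trio scaffold
#'
#' A candidate of length L is refuted when a single same-species
#' forward-orientation alignment covers the whole candidate and extends
#' strictly more than L/2 beyond both breakpoints
#' (\code{spanMode = "both"}, the default) or beyond at least one
#' breakpoint (\code{spanMode = "either"}). A collinear scaffold across the
#' breakpoints shows the sampled haplotype matches the reference order.
#' Reverse-orientation alignments support rather than refute an inversion
#' and never cause rejection.
#'
#' @param candidates GRanges of candidates.
#' @param alignments GRanges from \code{\link{trioAlignments}}.
#' @param spanMode \code{"both"} or \code{"either"}.
#'
#' @return A list with \code{kept} and \code{rejected} GRanges.
#' @export
filterByTrioSpan <- function(candidates, alignments,
                             spanMode = c("both", "either")) {
    spanMode <- match.arg(spanMode)
    if (!length(candidates)) {
        rejected <- candidates
        S4Vectors::mcols(rejected)$reason <- character(0)
        return(list(kept = candidates, rejected = rejected))
    }
    rej <- rep(FALSE, length(candidates))
    if (length(alignments)) {
        fwd <- alignments[S4Vectors::mcols(alignments)$orientation ==
                          "forward"]
        hits <- GenomicRanges::findOverlaps(candidates, fwd,
                                            type = "within")
        if (length(hits)) {
            ci <- S4Vectors::queryHits(hits)
            ai <- S4Vectors::subjectHits(hits)
            sameSp <- S4Vectors::mcols(candidates)$species[ci] ==
                      S4Vectors::mcols(fwd)$species[ai]
            L <- GenomicRanges::width(candidates)[ci]
            extL <- .hoStart(candidates)[ci] - .hoStart(fwd)[ai]
            extR <- .hoEnd(fwd)[ai] - .hoEnd(candidates)[ci]
            spans <- if (spanMode == "both")
                extL > L / 2 & extR > L / 2
            else extL > L / 2 | extR > L / 2
            rej[unique(ci[sameSp & spans])] <- TRUE
        }
    }
    kept <- candidates[!rej]
    rejected <- candidates[rej]
    S4Vectors::mcols(rejected)$reason <-
        rep("spanned_by_trio_scaffold", length(rejected))
    list(kept = kept, rejected = rejected)
}

#' Reject candidates shorter than a minimum length
#'
#' Inversions shorter than 1 kb (the default cutoff) are rejected because
#' linkage disequilibrium between SNPs at that separation is already above
#' background, so such inversions cannot be what maintains linkage. The
#' rule is strict: a candidate of exactly \code{minBp} is kept.
#'
#' @param candidates GRanges of candidates.
#' @param minBp Minimum length in bp (default 1,000).
#' @return A list with \code{kept} and \code{rejected} GRanges.
#' @export
filterByLength <- function(candidates, minBp = 1000L) {
    if (minBp <= 0) stop("'minBp' must be positive")
    if (!length(candidates)) {
        rejected <- candidates
        S4Vectors::mcols(rejected)$reason <- character(0)
        return(list(kept = candidates, rejected = rejected))
    }
    rej <- GenomicRanges::width(candidates) < minBp
    kept <- candidates[!rej]
    rejected <- candidates[rej]
    S4Vectors::mcols(rejected)$reason <-
        rep("below_min_length", length(rejected))
    list(kept = kept, rejected = rejected)
}

#' Rescue tentative candidates corroborated by other samples
#'
#' Tentative-tier candidates (called under relaxed read support, e.g. for
#' a low-coverage sample) are retained only where they overlap at least one
#' default-tier candidate from a different sample (a different
#' species/sex combination); all default-tier candidates are retained.
#'
#' @param candidatesDefault GRanges of default-tier candidates.
#' @param candidatesTentative GRanges of tentative-tier candidates.
#' @return A single GRanges: all default candidates plus rescued
#'   tentative ones.
#' @export
rescueTentative <- function(candidatesDefault, candidatesTentative) {
    if (!length(candidatesTentative)) return(candidatesDefault)
    if (!length(candidatesDefault)) return(candidatesDefault)
    hits <- GenomicRanges::findOverlaps(candidatesTentative,
                                        candidatesDefault)
    tSample <- paste(S4Vectors::mcols(candidatesTentative)$species,
                     S4Vectors::mcols(candidatesTentative)$sex)
    dSample <- paste(S4Vectors::mcols(candidatesDefault)$species,
                     S4Vectors::mcols(candidatesDefault)$sex)
    other <- tSample[S4Vectors::queryHits(hits)] !=
             dSample[S4Vectors::subjectHits(hits)]
    keep <- unique(S4Vectors::queryHits(hits)[other])
    out <- c(candidatesDefault, candidatesTentative[keep])
    sort(out)
}

#' Merge overlapping candidates into groups
#'
#' Groups are the connected components of the interval-overlap graph:
#' candidates on the same chromosome whose intervals share at least one bp
#' are chained transitively (book-ended candidates that merely touch are
#' not merged). The group interval is the union span of its members.
#'
#' @param candidates GRanges of retained candidates.
#' @return A GRanges of group intervals with metadata columns
#'   \code{members} (IntegerList of candidate indices), \code{n_members},
#'   and \code{species_set} (comma-separated species of the members).
#' @export
mergeGroups <- function(candidates) {
    if (!length(candidates)) {
        out <- GenomicRanges::GRanges()
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(
            members = IRanges::IntegerList(),
            n_members = integer(0), species_set = character(0))
        return(out)
    }
    ## min.gapwidth = 0 merges only truly overlapping ranges
    red <- GenomicRanges::reduce(candidates, min.gapwidth = 0L,
                                 with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    spset <- vapply(seq_along(red), function(i) {
        paste(sort(unique(S4Vectors::mcols(candidates)$species[
            revmap[[i]]])), collapse = ",")
    }, character(1))
    S4Vectors::mcols(red) <- S4Vectors::DataFrame(
        members = revmap,
        n_members = lengths(revmap),
        species_set = spset)
    red
}

## Does any scaffold of this species show forward+reverse alignments
## flanking a breakpoint of the group interval? A scaffold qualifies when
## it has a reverse alignment overlapping the group and a forward
## alignment within flankBp of either breakpoint.
.trioInversionSpecies <- function(group, alignments, flankBp = 10000L) {
    chrom <- as.character(GenomeInfoDb::seqnames(group))
    onc <- alignments[as.character(
        GenomeInfoDb::seqnames(alignments)) == chrom]
    if (!length(onc)) return(character(0))
    gs <- .hoStart(group); ge <- .hoEnd(group)
    aS <- .hoStart(onc); aE <- .hoEnd(onc)
    mc <- S4Vectors::mcols(onc)
    revOverlap <- mc$orientation == "reverse" &
        .overlapLen(aS, aE, gs, ge) > 0
    nearBreak <- pmin(abs(aS - gs), abs(aE - gs),
                      abs(aS - ge), abs(aE - ge)) <= flankBp
    fwdFlank <- mc$orientation == "forward" & nearBreak
    out <- character(0)
    for (sp in unique(mc$species)) {
        scRev <- unique(mc$scaffold[revOverlap & mc$species == sp])
        scFwd <- unique(mc$scaffold[fwdFlank & mc$species == sp])
        if (length(intersect(scRev, scFwd))) out <- c(out, sp)
    }
    out
}

#' Classify candidate groups by their evidence
#'
#' Assigns each merged group one of three evidence classes, evaluated per
#' species: \code{"split_one_trio_both"} when split reads occur in only one
#' species but trio scaffolds show inversion evidence (forward and reverse
#' alignments flanking a breakpoint) in both; otherwise
#' \code{"split_and_trio"} when at least one species has both split-read
#' members and trio inversion evidence; otherwise \code{"split_only"}.
#' Also flags groups whose breakpoints fall near a contig boundary, where
#' an apparent inversion may reflect reference misassembly.
#'
#' @param groups GRanges from \code{\link{mergeGroups}}.
#' @param candidates The candidate GRanges the groups were built from.
#' @param alignments GRanges from \code{\link{trioAlignments}}.
#' @param contigs Optional contig layout: a data.frame with \code{chrom}
#'   and \code{boundary_bp} (0-based positions of contig ends).
#' @param nearBp Distance (bp) within which a breakpoint counts as "near"
#'   a contig boundary (default 5,000).
#' @param flankBp Breakpoint flank used to pair forward/reverse scaffold
#'   alignments (default 10,000).
#'
#' @return The groups GRanges with added metadata columns
#'   \code{classification}, \code{species_set} (updated for the third
#'   class) and \code{near_contig_boundary}.
#' @export
classifyGroups <- function(groups, candidates, alignments, contigs = NULL,
                           nearBp = 5000L, flankBp = 10000L) {
    if (nearBp < 0) stop("'nearBp' must be >= 0")
    if (!length(groups)) {
        S4Vectors::mcols(groups)$classification <- character(0)
        S4Vectors::mcols(groups)$near_contig_boundary <- logical(0)
        return(groups)
    }
    if (any(lengths(S4Vectors::mcols(groups)$members) == 0L))
        stop("cannot classify a group with no members")
    cls <- character(length(groups))
    spset <- character(length(groups))
    near <- logical(length(groups))
    for (i in seq_along(groups)) {
        g <- groups[i]
        memb <- S4Vectors::mcols(groups)$members[[i]]
        splitSp <- sort(unique(
            S4Vectors::mcols(candidates)$species[memb]))
        trioSp <- .trioInversionSpecies(g, alignments, flankBp)
        if (length(splitSp) == 1L && length(trioSp) >= 2L) {
            cls[i] <- "split_one_trio_both"
            spset[i] <- paste(sort(unique(c(splitSp, trioSp))),
                              collapse = ",")
        } else if (length(intersect(splitSp, trioSp))) {
            cls[i] <- "split_and_trio"
            spset[i] <- paste(splitSp, collapse = ",")
        } else {
            cls[i] <- "split_only"
            spset[i] <- paste(splitSp, collapse = ",")
        }
        if (!is.null(contigs)) {
            b <- contigs$boundary_bp[contigs$chrom ==
                as.character(GenomeInfoDb::seqnames(g))]
            if (length(b))
                near[i] <- min(abs(b - .hoStart(g)),
                               abs(b - .hoEnd(g))) <= nearBp
        }
    }
    S4Vectors::mcols(groups)$classification <- cls
    S4Vectors::mcols(groups)$species_set <- spset
    S4Vectors::mcols(groups)$near_contig_boundary <- near
    groups
}

#' Run the full candidate sieve
#'
#' Applies the three rejection filters (same-species recombination
#' containment, collinear trio-scaffold spanning, minimum length) to the
#' default-tier candidates, applies the same filters to tentative-tier
#' candidates and rescues those overlapping a retained default candidate
#' from a different sample, merges the survivors into overlap groups and
#' classifies each group's evidence. Each filter is a pure predicate on one
#' candidate, so the retained set does not depend on filter order; every
#' rejected candidate records the first rule (in the order above) that
#' rejected it.
#'
#' @param candidates GRanges of all candidates (both tiers).
#' @param crossovers GRanges of species-labelled crossovers.
#' @param alignments GRanges of trio scaffold alignments.
#' @param contigs Optional contig layout (see
#'   \code{\link{classifyGroups}}).
#' @param minBp,spanMode,nearBp,flankBp Filter parameters, passed through.
#'
#' @return A list: \code{kept} (retained candidates), \code{rejected}
#'   (with \code{reason}), \code{groups} (classified groups), and
#'   \code{report} (per-candidate decision data.frame).
#' @export
runSieve <- function(candidates, crossovers, alignments, contigs = NULL,
                     minBp = 1000L, spanMode = "both", nearBp = 5000L,
                     flankBp = 10000L) {
    tier <- S4Vectors::mcols(candidates)$tier
    if (is.null(tier)) tier <- rep("default", length(candidates))
    applyFilters <- function(x) {
        f1 <- filterByRecombination(x, crossovers)
        f2 <- filterByTrioSpan(f1$kept, alignments, spanMode)
        f3 <- filterByLength(f2$kept, minBp)
        list(kept = f3$kept,
             rejected = c(f1$rejected, f2$rejected, f3$rejected))
    }
    def <- applyFilters(candidates[tier == "default"])
    ten <- applyFilters(candidates[tier == "tentative"])
    tKeep <- logical(length(ten$kept))
    if (length(ten$kept) && length(def$kept)) {
        hits <- GenomicRanges::findOverlaps(ten$kept, def$kept)
        tS <- paste(S4Vectors::mcols(ten$kept)$species,
                    S4Vectors::mcols(ten$kept)$sex)
        dS <- paste(S4Vectors::mcols(def$kept)$species,
                    S4Vectors::mcols(def$kept)$sex)
        other <- tS[S4Vectors::queryHits(hits)] !=
                 dS[S4Vectors::subjectHits(hits)]
        tKeep[unique(S4Vectors::queryHits(hits)[other])] <- TRUE
    }
    kept <- sort(c(def$kept, ten$kept[tKeep]))
    droppedTent <- ten$kept[!tKeep]
    groups <- classifyGroups(mergeGroups(kept), kept, alignments,
                             contigs, nearBp, flankBp)
    rep1 <- function(gr, decision) {
        if (!length(gr)) return(NULL)
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start_bp = .hoStart(gr), end_bp = .hoEnd(gr),
                   species = S4Vectors::mcols(gr)$species,
                   sex = S4Vectors::mcols(gr)$sex,
                   tier = S4Vectors::mcols(gr)$tier,
                   decision = decision,
                   reason = if (decision == "rejected")
                       S4Vectors::mcols(gr)$reason else "")
    }
    report <- rbind(rep1(kept, "kept"),
                    rep1(c(def$rejected, ten$rejected), "rejected"),
                    rep1(droppedTent, "rejected_unrescued"))
    list(kept = kept, rejected = c(def$rejected, ten$rejected),
         groups = groups, report = report)
}
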