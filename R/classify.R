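## Four-way transcript classification against the gene annotation, UTR
## computation, convergent 3'-overlap detection, and comparison with a
## TSS catalogue.
##
## The class cascade is deterministic (first match wins):
##   cdRNA  - covers >= cdrna_cds_cover of a same-strand CDS
##   cdRNA  - rescued: intersects a same-strand CDS whose own 5' end has
##            TSS support (short call over a weakly covered ORF)
##   isRNA  - contained within a same-strand CDS (small slack)
##   asRNA  - opposite-strand CDS overlap of at least as_min_overlap nt
##   igRNA  - no CDS overlap on either strand
##   unassigned otherwise
## Sense relationships outrank antisense ones: a transcript antisense to
## one gene but coding on its own strand is an mRNA, not an asRNA.

#' Parameters for transcript classification
#'
#' @param cdrna_cds_cover minimum fraction of a same-strand CDS a
#'   transcript must cover to count as encoding it (default 0.8).
#' @param as_min_overlap minimum opposite-strand overlap in nt for an
#'   asRNA call (default 10).
#' @param operon_containment CDS fraction required for a gene to be
#'   listed among a transcript's covered genes (default 0.9).
#' @param leaderless_max maximum 5'-UTR of a leaderless transcript in nt
#'   (default 3).
#' @param tss_window half-width in nt of the window within which a TSS
#'   supports a 5' end (default 10).
#' @param small_slack containment slack in nt for the isRNA test
#'   (default 10).
#' @param rescue_with_tss enable the cdRNA rescue rule; `NA` (default)
#'   means "on whenever a TSS catalogue is supplied".
#' @return list of class `ClassifyParams`.
#' @export
classifyParams <- function(cdrna_cds_cover = 0.8, as_min_overlap = 10,
                           operon_containment = 0.9, leaderless_max = 3,
                           tss_window = 10, small_slack = 10,
                           rescue_with_tss = NA) {
    stopifnot(cdrna_cds_cover > 0, cdrna_cds_cover <= 1,
              operon_containment > 0, operon_containment <= 1,
              as_min_overlap >= 0, tss_window >= 0, leaderless_max >= 0)
    structure(list(cdrna_cds_cover = cdrna_cds_cover,
                   as_min_overlap = as_min_overlap,
                   operon_containment = operon_containment,
                   leaderless_max = leaderless_max,
                   tss_window = tss_window, small_slack = small_slack,
                   rescue_with_tss = rescue_with_tss),
              class = "ClassifyParams")
}

## genomic 5' / 3' end of a stranded range
end5 <- function(gr) ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
end3 <- function(gr) ifelse(as.character(strand(gr)) == "+", end(gr), start(gr))

tssNear <- function(positions, tss, replicon, st, window) {
    ## positions: numeric; tss: data.frame(replicon, strand, position)
    sel <- tss$replicon == replicon & tss$strand == st
    if (!any(sel)) return(rep(FALSE, length(positions)))
    p <- tss$position[sel]
    vapply(positions, function(x) any(abs(p - x) <= window), logical(1))
}

#' Classify called transcripts
#'
#' Applies the class cascade to every transcript, fills in covered
#' genes, ORF counts, UTR lengths and (when a TSS catalogue is given)
#' 5'-end TSS support.
#'
#' @param tx A [TranscriptSet-class] (classes are overwritten).
#' @param genes CDS `GRanges` with `gene_id` (see [readAnnotation()]).
#' @param params A [classifyParams()] list.
#' @param tss optional TSS catalogue data.frame
#'   (`replicon`, `strand`, `position`).
#' @return The `TranscriptSet` with `txClass`, `coveredGenes`, `nOrfs`,
#'   `utr5`, `utr3`, `leaderless` and `tssSupported` filled in.
#' @export
classifyTranscripts <- function(tx, genes, params = classifyParams(),
                                tss = NULL) {
    stopifnot(is(tx, "TranscriptSet"))
    n <- length(tx)
    rescue <- if (is.na(params$rescue_with_tss)) !is.null(tss)
              else isTRUE(params$rescue_with_tss) && !is.null(tss)
    cls <- rep("unassigned", n)
    covered <- vector("list", n)
    utr5 <- utr3 <- rep(NA_real_, n)
    leaderless <- rep(NA, n)

    same <- GenomicRanges::findOverlaps(tx, genes, ignore.strand = FALSE)
    opp.tx <- invertStrand(tx)
    anti <- GenomicRanges::findOverlaps(opp.tx, genes, ignore.strand = FALSE)
    ovw <- function(hits, query) {
        BiocGenerics::width(IRanges::pintersect(
            ranges(query)[S4Vectors::queryHits(hits)],
            ranges(genes)[S4Vectors::subjectHits(hits)]))
    }
    same.w <- ovw(same, tx)
    anti.w <- ovw(anti, opp.tx)
    gene.w <- BiocGenerics::width(genes)

    for (i in seq_len(n)) {
        sh <- S4Vectors::subjectHits(same)[S4Vectors::queryHits(same) == i]
        sw <- same.w[S4Vectors::queryHits(same) == i]
        frac <- sw / gene.w[sh]
        cov.genes <- sh[frac >= params$operon_containment]
        ## order covered genes 5' -> 3' along the transcript
        if (length(cov.genes)) {
            o <- order(start(genes)[cov.genes])
            if (as.character(strand(tx)[i]) == "-") o <- rev(o)
            cov.genes <- cov.genes[o]
        }
        covered[[i]] <- genes$gene_id[cov.genes]

        if (any(frac >= params$cdrna_cds_cover)) {
            cls[i] <- "cdRNA"
            if (!length(cov.genes)) {
                ## encodes a gene by the coverage rule but none reaches the
                ## containment cut: keep the best-covered one
                covered[[i]] <- genes$gene_id[sh[which.max(frac)]]
            }
        } else if (rescue && length(sh) &&
                   any(tssNear(end5(genes[sh]),
                               tss, as.character(seqnames(tx)[i]),
                               as.character(strand(tx)[i]),
                               params$tss_window))) {
            cls[i] <- "cdRNA"
            if (!length(cov.genes)) {
                hit <- sh[tssNear(end5(genes[sh]), tss,
                                  as.character(seqnames(tx)[i]),
                                  as.character(strand(tx)[i]),
                                  params$tss_window)]
                covered[[i]] <- genes$gene_id[hit[1]]
            }
        } else if (length(sh) &&
                   any(start(genes)[sh] - params$small_slack <= start(tx)[i] &
                       end(genes)[sh] + params$small_slack >= end(tx)[i])) {
            cls[i] <- "isRNA"
        } else {
            ah <- S4Vectors::queryHits(anti) == i
            if (any(anti.w[ah] >= params$as_min_overlap)) {
                cls[i] <- "asRNA"
            } else if (!length(sh) && !any(ah)) {
                cls[i] <- "igRNA"
            }   # else unassigned: partial sense overlap without coverage
        }
    }

    ## UTRs for cdRNAs, from the outermost covered gene boundaries
    is.cd <- cls == "cdRNA"
    if (any(is.cd)) {
        u <- utrFromGenes(tx[is.cd], covered[is.cd], genes, params)
        utr5[is.cd] <- u$utr5
        utr3[is.cd] <- u$utr3
        leaderless[is.cd] <- u$leaderless
    }

    mc <- S4Vectors::mcols(tx)
    mc$txClass <- cls
    mc$coveredGenes <- IRanges::CharacterList(covered)
    mc$nOrfs <- ifelse(is.cd, lengths(covered), NA_integer_)
    mc$utr5 <- utr5
    mc$utr3 <- utr3
    mc$leaderless <- leaderless
    S4Vectors::mcols(tx) <- mc
    if (!is.null(tss)) {
        sup <- compareWithTss(tx, tss, params)
        tx$tssSupported <- sup$supported
    }
    tx
}

## shared UTR arithmetic; covered: list of gene-id vectors per transcript
utrFromGenes <- function(tx, covered, genes, params) {
    n <- length(tx)
    utr5 <- utr3 <- rep(NA_real_, n)
    idx <- match(lapply(covered, function(x) x[1]), genes$gene_id)
    for (i in seq_len(n)) {
        ids <- covered[[i]]
        if (!length(ids)) next
        g <- genes[match(ids, genes$gene_id)]
        plus <- as.character(strand(tx)[i]) == "+"
        if (plus) {
            utr5[i] <- min(start(g)) - start(tx)[i]
            utr3[i] <- end(tx)[i] - max(end(g))
        } else {
            utr5[i] <- end(tx)[i] - max(end(g))
            utr3[i] <- min(start(g)) - start(tx)[i]
        }
    }
    ## negative distances (transcript starts inside the gene) clip to 0
    utr5 <- pmax(utr5, 0)
    utr3 <- pmax(utr3, 0)
    list(utr5 = utr5, utr3 = utr3,
         leaderless = utr5 <= params$leaderless_max)
}

#' UTR lengths of protein-coding transcripts
#'
#' Strand-aware distance from the transcript 5' end to the first covered
#' CDS start codon (`utr5`) and from the last covered CDS stop to the
#' transcript 3' end (`utr3`); negative distances are clipped to 0.  A
#' transcript is leaderless when `utr5 <= leaderless_max`.
#'
#' @param tx a classified [TranscriptSet-class]; every transcript must be
#'   a cdRNA with at least one covered gene.
#' @param genes CDS `GRanges`.
#' @param params A [classifyParams()] list.
#' @return data.frame with `utr5`, `utr3`, `leaderless`.
#' @export
computeUtrs <- function(tx, genes, params = classifyParams()) {
    stopifnot(is(tx, "TranscriptSet"))
    if (any(txClass(tx) != "cdRNA"))
        stop("computeUtrs is defined for cdRNAs only", call. = FALSE)
    covered <- as.list(S4Vectors::mcols(tx)$coveredGenes)
    if (any(lengths(covered) == 0))
        stop("every cdRNA must have at least one covered gene", call. = FALSE)
    u <- utrFromGenes(tx, covered, genes, params)
    data.frame(utr5 = u$utr5, utr3 = u$utr3, leaderless = u$leaderless)
}

#' Number of ORFs per protein-coding transcript
#'
#' The count of annotated genes a cdRNA covers; at least 1 by
#' construction.
#'
#' @param tx a classified [TranscriptSet-class].
#' @return integer vector, `NA` for non-cdRNAs.
#' @export
countOrfs <- function(tx) {
    stopifnot(is(tx, "TranscriptSet"))
    n <- lengths(S4Vectors::mcols(tx)$coveredGenes)
    ifelse(txClass(tx) == "cdRNA", n, NA_integer_)
}

#' Detect convergent transcripts with overlapping 3' ends
#'
#' A pair of transcripts on opposite strands of one replicon is flagged
#' when their intervals overlap and the geometry is convergent: each
#' transcript's 3' end lies inside the other (head-to-head tails, the
#' configuration produced by read-through past a shared terminator
#' region).  Mere interval overlap without convergence does not count.
#'
#' @param tx A [TranscriptSet-class].
#' @return list with `pairs` (data.frame `txId_a`, `txId_b`,
#'   `overlap_nt`), `flags` (logical per transcript, in `tx` order), and
#'   `cdrna_fraction` (fraction of cdRNAs flagged, `NaN` when there are
#'   no cdRNAs).
#' @export
find3primeOverlaps <- function(tx) {
    stopifnot(is(tx, "TranscriptSet"))
    flags <- rep(FALSE, length(tx))
    plus <- which(as.character(strand(tx)) == "+")
    minus <- which(as.character(strand(tx)) == "-")
    pairs <- data.frame(txId_a = character(), txId_b = character(),
                        overlap_nt = integer(), stringsAsFactors = FALSE)
    if (length(plus) && length(minus)) {
        hits <- GenomicRanges::findOverlaps(tx[plus], tx[minus],
                                            ignore.strand = TRUE)
        for (k in seq_along(hits)) {
            a <- plus[S4Vectors::queryHits(hits)[k]]
            b <- minus[S4Vectors::subjectHits(hits)[k]]
            ## a on +: 3' end = end(a); b on -: 3' end = start(b)
            if (end(tx)[a] >= start(tx)[b] && end(tx)[a] <= end(tx)[b] &&
                start(tx)[b] >= start(tx)[a] && start(tx)[b] <= end(tx)[a]) {
                ov <- min(end(tx)[a], end(tx)[b]) -
                      max(start(tx)[a], start(tx)[b]) + 1L
                flags[a] <- flags[b] <- TRUE
                pairs[nrow(pairs) + 1L, ] <-
                    list(txId(tx)[a], txId(tx)[b], ov)
            }
        }
    }
    cd <- txClass(tx) == "cdRNA"
    list(pairs = pairs, flags = flags,
         cdrna_fraction = if (any(cd)) mean(flags[cd]) else NaN)
}

#' Compare transcript 5' ends with a TSS catalogue
#'
#' A transcript is TSS-supported when a same-strand TSS of the catalogue
#' lies within `tss_window` nt of its 5' end.  TSS that support no
#' transcript at all are counted as catalogue-only; the three counts
#' partition the union of the two data sets.
#'
#' @param tx A [TranscriptSet-class].
#' @param tss TSS catalogue data.frame (`replicon`, `strand`,
#'   `position`).
#' @param params A [classifyParams()] list (uses `tss_window`).
#' @return list with `supported` (logical per transcript), `by_class`
#'   (data.frame `class`, `n_both`, `n_only_transcripts`) and
#'   `n_only_tss`.
#' @export
compareWithTss <- function(tx, tss, params = classifyParams()) {
    stopifnot(is(tx, "TranscriptSet"))
    fives <- end5(tx)
    reps <- as.character(seqnames(tx))
    sts <- as.character(strand(tx))
    supported <- logical(length(tx))
    for (key in unique(paste(reps, sts))) {
        sel <- paste(reps, sts) == key
        supported[sel] <- tssNear(fives[sel], tss,
                                  reps[sel][1], sts[sel][1],
                                  params$tss_window)
    }
    tss.used <- logical(nrow(tss))
    for (j in seq_len(nrow(tss))) {
        sel <- reps == tss$replicon[j] & sts == tss$strand[j]
        tss.used[j] <- any(abs(fives[sel] - tss$position[j]) <= params$tss_window)
    }
    cl <- factor(txClass(tx), levels = TX_CLASSES)
    by_class <- data.frame(
        class = levels(cl),
        n_both = as.integer(tapply(supported, cl, sum, default = 0)),
        n_only_transcripts = as.integer(tapply(!supported, cl, sum, default = 0)))
    list(supported = supported, by_class = by_class,
         n_only_tss = sum(!tss.used))
}
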