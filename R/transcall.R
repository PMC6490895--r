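## Transcript boundary calling from strand-specific coverage.
##
## Rule: positions at or above the coverage threshold form expressed
## runs; adjacent runs merge across a gap when the gap is short, or when
## it lies inside an annotated same-strand CDS that both runs touch and
## keeps at least a floor coverage (ORF-bridged gap); merging repeats to
## a fixed point; short leftovers are dropped.

#' Parameters for transcript calling
#'
#' @param min_coverage minimum per-base read count for a position to be
#'   expressed (default 70 reads).
#' @param small_gap gap length in nt tolerated unconditionally between
#'   two expressed runs (default 5).
#' @param orf_gap_floor minimum coverage every position of an ORF-spanned
#'   gap must keep for the gap to be bridged (default 5 reads); must be
#'   below `min_coverage`.
#' @param min_length minimum transcript length in nt (default 50).
#' @param merge_distance after calling, transcripts on one strand closer
#'   than this are joined (default 0 = off).
#' @return list of class `CallerParams`.
#' @export
callerParams <- function(min_coverage = 70, small_gap = 5, orf_gap_floor = 5,
                         min_length = 50, merge_distance = 0) {
    stopifnot(min_coverage >= 0, small_gap >= 0, orf_gap_floor >= 0,
              min_length >= 0, merge_distance >= 0,
              min_coverage > orf_gap_floor)
    structure(list(min_coverage = min_coverage, small_gap = small_gap,
                   orf_gap_floor = orf_gap_floor, min_length = min_length,
                   merge_distance = merge_distance),
              class = "CallerParams")
}

## Segment one numeric coverage vector given same-strand CDS intervals
## (two-column matrix [start, end], 1-based inclusive).  Returns a matrix
## with columns start, end.
segmentTrack <- function(values, cds, params) {
    ## a zero threshold degenerates to "any coverage at all"
    expressed <- if (params$min_coverage > 0) values >= params$min_coverage
                 else values > 0
    if (!any(expressed)) return(cbind(start = integer(0), end = integer(0)))
    r <- rle(expressed)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    s <- starts[r$values]
    e <- ends[r$values]
    if (nrow(cds)) {
        ord <- order(cds[, 1])
        cds <- cds[ord, , drop = FALSE]
    }
    bridged <- function(gs, ge, runL, runR) {
        ## gap [gs, ge] must sit inside one CDS that both flanking runs
        ## intersect, and keep the floor coverage throughout
        if (!nrow(cds)) return(FALSE)
        hit <- cds[, 1] <= gs & cds[, 2] >= ge &          # gap within CDS
               cds[, 1] <= runL[2] & cds[, 2] >= runL[1] & # touches left run
               cds[, 1] <= runR[2] & cds[, 2] >= runR[1]   # touches right run
        any(hit) && min(values[gs:ge]) >= params$orf_gap_floor
    }
    repeat {
        if (length(s) < 2L) break
        merged <- FALSE
        i <- 1L
        while (i < length(s)) {
            glen <- s[i + 1L] - e[i] - 1L
            ok <- glen <= params$small_gap ||
                bridged(e[i] + 1L, s[i + 1L] - 1L, c(s[i], e[i]),
                        c(s[i + 1L], e[i + 1L]))
            if (ok) {
                e[i] <- e[i + 1L]
                s <- s[-(i + 1L)]; e <- e[-(i + 1L)]
                merged <- TRUE
            } else i <- i + 1L
        }
        if (!merged) break
    }
    if (params$merge_distance > 0 && length(s) > 1L) {
        i <- 1L
        while (i < length(s)) {
            if (s[i + 1L] - e[i] - 1L <= params$merge_distance) {
                e[i] <- e[i + 1L]; s <- s[-(i + 1L)]; e <- e[-(i + 1L)]
            } else i <- i + 1L
        }
    }
    keep <- (e - s + 1L) >= params$min_length
    cbind(start = s[keep], end = e[keep])
}

#' Call transcripts from stranded coverage
#'
#' Segments every replicon and strand of `covset` into transcripts:
#' runs of positions with coverage at or above `min_coverage`, merged
#' across gaps that are either at most `small_gap` nt long or are
#' ORF-bridged (gap entirely inside an annotated same-strand CDS that
#' both flanking runs intersect, with every gap position at or above
#' `orf_gap_floor`), merging applied to a fixed point; intervals shorter
#' than `min_length` are discarded.  Transcripts on one strand never
#' overlap.  `meanCoverage` is the arithmetic mean over the final
#' interval.
#'
#' @param covset A [CoverageSet-class].
#' @param genes `GRanges` of CDS features (see [readAnnotation()]); only
#'   same-strand CDSs can bridge a gap.  May be empty.
#' @param params A [callerParams()] list.
#' @return A [TranscriptSet-class] with class labels `"unassigned"`.
#' @examples
#' cov <- numeric(2000); cov[1001:1600] <- 100
#' cs <- CoverageSet(fwd = list(chr = cov), rev = list(chr = numeric(2000)))
#' callTranscripts(cs, GenomicRanges::GRanges(), callerParams())
#' @export
callTranscripts <- function(covset, genes = GenomicRanges::GRanges(),
                            params = callerParams()) {
    stopifnot(is(covset, "CoverageSet"))
    if (length(genes)) {
        unknown <- setdiff(unique(as.character(seqnames(genes))),
                           repliconNames(covset))
        if (length(unknown))
            stop("gene annotation on replicon absent from coverage: ",
                 unknown[1], call. = FALSE)
    }
    pieces <- list()
    for (rep in repliconNames(covset)) {
        for (st in c("+", "-")) {
            v <- trackValues(covset, rep, st)
            g <- genes[as.character(seqnames(genes)) == rep &
                       as.character(strand(genes)) == st]
            cds <- cbind(start(g), end(g))
            seg <- segmentTrack(v, cds, params)
            if (nrow(seg)) {
                mc <- vapply(seq_len(nrow(seg)), function(i)
                    mean(v[seg[i, 1]:seg[i, 2]]), numeric(1))
                pieces[[length(pieces) + 1L]] <- GenomicRanges::GRanges(
                    rep, IRanges::IRanges(seg[, 1], seg[, 2]), strand = st,
                    meanCoverage = mc)
            }
        }
    }
    gr <- if (length(pieces)) suppressWarnings(do.call(c, pieces))
          else GenomicRanges::GRanges(meanCoverage = numeric(0))
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    gr$txId <- if (length(gr)) sprintf("tx%04d", seq_along(gr)) else character(0)
    gr$txClass <- rep("unassigned", length(gr))
    sl <- repliconLengths(covset)
    seqlengths(gr) <- sl[seqlevels(gr)]
    TranscriptSet(gr)
}

#' Transcript count as a function of the coverage threshold
#'
#' Re-runs the caller at each threshold and tabulates how many
#' transcripts are predicted; the count is non-increasing in the
#' threshold.
#'
#' @param covset A [CoverageSet-class].
#' @param genes CDS `GRanges`.
#' @param thresholds numeric vector of minimum-coverage settings.
#' @param params base [callerParams()]; `min_coverage` is overridden.
#' @return data.frame with columns `threshold`, `n_transcripts`.
#' @export
sensitivityScan <- function(covset, genes, thresholds,
                            params = callerParams()) {
    stopifnot(length(thresholds) > 0)
    n <- vapply(thresholds, function(th) {
        p <- params
        p$min_coverage <- th
        if (p$orf_gap_floor >= th) p$orf_gap_floor <- max(0, th - 1e-9)
        length(callTranscripts(covset, genes, p))
    }, numeric(1))
    data.frame(threshold = thresholds, n_transcripts = as.integer(n))
}
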