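## Central S4 containers: stranded per-base coverage, called transcripts,
## and codon-usage tables.

TX_CLASSES <- c("cdRNA", "asRNA", "isRNA", "igRNA", "unassigned")

#' Stranded per-base coverage for a multi-replicon genome
#'
#' Holds one non-negative numeric vector per replicon and strand, each of
#' exactly the replicon length, i.e. the in-memory form of a pair of
#' strand-specific wiggle files.
#'
#' @slot fwd,rev named [S4Vectors::SimpleList]s of numeric vectors, one per
#'   replicon, plus-strand and minus-strand coverage respectively.
#'   Minus-strand values are stored as non-negative magnitudes regardless
#'   of how a wiggle file encoded them.
#' @slot seqlengths named integer vector of replicon lengths.
#'
#' @seealso [CoverageSet()], [readCoverage()], [writeWiggle()]
#' @exportClass CoverageSet
setClass("CoverageSet",
    representation(fwd = "SimpleList", rev = "SimpleList",
                   seqlengths = "integer"))

setValidity("CoverageSet", function(object) {
    sl <- object@seqlengths
    msg <- character()
    if (is.null(names(sl)) || anyDuplicated(names(sl)))
        msg <- c(msg, "seqlengths must be uniquely named")
    for (strand in c("fwd", "rev")) {
        l <- slot(object, strand)
        if (!identical(names(l), names(sl))) {
            msg <- c(msg, sprintf("%s tracks must be named like seqlengths", strand))
            next
        }
        for (rep in names(sl)) {
            v <- l[[rep]]
            if (!is.numeric(v) || length(v) != sl[[rep]])
                msg <- c(msg, sprintf("%s track '%s' must be numeric of length %d",
                                      strand, rep, sl[[rep]]))
            else if (anyNA(v) || any(v < 0))
                msg <- c(msg, sprintf("%s track '%s' has negative or missing values",
                                      strand, rep))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CoverageSet
#'
#' @param fwd,rev named lists of numeric per-base coverage vectors
#'   (plus / minus strand), one element per replicon, in the same order.
#' @return A [CoverageSet-class] object.
#' @examples
#' cs <- CoverageSet(fwd = list(chr = c(0, 5, 5)), rev = list(chr = c(1, 0, 0)))
#' repliconLengths(cs)
#' @export
CoverageSet <- function(fwd, rev) {
    sl <- vapply(fwd, length, integer(1))
    new("CoverageSet",
        fwd = S4Vectors::SimpleList(lapply(fwd, as.numeric)),
        rev = S4Vectors::SimpleList(lapply(rev, as.numeric)),
        seqlengths = sl)
}

#' @describeIn CoverageSet replicon names.
#' @param x A `CoverageSet`.
#' @export
repliconNames <- function(x) names(x@seqlengths)

#' @describeIn CoverageSet named integer replicon lengths.
#' @export
repliconLengths <- function(x) x@seqlengths

#' @describeIn CoverageSet the per-base numeric vector for one replicon
#'   and strand (`"+"` or `"-"`).
#' @param replicon replicon name.
#' @param strand `"+"` or `"-"`.
#' @export
trackValues <- function(x, replicon, strand = c("+", "-")) {
    strand <- match.arg(strand)
    l <- if (strand == "+") x@fwd else x@rev
    if (is.null(l[[replicon]]))
        stop("unknown replicon: ", replicon)
    l[[replicon]]
}

setMethod("show", "CoverageSet", function(object) {
    cat("CoverageSet with", length(object@seqlengths), "replicon(s)\n")
    for (rep in names(object@seqlengths)) {
        cat(sprintf("  %s (%d nt): total fwd %.0f, rev %.0f\n", rep,
                    object@seqlengths[[rep]],
                    sum(object@fwd[[rep]]), sum(object@rev[[rep]])))
    }
})

#' Called transcripts with class labels and annotation-derived metadata
#'
#' A `TranscriptSet` is a [GenomicRanges::GRanges] (1-based, inclusive)
#' with required metadata columns `txId`, `meanCoverage` and `txClass`
#' (one of cdRNA, asRNA, isRNA, igRNA, unassigned).  Classification adds
#' `coveredGenes` (a `CharacterList`), `nOrfs`, `utr5`, `utr3`,
#' `leaderless`, `tssSupported` and `overlapping3p`.
#'
#' @seealso [callTranscripts()], [classifyTranscripts()]
#' @exportClass TranscriptSet
setClass("TranscriptSet", contains = "GRanges")

setValidity("TranscriptSet", function(object) {
    mc <- S4Vectors::mcols(object)
    need <- c("txId", "meanCoverage", "txClass")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    if (length(object)) {
        if (!all(as.character(strand(object)) %in% c("+", "-")))
            return("transcripts must be stranded (+/-)")
        if (!all(mc$txClass %in% TX_CLASSES))
            return(paste("txClass values must be one of:", paste(TX_CLASSES, collapse = ", ")))
        if (anyDuplicated(mc$txId))
            return("txId values must be unique")
        if (any(is.na(mc$meanCoverage)) || any(mc$meanCoverage < 0))
            return("meanCoverage must be non-negative")
    }
    TRUE
})

#' Construct a TranscriptSet
#'
#' @param gr a stranded `GRanges`; metadata columns `txId`, `meanCoverage`,
#'   `txClass` are filled with defaults when absent (generated ids, `NA`
#'   coverage replaced by 0, class `"unassigned"`).
#' @return A [TranscriptSet-class].
#' @export
TranscriptSet <- function(gr = GenomicRanges::GRanges()) {
    mc <- S4Vectors::mcols(gr)
    if (is.null(mc$txId))
        mc$txId <- if (length(gr)) sprintf("tx%04d", seq_along(gr)) else character()
    if (is.null(mc$meanCoverage))
        mc$meanCoverage <- numeric(length(gr))
    if (is.null(mc$txClass))
        mc$txClass <- rep("unassigned", length(gr))
    S4Vectors::mcols(gr) <- mc
    new("TranscriptSet", gr)
}

#' Transcript length in nt
#'
#' Equals the number of covered genomic positions (`width` of the range).
#' @param x A `TranscriptSet`.
#' @export
txLength <- function(x) BiocGenerics::width(x)

#' @describeIn TranscriptSet class label per transcript.
#' @param x A `TranscriptSet`.
#' @export
txClass <- function(x) S4Vectors::mcols(x)$txClass

#' @describeIn TranscriptSet transcript identifiers.
#' @export
txId <- function(x) S4Vectors::mcols(x)$txId

setMethod("show", "TranscriptSet", function(object) {
    cat("TranscriptSet with", length(object), "transcript(s)\n")
    if (length(object)) {
        tab <- table(factor(txClass(object), levels = TX_CLASSES))
        cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
        cat("  length range:", paste(range(BiocGenerics::width(object)), collapse = "-"), "nt\n")
    }
})

#' Codon usage table with relative synonymous adaptiveness
#'
#' Counts of the 64 codons accumulated over a set of coding sequences,
#' plus the per-codon relative adaptiveness: within each synonymous
#' family, codon frequency divided by the frequency of the family's most
#' used codon, so every family maximum scores exactly 1.  Stop codons are
#' counted but excluded from adaptiveness scoring.  Zero-count sense
#' codons receive a 0.5 pseudo-count before normalisation so downstream
#' geometric means stay finite.
#'
#' @slot counts named numeric vector of 64 codon counts.
#' @slot adaptiveness named numeric vector over the 61 sense codons.
#' @seealso [buildCodonUsage()], [preferenceProfile()]
#' @exportClass CodonUsageTable
setClass("CodonUsageTable",
    representation(counts = "numeric", adaptiveness = "numeric"))

setValidity("CodonUsageTable", function(object) {
    if (length(object@counts) != 64L)
        return("counts must cover all 64 codons")
    if (any(object@counts < 0)) return("counts must be non-negative")
    aa <- Biostrings::GENETIC_CODE[names(object@adaptiveness)]
    if (any(aa == "*")) return("stop codons must be excluded from adaptiveness")
    mx <- tapply(object@adaptiveness, aa, max)
    if (any(abs(mx - 1) > 1e-9))
        return("every synonymous family's maximum adaptiveness must be exactly 1")
    TRUE
})

#' @describeIn CodonUsageTable raw codon counts (length 64).
#' @param x A `CodonUsageTable`.
#' @export
codonCounts <- function(x) x@counts

#' @describeIn CodonUsageTable relative adaptiveness over sense codons.
#' @export
relAdaptiveness <- function(x) x@adaptiveness

setMethod("show", "CodonUsageTable", function(object) {
    cat("CodonUsageTable:", format(sum(object@counts), big.mark = ","),
        "codons counted\n")
    top <- sort(object@adaptiveness, decreasing = TRUE)
    cat("  family maxima at 1; lowest adaptiveness",
        sprintf("%.3f (%s)\n", top[length(top)], names(top)[length(top)]))
})
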