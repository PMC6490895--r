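## Summary artifacts: class-by-replicon table with percentages,
## annotation-coverage table, length distributions with medians, operon
## histogram, and read-accounting ratios.

#' Round half-up
#'
#' Commercial rounding (0.5 away from zero), the convention behind
#' integer table percentages, as opposed to R's round-half-even.
#' @param x numeric.
#' @param digits decimal places.
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Lower-middle median
#'
#' For odd n the usual middle value; for even n the lower of the two
#' middle values, so the median of integer lengths is itself an
#' observed integer length.
#' @param x numeric vector.
#' @export
medianLower <- function(x) {
    n <- length(x)
    if (!n) return(NA_real_)
    sort(x)[(n + 1L) %/% 2L]
}

#' Class-by-replicon summary from a count matrix
#'
#' The arithmetic core of [classSummary()]: appends the row sums and
#' the integer percentage column (share of the grand total, rounded
#' half-up).
#'
#' @param counts integer matrix, classes in rows, replicons in columns.
#' @return list with `table` (counts plus `Sum` column), `percent`
#'   (named integer vector per class), `column_sums`, `grand_total`.
#' @examples
#' m <- rbind(cdRNAs = c(1414, 44, 156, 247), asRNAs = c(986, 49, 39, 148),
#'            isRNAs = c(178, 3, 15, 17),    igRNAs = c(157, 11, 12, 20))
#' summarizeClassCounts(m)$percent
#' @export
summarizeClassCounts <- function(counts) {
    stopifnot(is.matrix(counts))
    row.sum <- as.integer(round(rowSums(counts)))
    grand <- as.integer(sum(row.sum))
    pct <- if (grand > 0) as.integer(roundHalfUp(100 * row.sum / grand)) else
        rep(0L, nrow(counts))
    list(table = cbind(counts, Sum = row.sum),
         percent = stats::setNames(pct, rownames(counts)),
         column_sums = c(as.integer(round(colSums(counts))), Sum = grand),
         grand_total = grand)
}

#' Class-by-replicon transcript summary
#'
#' Counts classified transcripts per replicon and class; unassigned
#' transcripts are excluded from the table and reported separately.
#'
#' @param tx a classified [TranscriptSet-class].
#' @param replicons optional replicon order (default: seqlevels).
#' @return as [summarizeClassCounts()], plus `n_unassigned`.
#' @export
classSummary <- function(tx, replicons = NULL) {
    stopifnot(is(tx, "TranscriptSet"))
    if (is.null(replicons)) replicons <- seqlevels(tx)
    cls <- factor(txClass(tx), levels = setdiff(TX_CLASSES, "unassigned"))
    rep <- factor(as.character(seqnames(tx)), levels = replicons)
    keep <- !is.na(cls)
    m <- table(cls[keep], rep[keep])
    counts <- matrix(as.integer(m), nrow = nrow(m),
                     dimnames = dimnames(m))
    out <- summarizeClassCounts(counts)
    out$n_unassigned <- sum(txClass(tx) == "unassigned")
    out
}

#' Annotation-coverage from per-replicon counts
#'
#' Integer detection fractions per replicon (rounded half-up) and the
#' overall fraction computed from the summed numerator and denominator.
#'
#' @param annotated named integer vector of annotated ORFs per replicon.
#' @param detected named integer vector of ORFs observed on cdRNAs.
#' @return list with `table` (annotated, detected, fraction rows) and
#'   `overall_fraction`.
#' @examples
#' annotationCoverageFromCounts(c(Chr = 2992, pHV1 = 89, pHV3 = 383, pHV4 = 636),
#'                              c(Chr = 2453, pHV1 = 66, pHV3 = 216, pHV4 = 357))
#' @export
annotationCoverageFromCounts <- function(annotated, detected) {
    stopifnot(identical(names(annotated), names(detected)),
              all(detected <= annotated))
    frac <- ifelse(annotated > 0,
                   as.integer(roundHalfUp(100 * detected / annotated)), 0L)
    overall <- if (sum(annotated) > 0)
        as.integer(roundHalfUp(100 * sum(detected) / sum(annotated))) else 0L
    list(table = rbind(annotated = c(annotated, Sum = sum(annotated)),
                       detected = c(detected, Sum = sum(detected)),
                       fraction = c(frac, Sum = overall)),
         overall_fraction = overall)
}

#' Fraction of annotated ORFs detected on cdRNAs
#'
#' A gene counts as detected when it appears in the covered genes of at
#' least one cdRNA (each gene at most once, however many transcripts
#' carry it).
#'
#' @param tx a classified [TranscriptSet-class].
#' @param genes CDS `GRanges` with `gene_id`.
#' @return as [annotationCoverageFromCounts()].
#' @export
annotationCoverage <- function(tx, genes) {
    stopifnot(is(tx, "TranscriptSet"))
    reps <- unique(as.character(seqnames(genes)))
    cd <- txClass(tx) == "cdRNA"
    det.ids <- unique(unlist(S4Vectors::mcols(tx)$coveredGenes[cd]))
    ann <- table(factor(as.character(seqnames(genes)), levels = reps))
    det <- table(factor(as.character(seqnames(genes))[genes$gene_id %in% det.ids],
                        levels = reps))
    annotationCoverageFromCounts(stats::setNames(as.integer(ann), reps),
                                 stats::setNames(as.integer(det), reps))
}

#' Length distribution of one transcript class
#'
#' Histogram from 50 nt upward in fixed-width bins, the lower-middle
#' median, and the short/long tail fractions.
#'
#' @param tx A [TranscriptSet-class].
#' @param class one of cdRNA/asRNA/isRNA/igRNA, or `NULL` for all.
#' @param bin_width histogram bin width in nt (default 50).
#' @return list with `histogram` (data.frame `from`, `to`, `count`),
#'   `median`, `n`, `frac_below_300`, `frac_above_300`, `frac_above_500`.
#'   An empty class yields `n = 0` and an `NA` median.
#' @export
lengthStats <- function(tx, class = NULL, bin_width = 50) {
    stopifnot(is(tx, "TranscriptSet"))
    len <- BiocGenerics::width(tx)
    if (!is.null(class)) len <- len[txClass(tx) == class]
    if (!length(len))
        return(list(histogram = data.frame(from = numeric(0), to = numeric(0),
                                           count = integer(0)),
                    median = NA_real_, n = 0L, frac_below_300 = NA_real_,
                    frac_above_300 = NA_real_, frac_above_500 = NA_real_))
    lo <- 50
    hi <- max(len, lo + bin_width)
    breaks <- seq(lo, hi + bin_width, by = bin_width)
    cut.idx <- findInterval(pmax(len, lo), breaks, rightmost.closed = FALSE)
    counts <- tabulate(cut.idx, nbins = length(breaks) - 1L)
    list(histogram = data.frame(from = breaks[-length(breaks)],
                                to = breaks[-1], count = counts),
         median = medianLower(len), n = length(len),
         frac_below_300 = mean(len < 300),
         frac_above_300 = mean(len > 300),
         frac_above_500 = mean(len > 500))
}

#' Operon-size histogram of protein-coding transcripts
#'
#' @param tx a classified [TranscriptSet-class] with `nOrfs` set.
#' @return list with `histogram` (counts of cdRNAs by ORF number),
#'   `monocistronic_fraction`, `n_gt7` (cdRNAs with more than 7 ORFs),
#'   `n_cdrna`.
#' @export
operonHistogram <- function(tx) {
    stopifnot(is(tx, "TranscriptSet"))
    n <- countOrfs(tx)
    n <- n[!is.na(n)]
    if (!length(n))
        return(list(histogram = integer(0), monocistronic_fraction = NaN,
                    n_gt7 = 0L, n_cdrna = 0L))
    h <- table(factor(n, levels = seq_len(max(n))))
    list(histogram = stats::setNames(as.integer(h), names(h)),
         monocistronic_fraction = mean(n == 1),
         n_gt7 = sum(n > 7), n_cdrna = length(n))
}

#' Read-accounting percentage
#'
#' `100 * mapped / total`, rounded half-up to two decimals — the form in
#' which mapping statistics are reported.
#'
#' @param mapped,total non-negative counts, `mapped <= total`,
#'   `total > 0`.
#' @return percentage with two decimals.
#' @examples
#' readAccounting(40712641, 58437942)  # 69.67
#' @export
readAccounting <- function(mapped, total) {
    if (total <= 0) stop("total must be positive", call. = FALSE)
    stopifnot(mapped >= 0, mapped <= total)
    roundHalfUp(100 * mapped / total, 2)
}

#' Run the analysis pipeline on a dataset
#'
#' Calls transcripts from the coverage, classifies them, flags 3'
#' overlaps, compares with the TSS catalogue when present, and collects
#' the summary tables.  This is the programmatic equivalent of the
#' command-line `run` subcommand.
#'
#' @param covset A [CoverageSet-class].
#' @param genes CDS `GRanges`.
#' @param genome optional `DNAStringSet`; enables the coding screen.
#' @param tss optional TSS catalogue data.frame.
#' @param caller A [callerParams()] list.
#' @param classifier A [classifyParams()] list.
#' @param screen A [screenParams()] list, or `NULL` to skip the
#'   non-coding screen.
#' @return list with `transcripts` (A [TranscriptSet-class]),
#'   `class_summary`, `annotation_coverage`, `operons`, `overlaps3p`,
#'   `tss_comparison` (or `NULL`), `screen` (or `NULL`).
#' @export
runPipeline <- function(covset, genes, genome = NULL, tss = NULL,
                        caller = callerParams(),
                        classifier = classifyParams(),
                        screen = NULL) {
    tx <- callTranscripts(covset, genes, caller)
    tx <- classifyTranscripts(tx, genes, classifier, tss)
    ov <- find3primeOverlaps(tx)
    tx$overlapping3p <- ov$flags
    scr <- NULL
    if (!is.null(screen) && !is.null(genome)) {
        usage <- buildCodonUsage(extractCds(genome, genes))
        scr <- screenNoncoding(tx, genome, genes, usage, screen)
    }
    list(transcripts = tx,
         class_summary = classSummary(tx),
         annotation_coverage = annotationCoverage(tx, genes),
         operons = operonHistogram(tx),
         overlaps3p = ov,
         tss_comparison = if (!is.null(tss))
             compareWithTss(tx, tss, classifier) else NULL,
         screen = scr)
}

#' Extract in-frame CDS sequences from a genome
#'
#' @param genome `DNAStringSet`.
#' @param genes CDS `GRanges` (minus-strand features are
#'   reverse-complemented).
#' @return character vector of coding sequences, named by `gene_id`.
#' @export
extractCds <- function(genome, genes) {
    out <- vapply(seq_along(genes), function(i) {
        senseSeq(genome, as.character(seqnames(genes)[i]),
                 as.character(strand(genes)[i]),
                 start(genes)[i], end(genes)[i])
    }, character(1))
    stats::setNames(out, genes$gene_id)
}
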