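## Comparison of called transcripts against the simulator's planted
## ground truth: boundary-accurate recovery, class agreement, and the
## fraction of calls touching no truth transcript.

#' Match called transcripts against planted ground truth
#'
#' A truth transcript is recovered when some call on the same replicon
#' and strand has both boundaries within `tol` nt of it; its class is
#' correct when such a call carries the planted class label.  A call is
#' spurious when it intersects no truth transcript on its strand.
#'
#' @param tx A [TranscriptSet-class] of calls (classified or not).
#' @param truth `GRanges` from [simulateTranscripts()] (metadata
#'   `txClass`, `expression`).
#' @param tol boundary tolerance in nt (default 20).
#' @param min_expression restrict the recovery denominator to truth
#'   transcripts with at least this planted mean coverage (default 0 =
#'   all).
#' @return list with `recovered`, `class_correct` (logicals per truth
#'   transcript), `spurious` (logical per call), and the summary rates
#'   `recovery_rate` (over the restricted denominator),
#'   `class_accuracy` (over recovered transcripts) and `fdr`.
#' @export
matchTruth <- function(tx, truth, tol = 20, min_expression = 0) {
    stopifnot(is(tx, "TranscriptSet"))
    reps <- as.character(seqnames(tx))
    sts <- as.character(strand(tx))
    n <- length(truth)
    recovered <- cls.ok <- logical(n)
    has.class <- !is.null(S4Vectors::mcols(tx)$txClass) &&
        !all(txClass(tx) == "unassigned")
    for (i in seq_len(n)) {
        sel <- reps == as.character(seqnames(truth)[i]) &
               sts == as.character(strand(truth)[i]) &
               abs(start(tx) - start(truth)[i]) <= tol &
               abs(end(tx) - end(truth)[i]) <= tol
        recovered[i] <- any(sel)
        if (any(sel) && has.class)
            cls.ok[i] <- any(txClass(tx)[sel] == truth$txClass[i])
    }
    spurious <- !IRanges::overlapsAny(tx, truth, ignore.strand = FALSE)
    denom <- truth$expression >= min_expression
    list(recovered = recovered, class_correct = cls.ok, spurious = spurious,
         recovery_rate = if (any(denom)) mean(recovered[denom]) else NaN,
         class_accuracy = if (has.class && any(recovered))
             mean(cls.ok[recovered]) else NaN,
         fdr = if (length(tx)) mean(spurious) else NaN)
}
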