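## Coding-potential screen for "non-coding" transcripts: three-frame ORF
## finding (ATG/GTG starts, length floor), translation, isoelectric
## point, codon-usage tables with relative synonymous adaptiveness, and
## CAI-style codon-preference profiling against a seeded
## composition-matched null.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codonsOf <- function(seq, from = 1L) {
    ## split seq[from..] into complete codons
    n <- nchar(seq)
    last <- from + ((n - from + 1L) %/% 3L) * 3L - 1L
    if (last < from + 2L) return(character(0))
    starts <- seq.int(from, last, by = 3L)
    substring(seq, starts, starts + 2L)
}

isStopLike <- function(codons) codons %in% STOP_CODONS | grepl("N", codons)

#' Find candidate ORFs in a transcript sequence
#'
#' Scans all three reading frames of the sense strand for maximal open
#' reading frames: within each stop-bounded region, the ORF runs from
#' the first in-frame start codon to the next in-frame stop (nested
#' later starts are absorbed).  An ORF that reaches the end of the
#' sequence without a stop is reported with `open_ended = TRUE`.  Codons
#' containing N count as stops.
#'
#' @param seq character scalar, the transcript's sense strand 5' to 3'
#'   (A/C/G/T/N).
#' @param min_codons minimum ORF length in codons, start codon included,
#'   stop excluded (default 40).
#' @param starts allowed start codons (default ATG and GTG).
#' @return data.frame with `frame` (0/1/2), `start`/`end` (1-based nt
#'   offsets within `seq`; `end` is the last nt of the stop codon, or of
#'   the last complete codon for open-ended ORFs), `n_codons`,
#'   `open_ended`.
#' @examples
#' findOrfs(paste0("ATG", strrep("GAC", 39), "TAA"), min_codons = 40)
#' @export
findOrfs <- function(seq, min_codons = 40, starts = c("ATG", "GTG")) {
    seq <- toupper(seq)
    out <- list()
    if (nchar(seq) < 3L)
        return(data.frame(frame = integer(0), start = integer(0),
                          end = integer(0), n_codons = integer(0),
                          open_ended = logical(0)))
    for (frame in 0:2) {
        cod <- codonsOf(seq, frame + 1L)
        if (!length(cod)) next
        stop.at <- isStopLike(cod)
        is.start <- cod %in% starts
        i <- 1L
        nc <- length(cod)
        while (i <= nc) {
            if (is.start[i]) {
                j <- i
                while (j <= nc && !stop.at[j]) j <- j + 1L
                open <- j > nc
                ncod <- (if (open) nc else j - 1L) - i + 1L
                if (ncod >= min_codons) {
                    nt.start <- frame + 1L + (i - 1L) * 3L
                    nt.end <- frame + (if (open) nc else j) * 3L
                    out[[length(out) + 1L]] <- data.frame(
                        frame = frame, start = nt.start, end = nt.end,
                        n_codons = ncod, open_ended = open)
                }
                i <- if (open) nc + 1L else j + 1L
            } else if (stop.at[i]) {
                i <- i + 1L
            } else i <- i + 1L
        }
    }
    if (!length(out))
        return(data.frame(frame = integer(0), start = integer(0),
                          end = integer(0), n_codons = integer(0),
                          open_ended = logical(0)))
    do.call(rbind, out)
}

#' Translate an ORF nucleotide sequence
#'
#' Standard genetic code; an initiator GTG (or TTG) is translated as M.
#' A trailing stop codon is allowed and dropped; an internal stop codon,
#' or a codon containing N, is a malformed-ORF error.
#'
#' @param nt character scalar, length divisible by 3.
#' @return amino-acid string.
#' @examples
#' translateOrf("ATGGATGAC")  # "MDD"
#' translateOrf("GTGGAA")     # "ME"
#' @export
translateOrf <- function(nt) {
    nt <- toupper(nt)
    if (nchar(nt) %% 3L != 0L)
        stop("ORF length must be divisible by 3", call. = FALSE)
    cod <- codonsOf(nt)
    if (!length(cod)) return("")
    if (any(grepl("N", cod)))
        stop("codon containing N: ORF truncated at an ambiguous base",
             call. = FALSE)
    aa <- unname(Biostrings::GENETIC_CODE[cod])
    if (anyNA(aa))
        stop("invalid codon: ", cod[is.na(aa)][1], call. = FALSE)
    if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
    if (any(aa == "*"))
        stop("internal stop codon at position ", which(aa == "*")[1],
             call. = FALSE)
    if (length(aa)) aa[1] <- "M"      # initiator rule (GTG/TTG start -> Met)
    paste(aa, collapse = "")
}

#' EMBOSS pK values for ionizable groups
#'
#' The default acid dissociation constants used by [isoelectricPoint()]:
#' N-terminus 8.6, C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8,
#' R 12.5, Y 10.1.  Any named vector with these entries can be swapped
#' in (e.g. a Bjellqvist set).
#' @export
PK_EMBOSS <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
               H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

netCharge <- function(counts, nterm, cterm, pH, pK) {
    pos <- c(Nterm = nterm, K = counts[["K"]], R = counts[["R"]],
             H = counts[["H"]])
    neg <- c(Cterm = cterm, D = counts[["D"]], E = counts[["E"]],
             C = counts[["C"]], Y = counts[["Y"]])
    sum(pos / (1 + 10^(pH - pK[names(pos)]))) -
        sum(neg / (1 + 10^(pK[names(neg)] - pH)))
}

#' Isoelectric point of a protein
#'
#' The pH at which the Henderson-Hasselbalch net charge over the
#' ionizable groups (termini plus D, E, C, Y, H, K, R side chains) is
#' zero, found by bisection on pH 0..14.
#'
#' @param protein amino-acid string (standard one-letter alphabet).
#' @param pK named pK table; default [PK_EMBOSS].
#' @param tol bisection tolerance in pH units (default 1e-4).
#' @return pI in pH units.
#' @examples
#' isoelectricPoint("DDDDDD") < isoelectricPoint("KKKKKK")
#' @export
isoelectricPoint <- function(protein, pK = PK_EMBOSS, tol = 1e-4) {
    if (!nzchar(protein)) stop("empty protein", call. = FALSE)
    aa <- strsplit(toupper(protein), "")[[1]]
    valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    if (!all(aa %in% valid))
        stop("unknown residue: ", setdiff(aa, valid)[1], call. = FALSE)
    counts <- table(factor(aa, levels = valid))
    lo <- 0; hi <- 14
    while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (netCharge(counts, 1, 1, mid, pK) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

#' Build a codon usage table from coding sequences
#'
#' Accumulates in-frame codon counts over all CDSs (stop codons counted
#' but excluded from scoring) and computes relative synonymous
#' adaptiveness: within each amino-acid family, frequency divided by the
#' family maximum, so every family's top codon scores exactly 1.
#' Zero-count sense codons get a 0.5 pseudo-count before normalisation.
#' CDSs whose length is not divisible by 3 are skipped with a warning.
#'
#' @param cds a `DNAStringSet` or character vector of in-frame coding
#'   sequences (start codon first, stop codon last).
#' @param max_aa optional maximum protein length in amino acids; CDSs
#'   coding for longer proteins are excluded (used to build the
#'   small-protein table variant).
#' @return A [CodonUsageTable-class].
#' @export
buildCodonUsage <- function(cds, max_aa = NULL) {
    if (is(cds, "DNAStringSet")) cds <- as.character(cds)
    cds <- toupper(cds)
    bad <- nchar(cds) %% 3L != 0L
    if (any(bad)) {
        warning(sum(bad), " CDS(s) with length not divisible by 3 skipped")
        cds <- cds[!bad]
    }
    if (!is.null(max_aa)) cds <- cds[nchar(cds) / 3 - 1 <= max_aa]
    if (!length(cds)) stop("no usable CDS", call. = FALSE)
    all.codons <- names(Biostrings::GENETIC_CODE)
    counts <- setNames(numeric(64), all.codons)
    tab <- table(unlist(lapply(cds, codonsOf), use.names = FALSE))
    tab <- tab[names(tab) %in% all.codons]
    counts[names(tab)] <- as.numeric(tab)
    sense <- all.codons[Biostrings::GENETIC_CODE != "*"]
    eff <- counts[sense]
    eff[eff == 0] <- 0.5
    aa <- Biostrings::GENETIC_CODE[sense]
    fam.max <- tapply(eff, aa, max)
    adapt <- eff / fam.max[aa]
    new("CodonUsageTable", counts = counts,
        adaptiveness = setNames(as.numeric(adapt), sense))
}

geomean <- function(x) exp(mean(log(x)))

#' Windowed codon-preference profile and score of an ORF
#'
#' Per-codon scores are the table's relative adaptiveness values; the
#' profile at codon i is the geometric mean over a window centred at i
#' (shrunk at the edges), and the overall `preference_score` is the
#' geometric mean over all codons (a CAI).  A trailing stop codon is
#' ignored.
#'
#' @param orf_nt in-frame ORF nucleotide sequence.
#' @param table A [CodonUsageTable-class].
#' @param window window length in codons (default 25).
#' @return list with `profile` (numeric, one value per scored codon) and
#'   `preference_score`.
#' @export
preferenceProfile <- function(orf_nt, table, window = 25) {
    cod <- codonsOf(toupper(orf_nt))
    if (length(cod) && cod[length(cod)] %in% STOP_CODONS)
        cod <- cod[-length(cod)]
    if (!length(cod)) stop("no codons to score", call. = FALSE)
    sc <- relAdaptiveness(table)[cod]
    if (anyNA(sc))
        stop("unscorable codon (stop or ambiguous) inside ORF: ",
             cod[is.na(sc)][1], call. = FALSE)
    h <- window %/% 2
    n <- length(sc)
    logs <- log(sc)
    cums <- cumsum(c(0, logs))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    profile <- exp((cums[hi + 1L] - cums[lo]) / (hi - lo + 1L))
    list(profile = profile, preference_score = geomean(sc))
}

#' Null threshold for "exhibits the codon usage"
#'
#' Generates `n` random ORFs of `n_codons` codons from the genome's
#' mononucleotide composition (stop codons excluded, so every draw is a
#' scoreable sense codon), scores each with the table's CAI, and returns
#' the chosen percentile.  An ORF whose `preference_score` exceeds this
#' threshold is called consistent with the genome's codon usage.
#'
#' @param table A [CodonUsageTable-class].
#' @param n_codons ORF length in codons.
#' @param composition named base frequencies (A/C/G/T), e.g. from
#'   [baseComposition()].
#' @param n null sample size (default 1000).
#' @param percentile null quantile (default 0.95).
#' @param seed RNG seed for the null draw.
#' @return numeric threshold.
#' @export
nullPreferenceThreshold <- function(table, n_codons, composition,
                                    n = 1000, percentile = 0.95, seed = 1) {
    sense <- names(relAdaptiveness(table))
    p <- codonProbsFromComposition(composition)[sense]
    p <- p / sum(p)
    set.seed(as.integer(seed) %% .Machine$integer.max)
    draws <- matrix(sample(log(relAdaptiveness(table)), n * n_codons,
                           replace = TRUE, prob = p),
                    nrow = n)
    unname(stats::quantile(exp(rowMeans(draws)), percentile))
}

codonProbsFromComposition <- function(composition) {
    composition <- composition[c("A", "C", "G", "T")] /
        sum(composition[c("A", "C", "G", "T")])
    all.codons <- names(Biostrings::GENETIC_CODE)
    b <- function(k) substring(all.codons, k, k)
    setNames(composition[b(1)] * composition[b(2)] * composition[b(3)],
             all.codons)
}

#' Mononucleotide composition of a genome
#' @param seqs `DNAStringSet` or character vector.
#' @return named frequencies of A, C, G, T (N ignored).
#' @export
baseComposition <- function(seqs) {
    if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
    f <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
    f / sum(f)
}

#' Rise-and-decline test on a preference profile
#'
#' Flags profiles that cross the threshold upward and later downward
#' strictly inside the scored interval, i.e. both flanks are below the
#' threshold and an above-threshold run sits in between (the signature
#' of an internal mini-ORF rather than a frame that scores high
#' throughout).  The peak interval is the longest above-threshold run.
#'
#' @param profile numeric profile from [preferenceProfile()].
#' @param threshold numeric cutoff.
#' @return list with `flag` and `peak` (integer `c(from, to)` codon
#'   indices, or `NULL`).
#' @export
detectRiseDecline <- function(profile, threshold) {
    above <- profile > threshold
    if (!any(above)) return(list(flag = FALSE, peak = NULL))
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    peak <- c(starts[best], ends[best])
    interior <- any(r$values & starts > 1L & ends < length(profile))
    list(flag = interior, peak = peak)
}

#' Parameters for the non-coding screen
#'
#' @param min_codons ORF length floor (default 40 codons).
#' @param max_pi isoelectric-point ceiling (default 6.0).
#' @param starts allowed start codons.
#' @param window profile window in codons (default 25).
#' @param null_n,null_percentile,null_seed null distribution settings for
#'   [nullPreferenceThreshold()].
#' @return list of class `ScreenParams`.
#' @export
screenParams <- function(min_codons = 40, max_pi = 6.0,
                         starts = c("ATG", "GTG"), window = 25,
                         null_n = 1000, null_percentile = 0.95,
                         null_seed = 1) {
    structure(list(min_codons = min_codons, max_pi = max_pi,
                   starts = starts, window = window, null_n = null_n,
                   null_percentile = null_percentile,
                   null_seed = null_seed),
              class = "ScreenParams")
}

## sense-strand sequence of a stranded range
senseSeq <- function(genome, replicon, st, from, to) {
    s <- Biostrings::subseq(genome[[replicon]], from, to)
    if (st == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
}

#' Screen non-coding transcripts for overlooked small proteins
#'
#' Runs the filter chain on every asRNA, isRNA and igRNA: three-frame
#' ORF finding (ATG/GTG starts), length floor, translation, acidic-pI
#' filter, and the codon-usage preference filter against a
#' length-matched composition null.  For isRNAs the reading frame of the
#' host gene is excluded (it trivially exhibits the genomic codon usage)
#' and a candidate additionally needs a rise-and-decline of the windowed
#' profile inside the transcript.
#'
#' @param tx a classified [TranscriptSet-class].
#' @param genome `DNAStringSet` of replicon sequences.
#' @param genes CDS `GRanges` (used to determine isRNA host frames).
#' @param table A [CodonUsageTable-class].
#' @param params A [screenParams()] list.
#' @return list with `candidates` (data.frame: transcript, class, frame,
#'   offsets, n_codons, protein, pI, preference_score, rise_decline,
#'   passes) and `tally` (data.frame of survivors per filter stage, in
#'   chain order).
#' @export
screenNoncoding <- function(tx, genome, genes, table,
                            params = screenParams()) {
    stopifnot(is(tx, "TranscriptSet"))
    sel <- which(txClass(tx) %in% c("asRNA", "isRNA", "igRNA"))
    cand <- list()
    tally <- c(orfs_found = 0L, length_pass = 0L, pi_pass = 0L,
               preference_pass = 0L)
    comp <- baseComposition(genome)
    thr.cache <- new.env(parent = emptyenv())
    thr <- function(L) {
        key <- as.character(L)
        if (is.null(thr.cache[[key]]))
            thr.cache[[key]] <- nullPreferenceThreshold(
                table, L, comp, n = params$null_n,
                percentile = params$null_percentile,
                seed = params$null_seed + L)
        thr.cache[[key]]
    }
    for (i in sel) {
        rep <- as.character(seqnames(tx)[i])
        st <- as.character(strand(tx)[i])
        seq <- senseSeq(genome, rep, st, start(tx)[i], end(tx)[i])
        orfs <- findOrfs(seq, min_codons = 1, starts = params$starts)
        is.is <- txClass(tx)[i] == "isRNA"
        if (is.is && nrow(orfs)) {
            hostf <- hostFrame(tx[i], genes)
            if (!is.na(hostf)) orfs <- orfs[orfs$frame != hostf, , drop = FALSE]
        }
        tally["orfs_found"] <- tally["orfs_found"] + nrow(orfs)
        if (!nrow(orfs)) next
        orfs <- orfs[orfs$n_codons >= params$min_codons, , drop = FALSE]
        tally["length_pass"] <- tally["length_pass"] + nrow(orfs)
        for (k in seq_len(nrow(orfs))) {
            o <- orfs[k, ]
            nt <- substring(seq, o$start, o$end)
            prot <- tryCatch(translateOrf(nt), error = function(e) NA_character_)
            if (is.na(prot) || !nzchar(prot)) next
            pi <- isoelectricPoint(prot)
            pi.ok <- pi <= params$max_pi
            if (pi.ok) tally["pi_pass"] <- tally["pi_pass"] + 1L
            pp <- preferenceProfile(nt, table, window = params$window)
            cut <- thr(o$n_codons)
            pref.ok <- pp$preference_score > cut
            rd <- detectRiseDecline(pp$profile, cut)
            pass <- pi.ok && pref.ok && (!is.is || rd$flag)
            if (pi.ok && pref.ok && (!is.is || rd$flag))
                tally["preference_pass"] <- tally["preference_pass"] + 1L
            cand[[length(cand) + 1L]] <- data.frame(
                transcript_id = txId(tx)[i], class = txClass(tx)[i],
                frame = o$frame, start = o$start, end = o$end,
                n_codons = o$n_codons, open_ended = o$open_ended,
                protein = prot, pI = pi,
                preference_score = pp$preference_score,
                null_threshold = cut,
                rise_decline = rd$flag,
                pass_pi = pi.ok, pass_preference = pref.ok, passes = pass,
                stringsAsFactors = FALSE)
        }
    }
    candidates <- if (length(cand)) do.call(rbind, cand) else
        data.frame(transcript_id = character(), class = character(),
                   frame = integer(), start = integer(), end = integer(),
                   n_codons = integer(), open_ended = logical(),
                   protein = character(), pI = numeric(),
                   preference_score = numeric(), null_threshold = numeric(),
                   rise_decline = logical(), pass_pi = logical(),
                   pass_preference = logical(), passes = logical())
    list(candidates = candidates,
         tally = data.frame(stage = names(tally),
                            n_surviving = as.integer(tally)))
}

## reading frame (0/1/2, sense coordinates of the transcript) of the
## same-strand gene hosting an isRNA; NA when no host gene is found
hostFrame <- function(t1, genes) {
    host <- genes[as.character(seqnames(genes)) == as.character(seqnames(t1)) &
                  as.character(strand(genes)) == as.character(strand(t1)) &
                  start(genes) <= start(t1) + 10 & end(genes) >= end(t1) - 10]
    if (!length(host)) return(NA_integer_)
    g <- host[1]
    if (as.character(strand(t1)) == "+")
        (start(g) - start(t1)) %% 3L
    else
        (end(t1) - end(g)) %% 3L
}
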