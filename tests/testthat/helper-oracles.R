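## Independent brute-force oracles and shared fixtures.  The oracles are
## literal transcriptions of the rules, written position-by-position with
## no shortcuts, so they share no code with the package implementations.

## --- brute-force coverage segmentation -------------------------------
## mark expressed positions, then repeatedly fill any gap that the merge
## rules allow, until nothing changes; finally enumerate blocks.
bruteBlocks <- function(mask) {
    out <- NULL
    i <- 1L
    n <- length(mask)
    while (i <= n) {
        if (mask[i]) {
            j <- i
            while (j < n && mask[j + 1L]) j <- j + 1L
            out <- rbind(out, c(i, j))
            i <- j + 1L
        } else i <- i + 1L
    }
    if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

bruteSegment <- function(values, cds, p) {
    mask <- if (p$min_coverage > 0) values >= p$min_coverage else values > 0
    repeat {
        blocks <- bruteBlocks(mask)
        if (nrow(blocks) < 2L) break
        changed <- FALSE
        for (k in seq_len(nrow(blocks) - 1L)) {
            gs <- blocks[k, 2] + 1L
            ge <- blocks[k + 1L, 1] - 1L
            ok <- (ge - gs + 1L) <= p$small_gap
            if (!ok && nrow(cds)) {
                for (j in seq_len(nrow(cds))) {
                    inside <- cds[j, 1] <= gs && cds[j, 2] >= ge
                    left <- max(cds[j, 1], blocks[k, 1]) <= min(cds[j, 2], blocks[k, 2])
                    right <- max(cds[j, 1], blocks[k + 1L, 1]) <=
                             min(cds[j, 2], blocks[k + 1L, 2])
                    if (inside && left && right &&
                        all(values[gs:ge] >= p$orf_gap_floor)) {
                        ok <- TRUE
                        break
                    }
                }
            }
            if (ok) {
                mask[gs:ge] <- TRUE
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    b <- bruteBlocks(mask)
    b[b[, 2] - b[, 1] + 1L >= p$min_length, , drop = FALSE]
}

## random sparse coverage track plus a few random CDS intervals
randomTrackCase <- function(seed, n = 2000L) {
    set.seed(seed)
    v <- numeric(n)
    for (k in seq_len(sample(3:8, 1))) {
        from <- sample(n - 100L, 1L)
        len <- sample(30:400, 1L)
        to <- min(n, from + len - 1L)
        v[from:to] <- v[from:to] + stats::rpois(to - from + 1L, sample(c(10, 50, 90, 150), 1))
    }
    ncds <- sample(0:3, 1L)
    cds <- if (ncds) {
        t(vapply(seq_len(ncds), function(i) {
            from <- sample(n - 300L, 1L)
            c(from, min(n, from + sample(150:900, 1L)))
        }, numeric(2)))
    } else matrix(integer(0), ncol = 2)
    list(values = v, cds = cds)
}

## --- brute-force ORF scan --------------------------------------------
## test every in-frame position; keep starts not preceded by another
## start in the same stop-bounded region; extend to the next stop.
bruteOrfs <- function(seq, min_codons = 40, starts = c("ATG", "GTG")) {
    seq <- toupper(seq)
    n <- nchar(seq)
    codon <- function(p) substr(seq, p, p + 2L)
    isStop <- function(cd) cd %in% c("TAA", "TAG", "TGA") || grepl("N", cd)
    res <- NULL
    for (f in 0:2) {
        if (f + 3L > n) next
        for (p in seq.int(f + 1L, n - 2L, by = 3L)) {
            if (!(codon(p) %in% starts)) next
            maximal <- TRUE
            q <- p - 3L
            while (q >= f + 1L) {
                cq <- codon(q)
                if (isStop(cq)) break
                if (cq %in% starts) { maximal <- FALSE; break }
                q <- q - 3L
            }
            if (!maximal) next
            q <- p
            nc <- 0L
            open <- TRUE
            endnt <- NA_integer_
            while (q <= n - 2L) {
                cq <- codon(q)
                if (isStop(cq)) { open <- FALSE; endnt <- q + 2L; break }
                nc <- nc + 1L
                q <- q + 3L
            }
            if (open) endnt <- q - 1L
            if (nc >= min_codons)
                res <- rbind(res, data.frame(frame = f, start = p, end = endnt,
                                             n_codons = nc, open_ended = open))
        }
    }
    if (is.null(res))
        data.frame(frame = integer(0), start = integer(0), end = integer(0),
                   n_codons = integer(0), open_ended = logical(0))
    else res[order(res$frame, res$start), ]
}

randomDna <- function(n, gc = 0.5) {
    paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
}

## stop-free random ORF body for translation tests
randomOrfSeq <- function(n_codons) {
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE)), collapse = "")
}

randomPeptide <- function(n) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
          collapse = "")
}

## net charge recomputed independently for the pI root condition
referenceNetCharge <- function(protein, pH, pK = PK_EMBOSS) {
    aa <- strsplit(protein, "")[[1]]
    cnt <- function(x) sum(aa == x)
    pos <- sum(1 / (1 + 10^(pH - pK["Nterm"])),
               cnt("K") / (1 + 10^(pH - pK["K"])),
               cnt("R") / (1 + 10^(pH - pK["R"])),
               cnt("H") / (1 + 10^(pH - pK["H"])))
    neg <- sum(1 / (1 + 10^(pK["Cterm"] - pH)),
               cnt("D") / (1 + 10^(pK["D"] - pH)),
               cnt("E") / (1 + 10^(pK["E"] - pH)),
               cnt("C") / (1 + 10^(pK["C"] - pH)),
               cnt("Y") / (1 + 10^(pK["Y"] - pH)))
    pos - neg
}

## TranscriptSet builder for hand-laid geometries
makeTx <- function(replicon, start, end, strand, seqlen = 10000L,
                   meanCoverage = 100) {
    gr <- GenomicRanges::GRanges(replicon, IRanges::IRanges(start, end),
                                 strand = strand,
                                 seqlengths = stats::setNames(
                                     rep(seqlen, length.out = length(unique(replicon))),
                                     unique(replicon)))
    gr$meanCoverage <- rep(meanCoverage, length.out = length(gr))
    TranscriptSet(gr)
}

makeGenes <- function(replicon, start, end, strand, ids = NULL,
                      seqlen = 10000L) {
    gr <- GenomicRanges::GRanges(replicon, IRanges::IRanges(start, end),
                                 strand = strand,
                                 seqlengths = stats::setNames(
                                     rep(seqlen, length.out = length(unique(replicon))),
                                     unique(replicon)))
    gr$gene_id <- if (is.null(ids)) sprintf("g%02d", seq_along(gr)) else ids
    gr$product <- NA_character_
    gr$is_small <- BiocGenerics::width(gr) / 3 - 1 <= 100
    gr
}

## shared simulated datasets at study defaults, built once per session
simCache <- local({
    cache <- list()
    function(seed) {
        key <- as.character(seed)
        if (is.null(cache[[key]]))
            cache[[key]] <<- simulateDataset(simulationParams(seed = seed))
        cache[[key]]
    }
})
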