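test_that("class cascade handles the definitional geometries", {
    genes <- makeGenes("chr", c(1001, 3001), c(1600, 3900), c("+", "+"))
    ## transcript exactly spanning a CDS on its own strand -> cdRNA
    tx <- makeTx("chr", 1001, 1600, "+")
    cl <- classifyTranscripts(tx, genes)
    expect_identical(txClass(cl), "cdRNA")
    expect_identical(as.list(cl$coveredGenes)[[1]], "g01")
    expect_identical(countOrfs(cl), 1L)

    ## 150-nt transcript wholly antisense to a CDS -> asRNA
    cl <- classifyTranscripts(makeTx("chr", 1200, 1349, "-"), genes)
    expect_identical(txClass(cl), "asRNA")

    ## gene-free region -> igRNA
    cl <- classifyTranscripts(makeTx("chr", 2200, 2350, "+"), genes)
    expect_identical(txClass(cl), "igRNA")

    ## strictly inside a same-strand CDS, covering 40% of it -> isRNA
    cl <- classifyTranscripts(makeTx("chr", 3100, 3459, "+"), genes)
    expect_identical(txClass(cl), "isRNA")

    ## partial sense overlap without coverage or containment -> unassigned
    cl <- classifyTranscripts(makeTx("chr", 3700, 4200, "+"), genes)
    expect_identical(txClass(cl), "unassigned")

    ## opposite-strand overlap below as_min_overlap stays unassigned
    cl <- classifyTranscripts(makeTx("chr", 995, 1005, "-"), genes,
                              classifyParams(as_min_overlap = 10))
    expect_identical(txClass(cl), "unassigned")
})

test_that("sense wins over antisense and the TSS rescue reclassifies weak cdRNAs", {
    ## a transcript covering one gene and antisense to another is coding
    genes <- makeGenes("chr", c(1001, 1701), c(1600, 2300), c("+", "-"))
    cl <- classifyTranscripts(makeTx("chr", 1001, 1800, "+"), genes)
    expect_identical(txClass(cl), "cdRNA")

    ## short call over a long, weakly covered ORF: an internal sense RNA
    ## without TSS evidence, rescued to cdRNA when the ORF's own 5' end
    ## has TSS support
    genes <- makeGenes("chr", 1001, 2800, "+")
    short <- makeTx("chr", 1001, 1400, "+")
    expect_identical(txClass(classifyTranscripts(short, genes)), "isRNA")
    tss <- data.frame(replicon = "chr", strand = "+", position = 1005L)
    cl <- classifyTranscripts(short, genes, classifyParams(), tss = tss)
    expect_identical(txClass(cl), "cdRNA")
    ## no rescue when the TSS sits away from the ORF 5' end
    tss$position <- 2200L
    expect_identical(txClass(classifyTranscripts(short, genes,
                                                 classifyParams(), tss)),
                     "isRNA")
})

test_that("UTR arithmetic is strand-aware and clips negatives", {
    ## + strand: tx 91..400 over CDS 101..370 -> utr5 10, utr3 30
    genes <- makeGenes("chr", 101, 370, "+")
    cl <- classifyTranscripts(makeTx("chr", 91, 400, "+"), genes)
    u <- computeUtrs(cl, genes)
    expect_identical(u$utr5, 10)
    expect_identical(u$utr3, 30)
    expect_false(u$leaderless)

    ## same geometry mirrored to the - strand swaps the UTRs
    genes <- makeGenes("chr", 101, 370, "-")
    cl <- classifyTranscripts(makeTx("chr", 91, 400, "-"), genes)
    u <- computeUtrs(cl, genes)
    expect_identical(u$utr5, 30)
    expect_identical(u$utr3, 10)

    ## leaderless transcript: 5' end on the start codon
    genes <- makeGenes("chr", 101, 370, "+")
    cl <- classifyTranscripts(makeTx("chr", 101, 400, "+"), genes)
    expect_true(computeUtrs(cl, genes)$leaderless)

    ## calling on a non-cdRNA is a usage error
    cl <- classifyTranscripts(makeTx("chr", 2000, 2200, "+"), genes)
    expect_error(computeUtrs(cl, genes), "cdRNA")
})

test_that("ORF counting follows the covered genes of polycistronic calls", {
    ## two abutting CDSs on one transcript -> a binary transcript
    genes <- makeGenes("chr", c(1001, 1621), c(1600, 2300), c("+", "+"))
    cl <- classifyTranscripts(makeTx("chr", 1001, 2350, "+"), genes)
    expect_identical(countOrfs(cl), 2L)
    ## a nine-gene operon fully covered
    st <- 1000 + (0:8) * 700
    genes <- makeGenes("chr", st, st + 600, rep("+", 9))
    cl <- classifyTranscripts(makeTx("chr", 995, st[9] + 650, "+"), genes)
    expect_identical(countOrfs(cl), 9L)
    ## covered genes are listed 5' -> 3' along the transcript
    genes <- makeGenes("chr", c(1001, 1701), c(1600, 2300), c("-", "-"))
    cl <- classifyTranscripts(makeTx("chr", 995, 2310, "-"), genes)
    expect_identical(as.list(cl$coveredGenes)[[1]], c("g02", "g01"))
})

test_that("3'-overlap detection requires convergent geometry", {
    ## + [1,500] and - [451,900]: tails overlap by 50 nt
    tx <- makeTx("chr", c(1, 451), c(500, 900), c("+", "-"))
    ov <- find3primeOverlaps(tx)
    expect_identical(nrow(ov$pairs), 1L)
    expect_identical(ov$pairs$overlap_nt, 50L)
    expect_identical(ov$flags, c(TRUE, TRUE))

    ## disjoint intervals are never flagged
    ov <- find3primeOverlaps(makeTx("chr", c(1, 601), c(500, 900), c("+", "-")))
    expect_identical(nrow(ov$pairs), 0L)

    ## divergent overlap (tail-to-head) is not convergent: - transcript
    ## first, + transcript downstream, overlapping 5' ends
    ov <- find3primeOverlaps(makeTx("chr", c(451, 1), c(900, 500), c("+", "-")))
    expect_false(any(ov$flags))

    ## containment on opposite strands is not a 3' overlap
    ov <- find3primeOverlaps(makeTx("chr", c(1, 100), c(900, 300), c("+", "-")))
    expect_false(any(ov$flags))
})

test_that("TSS comparison partitions transcripts and catalogue entries", {
    tx <- makeTx("chr", c(1000, 3000, 5000), c(1500, 3400, 5200),
                 c("+", "+", "-"))
    tss <- data.frame(replicon = "chr", strand = c("+", "+", "-"),
                      position = c(1004L, 3600L, 5204L))
    cmp <- compareWithTss(tx, tss, classifyParams(tss_window = 10))
    expect_identical(cmp$supported, c(TRUE, FALSE, TRUE))
    expect_identical(cmp$n_only_tss, 1L)
    ## wrong strand does not support
    tss2 <- data.frame(replicon = "chr", strand = "-", position = 1004L)
    expect_false(compareWithTss(tx, tss2)$supported[1])
    ## empty catalogue: everything is transcript-only
    empty <- data.frame(replicon = character(), strand = character(),
                        position = integer())
    cmp <- compareWithTss(tx, empty)
    expect_false(any(cmp$supported))
    expect_identical(sum(cmp$by_class$n_only_transcripts), 3L)
})

test_that("classes partition simulated calls and respect their definitions", {
    ds <- simCache(2)
    tx <- callTranscripts(ds$coverage, ds$genes)
    tx <- classifyTranscripts(tx, ds$genes, classifyParams(), ds$tss)
    expect_true(all(txClass(tx) %in% c("cdRNA", "asRNA", "isRNA", "igRNA",
                                       "unassigned")))
    ## igRNAs: no CDS overlap on either strand
    ig <- tx[txClass(tx) == "igRNA"]
    expect_false(any(IRanges::overlapsAny(ig, ds$genes, ignore.strand = TRUE)))
    ## asRNAs: no same-strand CDS covered at the cdRNA level
    as.tx <- tx[txClass(tx) == "asRNA"]
    hits <- GenomicRanges::findOverlaps(as.tx, ds$genes, ignore.strand = FALSE)
    if (length(hits)) {
        w <- BiocGenerics::width(IRanges::pintersect(
            IRanges::ranges(as.tx)[S4Vectors::queryHits(hits)],
            IRanges::ranges(ds$genes)[S4Vectors::subjectHits(hits)]))
        frac <- w / BiocGenerics::width(ds$genes)[S4Vectors::subjectHits(hits)]
        expect_true(all(frac < 0.8))
    }
    ## overlap flags are symmetric with the pair list
    ov <- find3primeOverlaps(tx)
    in.pairs <- unique(c(ov$pairs$txId_a, ov$pairs$txId_b))
    expect_setequal(txId(tx)[ov$flags], in.pairs)
})

test_that("UTR and overlap statistics recover the planted structure", {
    u3.err <- c()
    ovf <- c()
    pair.det <- c()
    only.tx <- c()
    for (seed in 1:3) {
        ds <- simCache(seed)
        tx <- callTranscripts(ds$coverage, ds$genes)
        tx <- classifyTranscripts(tx, ds$genes, classifyParams(), ds$tss)
        ## 3'-UTR error against truth, for boundary-accurate cdRNA calls
        truth <- ds$truth[ds$truth$txClass == "cdRNA"]
        for (i in seq_along(truth)) {
            sel <- which(as.character(GenomeInfoDb::seqnames(tx)) ==
                             as.character(GenomeInfoDb::seqnames(truth)[i]) &
                         as.character(BiocGenerics::strand(tx)) ==
                             as.character(BiocGenerics::strand(truth)[i]) &
                         abs(BiocGenerics::start(tx) - BiocGenerics::start(truth)[i]) <= 20 &
                         abs(BiocGenerics::end(tx) - BiocGenerics::end(truth)[i]) <= 20 &
                         txClass(tx) == "cdRNA")
            if (!length(sel)) next
            j <- sel[1]
            g <- ds$genes[ds$genes$gene_id %in% unlist(truth$geneIds[i])]
            true.u3 <- if (as.character(BiocGenerics::strand(truth)[i]) == "+")
                BiocGenerics::end(truth)[i] - max(BiocGenerics::end(g))
            else min(BiocGenerics::start(g)) - BiocGenerics::start(truth)[i]
            u3.err <- c(u3.err, abs(tx$utr3[j] - max(true.u3, 0)))
        }
        ## overlap recovery, conditional on both partners being recovered
        ## (a pair whose low-expression partner is miscalled cannot carry
        ## the flag, whatever the classifier does)
        trx <- TranscriptSet(ds$truth)
        trx$txClass <- ds$truth$txClass
        ovT <- find3primeOverlaps(trx)
        ovC <- find3primeOverlaps(tx)
        ovf <- c(ovf, ovT$cdrna_fraction)
        idT <- txId(trx)
        rec <- function(i) {
            sel <- which(as.character(GenomeInfoDb::seqnames(tx)) ==
                             as.character(GenomeInfoDb::seqnames(ds$truth)[i]) &
                         as.character(BiocGenerics::strand(tx)) ==
                             as.character(BiocGenerics::strand(ds$truth)[i]) &
                         abs(BiocGenerics::start(tx) - BiocGenerics::start(ds$truth)[i]) <= 20 &
                         abs(BiocGenerics::end(tx) - BiocGenerics::end(ds$truth)[i]) <= 20)
            if (length(sel)) sel[1] else NA_integer_
        }
        for (k in seq_len(nrow(ovT$pairs))) {
            a <- rec(match(ovT$pairs$txId_a[k], idT))
            b <- rec(match(ovT$pairs$txId_b[k], idT))
            if (is.na(a) || is.na(b)) next
            pair.det <- c(pair.det, ovC$flags[a] && ovC$flags[b])
        }
        ## TSS support among boundary-accurate calls reflects the planted
        ## 0.3 catalogue dropout
        jj <- vapply(seq_along(ds$truth), rec, integer(1))
        only.tx <- c(only.tx, mean(!tx$tssSupported[jj[!is.na(jj)]]))
    }
    expect_lt(mean(u3.err), 10)
    ## the generator plants ~0.3 of cdRNAs with overlapping 3' ends
    expect_lt(abs(mean(ovf) - 0.3), 0.07)
    ## the classifier finds nearly all overlaps that survive calling
    expect_gte(mean(pair.det), 0.9)
    expect_lt(abs(mean(only.tx) - 0.3), 0.07)
})
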