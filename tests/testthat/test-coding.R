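test_that("ORF finding honours the 40-codon boundary and start requirement", {
    body39 <- strrep("GAC", 39)
    orf <- findOrfs(paste0("ATG", body39, "TAA"), min_codons = 40)
    expect_identical(nrow(orf), 1L)
    expect_identical(orf$n_codons, 40L)
    expect_false(orf$open_ended)
    ## one codon fewer fails the floor
    expect_identical(nrow(findOrfs(paste0("ATG", strrep("GAC", 38), "TAA"),
                                   min_codons = 40)), 0L)
    ## no ATG/GTG in any frame -> nothing
    expect_identical(nrow(findOrfs(strrep("CCT", 100))), 0L)
    ## N-containing codons terminate like stops
    expect_identical(nrow(findOrfs(paste0("ATG", strrep("GAC", 20), "NAA",
                                          strrep("GAC", 30)), min_codons = 40)), 0L)
    ## shorter than one codon
    expect_identical(nrow(findOrfs("AT")), 0L)
})

test_that("ORF finding matches the brute-force scanner on random sequences", {
    set.seed(3)
    for (i in 1:150) {
        seq <- randomDna(500, gc = sample(c(0.35, 0.5, 0.65), 1))
        got <- findOrfs(seq, min_codons = 10)
        want <- bruteOrfs(seq, min_codons = 10)
        rownames(got) <- rownames(want) <- NULL
        expect_identical(got[order(got$frame, got$start), ], want,
                         info = paste("case", i))
    }
})

test_that("translation follows the standard code with the initiator rule", {
    expect_identical(translateOrf("ATGGATGAC"), "MDD")
    expect_identical(translateOrf("GTGGAA"), "ME")
    expect_identical(translateOrf("ATGTAA"), "M")     # trailing stop dropped
    expect_error(translateOrf("ATGTAAGAC"), "internal stop")
    expect_error(translateOrf("ATGGA"), "divisible")
    expect_error(translateOrf("ATGGANTAA"), "N")
    ## agreement with an independent implementation of the code
    set.seed(33)
    for (i in 1:200) {
        nt <- randomOrfSeq(sample(5:80, 1))
        ref <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
        substr(ref, 1, 1) <- "M"
        expect_identical(translateOrf(nt), ref)
    }
})

test_that("isoelectric point solves the charge root and orders acid vs base", {
    ## root condition: net charge at the returned pI is ~0
    set.seed(44)
    for (i in 1:100) {
        p <- randomPeptide(sample(10:200, 1))
        pi <- isoelectricPoint(p)
        expect_lt(abs(referenceNetCharge(p, pi)), 0.01)
    }
    expect_lt(isoelectricPoint(strrep("D", 12)), isoelectricPoint(strrep("K", 12)))
    ## appending an acidic residue never raises the pI (bisection slack)
    set.seed(45)
    for (i in 1:100) {
        p <- randomPeptide(sample(5:60, 1))
        expect_lte(isoelectricPoint(paste0(p, "D")),
                   isoelectricPoint(p) + 0.006)
    }
    expect_error(isoelectricPoint("MDX"), "unknown residue")
    expect_error(isoelectricPoint(""), "empty")
})

test_that("codon usage tables normalise families and support the size filter", {
    tab <- buildCodonUsage("ATGGACTAA")
    expect_identical(unname(codonCounts(tab)[c("ATG", "GAC", "TAA")]), c(1, 1, 1))
    expect_identical(unname(relAdaptiveness(tab)[["GAC"]]), 1)
    ## every family maximum is exactly 1 on any input
    set.seed(5)
    cds <- vapply(1:30, function(i) randomOrfSeq(sample(50:300, 1)), character(1))
    tab <- buildCodonUsage(cds)
    aa <- Biostrings::GENETIC_CODE[names(relAdaptiveness(tab))]
    expect_true(all(abs(tapply(relAdaptiveness(tab), aa, max) - 1) < 1e-12))
    ## out-of-frame CDS is skipped with a warning
    expect_warning(buildCodonUsage(c("ATGGACTAA", "ATGGA")), "skipped")
    ## size filter keeps only small proteins
    small <- buildCodonUsage(cds, max_aa = 100)
    expect_lt(sum(codonCounts(small)), sum(codonCounts(tab)))
})

test_that("preference scores hit the normalisation limits", {
    sim <- simulateGenome(simulationParams(seed = 6, genome_length = 60000L,
                                           n_genes = 40L, n_replicons = 1L))
    tab <- buildCodonUsage(extractCds(sim$genome, sim$genes))
    ## ORF built purely of family-maximum codons scores exactly 1
    ra <- relAdaptiveness(tab)
    aa <- Biostrings::GENETIC_CODE[names(ra)]
    best <- vapply(split(ra, aa), function(x) names(x)[which.max(x)], character(1))
    orf <- paste(sample(best, 120, replace = TRUE), collapse = "")
    pp <- preferenceProfile(orf, tab)
    expect_equal(pp$preference_score, 1)
    expect_true(all(abs(pp$profile - 1) < 1e-12))
    ## a family-uniform table scores every ORF the same constant
    counts <- codonCounts(tab)
    counts[] <- 10
    uni <- new("CodonUsageTable", counts = counts,
               adaptiveness = setNames(rep(1, sum(Biostrings::GENETIC_CODE != "*")),
                                       names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]))
    set.seed(61)
    s1 <- preferenceProfile(randomOrfSeq(60), uni)$preference_score
    s2 <- preferenceProfile(randomOrfSeq(90), uni)$preference_score
    expect_equal(s1, 1)
    expect_identical(s1, s2)
})

test_that("true coding sequences separate from composition-matched null ORFs", {
    sim <- simulateGenome(simulationParams(seed = 8, genome_length = 80000L,
                                           n_genes = 60L, n_replicons = 1L))
    cds <- extractCds(sim$genome, sim$genes)
    tab <- buildCodonUsage(cds)
    comp <- baseComposition(sim$genome)
    above <- vapply(cds, function(s) {
        nc <- nchar(s) / 3 - 1
        pp <- preferenceProfile(s, tab)
        thr <- nullPreferenceThreshold(tab, as.integer(nc), comp,
                                       n = 300, seed = 9)
        pp$preference_score > thr
    }, logical(1))
    expect_gte(mean(above), 0.95)
    ## null ORFs of the same composition pass at about the nominal rate
    set.seed(10)
    sense <- names(relAdaptiveness(tab))
    pr <- halotx:::codonProbsFromComposition(comp)[sense]
    pr <- pr / sum(pr)
    thr80 <- nullPreferenceThreshold(tab, 80L, comp, n = 300, seed = 9)
    set.seed(10)
    fp <- vapply(1:200, function(i) {
        nt <- paste(sample(sense, 80, replace = TRUE, prob = pr), collapse = "")
        preferenceProfile(nt, tab)$preference_score > thr80
    }, logical(1))
    expect_lte(mean(fp), 0.10)
})

test_that("rise-and-decline flags interior peaks only", {
    rd <- detectRiseDecline(c(0.2, 0.2, 0.9, 0.9, 0.2), 0.5)
    expect_true(rd$flag)
    expect_identical(rd$peak, c(3L, 4L))
    ## monotone rise ending high: no decline -> not flagged
    expect_false(detectRiseDecline(seq(0.1, 0.9, length.out = 10), 0.5)$flag)
    ## high throughout -> not flagged
    expect_false(detectRiseDecline(rep(0.9, 10), 0.5)$flag)
    expect_false(detectRiseDecline(rep(0.1, 10), 0.5)$flag)
})

test_that("the screen finds a planted acidic ORF and tallies the filter chain", {
    sim <- simulateGenome(simulationParams(seed = 12, genome_length = 60000L,
                                           n_genes = 40L, n_replicons = 1L))
    tab <- buildCodonUsage(extractCds(sim$genome, sim$genes))
    ra <- relAdaptiveness(tab)
    aa <- Biostrings::GENETIC_CODE[names(ra)]
    best <- vapply(split(ra, aa), function(x) names(x)[which.max(x)], character(1))
    ## plant a 60-codon acidic ORF built from top codons in a gene-free gap
    orf <- paste(c("ATG", rep(best[["D"]], 25), rep(best[["E"]], 25),
                   rep(best[["G"]], 9), "TGA"), collapse = "")
    genome <- as.character(sim$genome[[1]])
    gaps <- GenomicRanges::gaps(GenomicRanges::reduce(sim$genes, ignore.strand = TRUE))
    gaps <- gaps[BiocGenerics::strand(gaps) == "*" & BiocGenerics::width(gaps) > 400]
    at <- BiocGenerics::start(gaps)[1] + 50L
    substr(genome, at, at + nchar(orf) - 1L) <- orf
    genome <- Biostrings::DNAStringSet(setNames(genome, names(sim$genome)[1]))

    tx <- makeTx(names(genome), at - 20L, at + nchar(orf) + 19L, "+",
                 seqlen = BiocGenerics::width(genome))
    tx$txClass <- "igRNA"
    res <- screenNoncoding(tx, genome, sim$genes, tab,
                           screenParams(null_n = 300))
    expect_identical(sum(res$candidates$passes), 1L)
    expect_identical(res$candidates$n_codons[res$candidates$passes], 60L)
    expect_lte(res$candidates$pI[res$candidates$passes][1], 6)

    ## a 39-codon planted ORF dies at the length filter and the tally shows it
    short.orf <- paste(c("ATG", rep(best[["D"]], 38), "TGA"), collapse = "")
    genome2 <- as.character(sim$genome[[1]])
    substr(genome2, at, at + nchar(short.orf) - 1L) <- short.orf
    ## scrub the rest of the window so no other ORF lurks there
    genome2 <- Biostrings::DNAStringSet(setNames(genome2, names(sim$genome)[1]))
    tx2 <- makeTx(names(genome2), at - 2L, at + nchar(short.orf) + 1L, "+",
                  seqlen = BiocGenerics::width(genome2))
    tx2$txClass <- "igRNA"
    res2 <- screenNoncoding(tx2, genome2, sim$genes, tab,
                            screenParams(null_n = 300))
    tally <- setNames(res2$tally$n_surviving, res2$tally$stage)
    expect_gte(tally[["orfs_found"]], 1)
    expect_identical(tally[["length_pass"]], 0L)
    expect_identical(tally[["preference_pass"]], 0L)
    ## tallies never increase along the chain
    expect_true(all(diff(setNames(res$tally$n_surviving, NULL)) <= 0))
})

test_that("isRNA screening excludes the host frame and demands rise-and-decline", {
    ds <- simCache(3)
    tab <- buildCodonUsage(extractCds(ds$genome, ds$genes))
    tx <- TranscriptSet(ds$truth[ds$truth$txClass == "isRNA"])
    tx$txClass <- ds$truth$txClass[ds$truth$txClass == "isRNA"]
    res <- screenNoncoding(tx, ds$genome, ds$genes, tab,
                           screenParams(null_n = 200))
    ## the host gene frame is excluded, so candidates in that frame never appear
    for (k in seq_len(nrow(res$candidates))) {
        i <- match(res$candidates$transcript_id[k], txId(tx))
        hf <- halotx:::hostFrame(tx[i], ds$genes)
        if (!is.na(hf)) expect_false(res$candidates$frame[k] == hf)
    }
    ## any passing isRNA candidate carries the rise-and-decline signature
    pass <- res$candidates[res$candidates$passes, ]
    if (nrow(pass)) expect_true(all(pass$rise_decline))
})
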