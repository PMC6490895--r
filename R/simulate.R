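## Seed-deterministic simulator for a haloarchaeal-like transcriptome:
## GC-rich multi-replicon genome with acidic, codon-biased CDSs arranged
## in transcription units, planted transcripts of the four classes with
## realistic length / UTR / 3'-overlap structure, and noisy
## strand-specific coverage with a locally correlated multiplicative
## field plus Poisson background, together with a TSS catalogue.

#' Simulation parameters
#'
#' Defaults emulate the statistical structure of a haloarchaeal mixed
#' RNA-Seq study: ~65% GC genome, acidic proteome, four transcript
#' classes in roughly 0.53/0.35/0.06/0.06 proportion, sRNA lengths
#' lognormal with median 140 nt, ~2/3 of protein-coding transcripts
#' monocistronic, mostly leaderless 5' ends, and ~30% of convergent
#' coding transcripts with overlapping 3' ends.
#'
#' @param seed integer RNG seed; every simulation stage derives its own
#'   stream from it.
#' @param genome_length total genome in nt, split across replicons.
#' @param n_replicons number of replicons (main chromosome plus
#'   mini-chromosomes named pHV1, pHV3, pHV4).
#' @param gc_content background GC fraction.
#' @param n_genes number of annotated CDSs.
#' @param polycistronic_fraction fraction of transcription units (hence
#'   of cdRNAs) carrying more than one gene; 1/3 yields the ~2/3
#'   monocistronic fraction.
#' @param class_mix target cdRNA/asRNA/isRNA/igRNA proportions.
#' @param srna_meanlog,srna_sdlog lognormal sRNA length (median
#'   `exp(srna_meanlog)` = 140 nt).
#' @param expr_meanlog,expr_sdlog lognormal per-transcript mean coverage
#'   (median 300 reads).
#' @param background_rate mean off-transcript Poisson coverage.
#' @param within_transcript_cv coefficient of variation of the smoothed
#'   multiplicative coverage field (0 = uniform coverage).
#' @param smooth_window moving-average window of the field in nt.
#' @param utr3_mean mean 3'-UTR in nt.
#' @param leaderless_fraction fraction of cdRNAs with a 5'-UTR of at
#'   most 3 nt.
#' @param overlap3_fraction fraction of convergent cdRNA pairs given
#'   overlapping 3' extensions.
#' @param tss_dropout fraction of planted transcripts whose TSS is
#'   withheld from the catalogue.
#' @param decoy_tss_fraction catalogue-only TSS, as a fraction of the
#'   planted transcript count.
#' @param silent_fraction fraction of transcription units left
#'   unexpressed; isRNAs are planted inside silent genes (an isRNA
#'   inside an expressed gene would be swallowed by its cdRNA coverage).
#' @return list of class `SimulationParams`.
#' @export
simulationParams <- function(seed = 1L,
                             genome_length = 200000L,
                             n_replicons = 2L,
                             gc_content = 0.65,
                             n_genes = 150L,
                             polycistronic_fraction = 1 / 3,
                             class_mix = c(cdRNA = 0.53, asRNA = 0.35,
                                           isRNA = 0.06, igRNA = 0.06),
                             srna_meanlog = log(140), srna_sdlog = 0.45,
                             expr_meanlog = log(300), expr_sdlog = 1.0,
                             background_rate = 2,
                             within_transcript_cv = 0.5,
                             smooth_window = 50L,
                             utr3_mean = 60,
                             leaderless_fraction = 0.8,
                             overlap3_fraction = 0.3,
                             tss_dropout = 0.3,
                             decoy_tss_fraction = 0.25,
                             silent_fraction = 0.15) {
    stopifnot(abs(sum(class_mix) - 1) < 1e-6, all(class_mix >= 0),
              gc_content > 0, gc_content < 1,
              background_rate >= 0, within_transcript_cv >= 0,
              genome_length >= 10 * 900)
    structure(as.list(environment()), class = "SimulationParams")
}

## ---- internal constants: acidic amino-acid profile and GC3-biased
## codon weighting used to emit haloarchaeal-style CDSs ----------------

ACIDIC_AA_FREQ <- c(A = 0.095, R = 0.055, N = 0.030, D = 0.105, C = 0.005,
                    E = 0.110, Q = 0.025, G = 0.085, H = 0.020, I = 0.040,
                    L = 0.080, K = 0.020, M = 0.015, F = 0.030, P = 0.040,
                    S = 0.055, T = 0.055, W = 0.010, Y = 0.025, V = 0.100)

#' Built-in haloarchaeal-style codon weights
#'
#' Within each synonymous family, codons are weighted by
#' `exp(beta * n_GC)` where `n_GC` counts G/C bases of the codon, giving
#' the strong GC3 preference (e.g. GAC over GAT) typical of halophilic
#' archaea.  Any user-built [CodonUsageTable-class] can replace the
#' resulting usage downstream.
#'
#' @param beta GC bias strength (default 2).
#' @return named list mapping each amino acid (and `"*"`) to a named
#'   probability vector over its codons.
#' @export
haloCodonWeights <- function(beta = 2) {
    gc <- vapply(strsplit(names(Biostrings::GENETIC_CODE), ""),
                 function(b) sum(b %in% c("G", "C")), numeric(1))
    w <- exp(beta * gc)
    split.codons <- split(setNames(w, names(Biostrings::GENETIC_CODE)),
                          Biostrings::GENETIC_CODE)
    lapply(split.codons, function(x) x / sum(x))
}

sampleSeq <- function(n, gc) {
    paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
}

## emit one CDS of n_aa residues (incl. the initiator Met): start codon,
## codon-biased body, stop codon; no internal stops by construction
emitCds <- function(n_aa, weights) {
    aa <- sample(names(ACIDIC_AA_FREQ), n_aa - 1L, replace = TRUE,
                 prob = ACIDIC_AA_FREQ)
    body <- vapply(aa, function(a) {
        p <- weights[[a]]
        sample(names(p), 1L, prob = p)
    }, character(1))
    start <- sample(c("ATG", "GTG"), 1L, prob = c(0.85, 0.15))
    stopc <- sample(names(weights[["*"]]), 1L, prob = weights[["*"]])
    paste(c(start, body, stopc), collapse = "")
}

#' Simulate a haloarchaeal-like genome and annotation
#'
#' Generates replicon sequences at the requested GC with embedded
#' in-frame, ATG/GTG-initiated, stop-terminated CDSs whose codons are
#' drawn from an acidic, GC3-biased usage; genes are arranged in
#' transcription units (a `polycistronic_fraction` of units carry 2-4
#' head-to-tail genes with short internal gaps), never overlapping on
#' one strand.
#'
#' @param params A [simulationParams()] list.
#' @return list with `genome` (`DNAStringSet`), `genes` (CDS `GRanges`
#'   with `gene_id`, `unit`, `is_small`), and `units` (data.frame of
#'   transcription units: replicon, strand, span, gene count).
#' @export
simulateGenome <- function(params = simulationParams()) {
    set.seed(params$seed)
    weights <- haloCodonWeights()
    ## replicon lengths: main chromosome 70%, remainder split evenly
    nrep <- params$n_replicons
    lens <- if (nrep == 1L) params$genome_length else
        c(round(params$genome_length * 0.7),
          rep(round(params$genome_length * 0.3 / (nrep - 1L)), nrep - 1L))
    rep.names <- c("Chr", "pHV1", "pHV3", "pHV4")[seq_len(nrep)]
    names(lens) <- rep.names

    ## transcription-unit plan
    n.units <- max(1L, round(params$n_genes /
        (1 + params$polycistronic_fraction * 1.6)))   # E[extra genes|poly] = 1.6
    poly <- runif(n.units) < params$polycistronic_fraction
    sizes <- ifelse(poly, sample(2:4, n.units, replace = TRUE,
                                 prob = c(0.55, 0.3, 0.15)), 1L)
    while (sum(sizes) > params$n_genes && n.units > 1L) {
        sizes <- sizes[-length(sizes)]
        n.units <- n.units - 1L
    }

    gene.rows <- list()
    unit.rows <- list()
    seqs <- list()
    unit.id <- 0L
    gene.id <- 0L
    ## assign units to replicons proportional to length
    unit.rep <- sample(rep.names, length(sizes), replace = TRUE,
                       prob = lens / sum(lens))
    for (rep in rep.names) {
        L <- lens[[rep]]
        chunks <- list()
        pos <- 1L
        my.units <- which(unit.rep == rep)
        for (u in my.units) {
            gap <- sample(200:600, 1L)
            if (pos + gap > L - 3000L) break
            chunks[[length(chunks) + 1L]] <- sampleSeq(gap, params$gc_content)
            pos <- pos + gap
            st <- sample(c("+", "-"), 1L)
            k <- sizes[u]
            n.aa <- pmax(40L, pmin(700L, round(stats::rlnorm(k, log(230), 0.45))))
            cds <- vapply(n.aa + 1L, emitCds, character(1), weights = weights)
            igaps <- if (k > 1L) sample(3:30, k - 1L, replace = TRUE) else integer(0)
            unit.len <- sum(nchar(cds)) + sum(igaps)
            if (pos + unit.len > L - 700L) break
            unit.id <- unit.id + 1L
            ## on '-' units the downstream-most gene sits leftmost; gene
            ## order within the unit is 5'->3'
            order.idx <- if (st == "+") seq_len(k) else rev(seq_len(k))
            cursor <- pos
            starts <- integer(k); ends <- integer(k)
            for (j in seq_len(k)) {
                starts[j] <- cursor
                ends[j] <- cursor + nchar(cds[j]) - 1L
                cursor <- ends[j] + 1L + if (j < k) igaps[j] else 0L
            }
            piece <- cds
            if (st == "-") piece <- vapply(cds, function(x)
                as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
                character(1))
            ## interleave CDS pieces and internal gaps
            for (j in seq_len(k)) {
                chunks[[length(chunks) + 1L]] <- piece[j]
                if (j < k)
                    chunks[[length(chunks) + 1L]] <- sampleSeq(igaps[j], params$gc_content)
            }
            for (j in order.idx) {
                gene.id <- gene.id + 1L
                gene.rows[[gene.id]] <- data.frame(
                    gene_id = sprintf("HXS_%04d", gene.id), replicon = rep,
                    strand = st, start = starts[j], end = ends[j],
                    unit = unit.id, n_aa = nchar(cds[j]) / 3 - 1,
                    stringsAsFactors = FALSE)
            }
            unit.rows[[unit.id]] <- data.frame(
                unit = unit.id, replicon = rep, strand = st,
                start = starts[1], end = ends[k], n_genes = k,
                stringsAsFactors = FALSE)
            pos <- cursor
        }
        chunks[[length(chunks) + 1L]] <- sampleSeq(L - pos + 1L, params$gc_content)
        seqs[[rep]] <- paste(unlist(chunks), collapse = "")
    }
    if (!length(gene.rows))
        stop("could not place any gene; increase genome_length", call. = FALSE)
    gd <- do.call(rbind, gene.rows)
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- rep.names
    stopifnot(identical(unname(vapply(seqs, nchar, integer(1))),
                        unname(as.integer(lens))))
    genes <- GenomicRanges::GRanges(gd$replicon,
                                    IRanges::IRanges(gd$start, gd$end),
                                    strand = gd$strand,
                                    seqlengths = lens)
    genes$gene_id <- gd$gene_id
    genes$unit <- gd$unit
    genes$product <- "simulated protein"
    genes$is_small <- gd$n_aa <= 100
    list(genome = genome, genes = GenomicRanges::sort(genes, ignore.strand = TRUE),
         units = do.call(rbind, unit.rows))
}

## interval bookkeeping: one IRanges per replicon/strand of occupied
## space (with margin), used to keep same-strand plantings disjoint
occupancyAdd <- function(occ, rep, st, from, to) {
    key <- paste(rep, st)
    ir <- IRanges::IRanges(from, to)
    occ[[key]] <- if (is.null(occ[[key]])) ir else c(occ[[key]], ir)
    occ
}
occupancyFree <- function(occ, rep, st, from, to, margin = 25L) {
    key <- paste(rep, st)
    if (is.null(occ[[key]])) return(TRUE)
    q <- IRanges::IRanges(max(1L, from - margin), to + margin)
    !any(IRanges::overlapsAny(q, occ[[key]]))
}

#' Plant ground-truth transcripts of the four classes
#'
#' Expressed transcription units become cdRNAs (genes plus sampled
#' UTRs, mostly leaderless); a share of convergent cdRNA pairs get
#' 3'-extensions overlapping by 10-100 nt; asRNAs are placed opposite
#' randomly chosen genes, isRNAs strictly inside silent same-strand
#' genes, igRNAs in gene-free gaps; sRNA lengths are lognormal.  All
#' same-strand plantings are disjoint (separated by at least 25 nt) so
#' each truth transcript is a callable unit.
#'
#' @param params A [simulationParams()] list.
#' @param sim output of [simulateGenome()].
#' @return `GRanges` of truth records with `txClass`, `expression`
#'   (planted mean coverage), `geneIds` (`CharacterList`), `unit`.
#' @export
simulateTranscripts <- function(params, sim) {
    set.seed(params$seed + 1L)
    genes <- sim$genes
    units <- sim$units
    sl <- stats::setNames(BiocGenerics::width(sim$genome), names(sim$genome))
    occ <- list()
    rows <- list()
    addRow <- function(rep, st, from, to, cls, ids, unit = NA_integer_) {
        rows[[length(rows) + 1L]] <<- data.frame(
            replicon = rep, strand = st, start = from, end = to,
            class = cls, gene_ids = I(list(ids)), unit = unit,
            stringsAsFactors = FALSE)
    }

    expressed <- runif(nrow(units)) >= params$silent_fraction
    ## --- cdRNAs ------------------------------------------------------
    for (r in seq_len(nrow(units))) {
        if (!expressed[r]) next
        u <- units[r, ]
        leaderless <- runif(1) < params$leaderless_fraction
        u5 <- if (leaderless) sample(0:3, 1L) else sample(10:150, 1L)
        u3 <- round(stats::rexp(1, 1 / params$utr3_mean)) + 5L
        if (u$strand == "+") {
            from <- max(1L, u$start - u5); to <- min(sl[[u$replicon]], u$end + u3)
        } else {
            from <- max(1L, u$start - u3); to <- min(sl[[u$replicon]], u$end + u5)
        }
        ## clip UTR extensions so same-strand plantings stay disjoint
        iv <- occ[[paste(u$replicon, u$strand)]]
        if (!is.null(iv)) {
            lft <- BiocGenerics::end(iv)[BiocGenerics::end(iv) < u$start]
            if (length(lft)) from <- max(from, max(lft) + 26L)
            rgt <- BiocGenerics::start(iv)[BiocGenerics::start(iv) > u$end]
            if (length(rgt)) to <- min(to, min(rgt) - 26L)
        }
        ids <- genes$gene_id[genes$unit == u$unit]
        ## 5'->3' order
        if (u$strand == "-") ids <- rev(ids)
        addRow(u$replicon, u$strand, from, to, "cdRNA", ids, u$unit)
        occ <- occupancyAdd(occ, u$replicon, u$strand, from, to)
    }
    truth <- do.call(rbind, rows)

    ## --- overlapping 3' extensions for convergent cdRNA pairs --------
    ## overlap3_fraction targets the fraction of cdRNAs that end up with
    ## an overlapping 3' end (each planted pair flags two cdRNAs)
    cd <- which(truth$class == "cdRNA")
    conv <- list()
    n.existing <- 0L      # convergent pairs already overlapping via their UTRs
    byrep <- split(cd, truth$replicon[cd])
    for (rep in names(byrep)) {
        idx <- byrep[[rep]][order(truth$start[byrep[[rep]]])]
        for (k in seq_len(max(0L, length(idx) - 1L))) {
            a <- idx[k]; b <- idx[k + 1L]
            ## convergent: upstream '+' unit followed by a '-' unit
            if (truth$strand[a] == "+" && truth$strand[b] == "-") {
                if (truth$end[a] < truth$start[b])
                    conv[[length(conv) + 1L]] <- c(a, b)
                else if (truth$end[a] <= truth$end[b] &&
                         truth$start[b] >= truth$start[a])
                    n.existing <- n.existing + 1L
            }
        }
    }
    n.pairs <- min(length(conv),
                   max(0L, round(params$overlap3_fraction * length(cd) / 2) -
                           n.existing))
    for (pair in if (n.pairs > 0) sample(conv, n.pairs) else list()) {
        a <- pair[1]; b <- pair[2]
        o <- sample(10:100, 1L)
        m <- (truth$end[a] + truth$start[b]) %/% 2L
        new.a <- m + ceiling(o / 2); new.b <- m - floor(o / 2)
        ## keep each 3' end inside the partner, clear of its far end
        if (new.a <= truth$end[b] - 50L && new.b >= truth$start[a] + 50L) {
            truth$end[a] <- new.a
            truth$start[b] <- new.b
        }
    }
    ## rebuild occupancy after extensions
    occ <- list()
    for (r in seq_len(nrow(truth)))
        occ <- occupancyAdd(occ, truth$replicon[r], truth$strand[r],
                            truth$start[r], truth$end[r])

    n.cd <- sum(truth$class == "cdRNA")
    mix <- params$class_mix
    n.as <- round(n.cd * mix[["asRNA"]] / mix[["cdRNA"]])
    n.is <- round(n.cd * mix[["isRNA"]] / mix[["cdRNA"]])
    n.ig <- round(n.cd * mix[["igRNA"]] / mix[["cdRNA"]])
    srnaLen <- function() max(50L, round(stats::rlnorm(1, params$srna_meanlog,
                                                       params$srna_sdlog)))
    flip <- c("+" = "-", "-" = "+")

    ## --- asRNAs: opposite strand of random genes ----------------------
    tries <- 0L
    placed <- 0L
    while (placed < n.as && tries < n.as * 60L) {
        tries <- tries + 1L
        g <- genes[sample(length(genes), 1L)]
        len <- srnaLen()
        rep <- as.character(seqnames(g))
        st <- flip[[as.character(strand(g))]]
        ## centre inside the gene so the antisense overlap is substantial
        c0 <- sample(start(g):end(g), 1L)
        from <- max(1L, c0 - len %/% 2L)
        to <- min(sl[[rep]], from + len - 1L)
        if (to - from + 1L < 50L) next
        if (!occupancyFree(occ, rep, st, from, to)) next
        addRow(rep, st, from, to, "asRNA", character(0))
        occ <- occupancyAdd(occ, rep, st, from, to)
        placed <- placed + 1L
    }

    ## --- isRNAs: inside silent same-strand genes ----------------------
    silent.units <- units$unit[!expressed]
    silent.genes <- genes[genes$unit %in% silent.units]
    tries <- 0L; placed <- 0L
    while (placed < n.is && tries < n.is * 60L && length(silent.genes)) {
        tries <- tries + 1L
        g <- silent.genes[sample(length(silent.genes), 1L)]
        len <- srnaLen()
        if (len + 30L > BiocGenerics::width(g)) next
        rep <- as.character(seqnames(g))
        st <- as.character(strand(g))
        from <- sample(start(g):(end(g) - len - 15L), 1L)
        from <- max(from, start(g) + 15L)
        to <- from + len - 1L
        if (to > end(g) - 15L) next
        if (!occupancyFree(occ, rep, st, from, to)) next
        addRow(rep, st, from, to, "isRNA", character(0))
        occ <- occupancyAdd(occ, rep, st, from, to)
        placed <- placed + 1L
    }

    ## --- igRNAs: gene-free gaps on either strand ----------------------
    gaps <- GenomicRanges::gaps(GenomicRanges::reduce(
        GenomicRanges::GRanges(seqnames(genes),
                               IRanges::IRanges(start(genes) - 30L,
                                                end(genes) + 30L)),
        ignore.strand = TRUE))
    gaps <- gaps[as.character(strand(gaps)) == "*" &
                 BiocGenerics::width(gaps) >= 120L]
    tries <- 0L; placed <- 0L
    while (placed < n.ig && tries < n.ig * 60L && length(gaps)) {
        tries <- tries + 1L
        gp <- gaps[sample(length(gaps), 1L)]
        len <- srnaLen()
        if (len + 10L > BiocGenerics::width(gp)) next
        rep <- as.character(seqnames(gp))
        st <- sample(c("+", "-"), 1L)
        from <- sample(start(gp):(end(gp) - len), 1L)
        to <- from + len - 1L
        if (!occupancyFree(occ, rep, st, from, to)) next
        addRow(rep, st, from, to, "igRNA", character(0))
        occ <- occupancyAdd(occ, rep, st, from, to)
        placed <- placed + 1L
    }

    truth <- do.call(rbind, c(list(truth), rows[-seq_len(nrow(truth))]))
    truth$expression <- stats::rlnorm(nrow(truth), params$expr_meanlog,
                                      params$expr_sdlog)
    gr <- GenomicRanges::GRanges(truth$replicon,
                                 IRanges::IRanges(truth$start, truth$end),
                                 strand = truth$strand, seqlengths = sl)
    gr$txClass <- truth$class
    gr$expression <- truth$expression
    gr$geneIds <- IRanges::CharacterList(truth$gene_ids)
    gr$unit <- truth$unit
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## smoothed positive multiplicative field of mean 1 whose CV after the
## moving average is ~cv: pre-smoothing gamma shape 1/(cv^2 * w)
noiseField <- function(n, cv, w) {
    if (cv == 0) return(rep(1, n))
    shape <- 1 / (cv^2 * w)
    raw <- stats::rgamma(n + w - 1L, shape = shape, rate = shape)
    cs <- cumsum(raw)
    (cs[seq.int(w, length.out = n)] -
        c(0, cs)[seq.int(1L, length.out = n)]) / w
}

#' Simulate strand-specific coverage and the TSS catalogue
#'
#' Per-transcript coverage is `expression * field` where `field` is a
#' gamma multiplicative process smoothed with a moving average
#' (`within_transcript_cv`, `smooth_window`), plus Poisson background at
#' `background_rate`, finally Poisson-sampled to integers.  In the
#' noiseless limit (`within_transcript_cv = 0` and
#' `background_rate = 0`) coverage is exactly the rounded expression
#' level inside each transcript and 0 outside, which makes the planted
#' boundaries exactly recoverable.  The TSS catalogue holds each truth
#' transcript's 5' position minus a dropout fraction, plus decoys.
#'
#' @param params A [simulationParams()] list.
#' @param truth `GRanges` from [simulateTranscripts()].
#' @param sim output of [simulateGenome()].
#' @return list with `coverage` (A [CoverageSet-class]) and `tss`
#'   (data.frame `replicon`, `strand`, `position`).
#' @export
simulateCoverage <- function(params, truth, sim) {
    set.seed(params$seed + 2L)
    sl <- stats::setNames(BiocGenerics::width(sim$genome), names(sim$genome))
    lam <- list(`+` = lapply(sl, numeric), `-` = lapply(sl, numeric))
    for (i in seq_along(truth)) {
        rep <- as.character(seqnames(truth)[i])
        st <- as.character(strand(truth)[i])
        n <- BiocGenerics::width(truth)[i]
        f <- noiseField(n, params$within_transcript_cv, params$smooth_window)
        idx <- start(truth)[i]:end(truth)[i]
        lam[[st]][[rep]][idx] <- lam[[st]][[rep]][idx] +
            truth$expression[i] * f
    }
    noiseless <- params$within_transcript_cv == 0 && params$background_rate == 0
    draw <- function(v) {
        if (noiseless) round(v)
        else as.numeric(stats::rpois(length(v), v + params$background_rate))
    }
    cov <- CoverageSet(fwd = lapply(lam[["+"]], draw),
                       rev = lapply(lam[["-"]], draw))

    keep <- runif(length(truth)) >= params$tss_dropout
    tss <- data.frame(replicon = as.character(seqnames(truth))[keep],
                      strand = as.character(strand(truth))[keep],
                      position = end5(truth)[keep],
                      stringsAsFactors = FALSE)
    n.decoy <- round(params$decoy_tss_fraction * length(truth))
    if (n.decoy > 0) {
        rep <- sample(names(sl), n.decoy, replace = TRUE, prob = sl / sum(sl))
        tss <- rbind(tss, data.frame(
            replicon = rep, strand = sample(c("+", "-"), n.decoy, TRUE),
            position = vapply(rep, function(r) sample(sl[[r]], 1L), numeric(1)),
            stringsAsFactors = FALSE))
    }
    rownames(tss) <- NULL
    list(coverage = cov, tss = tss)
}

#' Run the full simulator
#'
#' Convenience wrapper: genome + annotation, planted truth transcripts,
#' coverage and TSS catalogue, all deterministic under `params$seed`.
#'
#' @param params A [simulationParams()] list.
#' @return list with `genome`, `genes`, `units`, `truth`, `coverage`,
#'   `tss`, `params`.
#' @export
simulateDataset <- function(params = simulationParams()) {
    sim <- simulateGenome(params)
    truth <- simulateTranscripts(params, sim)
    cv <- simulateCoverage(params, truth, sim)
    list(genome = sim$genome, genes = sim$genes, units = sim$units,
         truth = truth, coverage = cv$coverage, tss = cv$tss,
         params = params)
}
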