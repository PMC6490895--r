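## Readers and writers for the formats the pipeline touches: FASTA
## genomes, GFF3 gene models, strand-specific wiggle coverage, and the
## TSV transcript / TSS tables.  All on-disk coordinates follow the
## format's own convention (GFF3 and wiggle 1-based, transcript table
## 0-based half-open); in memory everything is 1-based GRanges/IRanges.

fmtStop <- function(...) stop(sprintf(...), call. = FALSE)

#' Read a multi-record genome FASTA
#'
#' @param path FASTA file, one record per replicon.
#' @return A [Biostrings::DNAStringSet], upper-cased, one element per
#'   replicon.  Record ids are truncated at the first whitespace.
#'   Characters outside A, C, G, T, N are rejected; duplicate ids are an
#'   error; an empty file yields an empty set.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrX", "ACGTACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) fmtStop("no such file: %s", path)
    if (file.size(path) == 0L) return(Biostrings::DNAStringSet())
    seqs <- withCallingHandlers(
        Biostrings::readDNAStringSet(path),
        warning = function(w) {
            if (grepl("invalid one-letter sequence code", conditionMessage(w)))
                fmtStop("%s: sequence contains characters outside A/C/G/T/N", path)
            invokeRestart("muffleWarning")
        })
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        fmtStop("duplicate replicon id in %s: %s", path,
                names(seqs)[duplicated(names(seqs))][1])
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    bad <- Biostrings::letterFrequency(seqs, "ACGTN") != BiocGenerics::width(seqs)
    if (any(bad))
        fmtStop("record '%s' contains characters outside A/C/G/T/N",
                names(seqs)[bad][1])
    if (any(BiocGenerics::width(seqs) == 0))
        fmtStop("record '%s' has an empty sequence",
                names(seqs)[BiocGenerics::width(seqs) == 0][1])
    seqs
}

#' Write a genome FASTA
#' @param seqs a named `DNAStringSet` (or named character vector).
#' @param path output file.
#' @export
writeGenome <- function(seqs, path) {
    if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path, width = 70L)
    invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports features of the requested types and returns them as a
#' stranded `GRanges` with metadata columns `gene_id` (locus_tag if
#' present, else ID), `product`, and `is_small` (encoded protein of at
#' most 100 aa).  Coordinates stay 1-based inclusive, the GFF3 and
#' GRanges convention.
#'
#' @param path GFF3 file.
#' @param feature_types character vector of feature types to keep
#'   (default `"CDS"`).
#' @param seqlengths optional named replicon lengths; features on
#'   replicons absent from it are rejected.
#' @return `GRanges` of gene models.
#' @export
readAnnotation <- function(path, feature_types = "CDS", seqlengths = NULL) {
    if (!file.exists(path)) fmtStop("no such file: %s", path)
    ## pre-scan for the errors we must report with a line reference
    lines <- readLines(path)
    body <- !startsWith(lines, "#") & nzchar(lines)
    for (i in which(body)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(f) < 9) next
        if (!(f[3] %in% feature_types)) next
        s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
        if (is.na(s) || is.na(e) || s > e)
            fmtStop("%s line %d: start > end (or non-numeric coordinates)", path, i)
        if (!grepl("(^|;)\\s*(ID|locus_tag)=", f[9]))
            fmtStop("%s line %d: feature has neither ID nor locus_tag", path, i)
    }
    gr <- rtracklayer::import.gff3(path)
    gr <- gr[as.character(gr$type) %in% feature_types]
    if (!is.null(seqlengths)) {
        unknown <- setdiff(unique(as.character(seqnames(gr))), names(seqlengths))
        if (length(unknown))
            fmtStop("%s: feature(s) on unknown replicon '%s'", path, unknown[1])
        out <- start(gr) < 1L |
            end(gr) > seqlengths[as.character(seqnames(gr))]
        if (any(out))
            fmtStop("%s: feature outside replicon bounds at %s:%d", path,
                    as.character(seqnames(gr))[out][1], start(gr)[out][1])
        gr <- GenomicRanges::GRanges(seqnames(gr), ranges(gr), strand(gr),
                                     S4Vectors::mcols(gr),
                                     seqlengths = seqlengths)
    }
    id <- if (!is.null(gr$locus_tag)) ifelse(is.na(gr$locus_tag) | gr$locus_tag == "",
                                             as.character(gr$ID), gr$locus_tag)
          else as.character(gr$ID)
    out <- GenomicRanges::granges(gr)
    out$gene_id <- id
    out$product <- if (!is.null(gr$product)) as.character(gr$product) else NA_character_
    out$is_small <- (BiocGenerics::width(out) / 3 - 1) <= 100
    out
}

#' Write gene models as GFF3
#' @param genes `GRanges` with a `gene_id` column (see [readAnnotation()]).
#' @param path output file.
#' @param feature_type GFF3 type column (default `"CDS"`).
#' @export
writeAnnotation <- function(genes, path, feature_type = "CDS") {
    gr <- GenomicRanges::granges(genes)
    gr$source <- "halotx"
    gr$type <- feature_type
    gr$ID <- genes$gene_id
    gr$locus_tag <- genes$gene_id
    if (!is.null(genes$product)) gr$product <- genes$product
    gr$phase <- 0L
    rtracklayer::export.gff3(gr, path)
    invisible(path)
}

#' Read one strand's wiggle coverage
#'
#' Understands both fixedStep and variableStep dialects (1-based
#' positions).  Positions absent from the file are 0.  Some pipelines
#' encode reverse-strand coverage as negative numbers; with
#' `sign_fold = TRUE` (default) magnitudes are taken, so either encoding
#' parses to the same non-negative track.
#'
#' @param path wiggle file.
#' @param seqlengths named replicon lengths used to allocate full-length
#'   vectors; positions beyond a declared length, or replicons not
#'   declared, are format errors.
#' @param sign_fold take absolute values of scores.
#' @return named list of per-base numeric vectors, one per replicon in
#'   `seqlengths` (zero-filled when the file has no data for it).
#' @export
readWiggle <- function(path, seqlengths, sign_fold = TRUE) {
    if (!file.exists(path)) fmtStop("no such file: %s", path)
    tracks <- lapply(seqlengths, function(n) numeric(n))
    lines <- readLines(path)
    if (!length(lines)) return(tracks)
    ## block declarations; everything in between is data for that block
    decl <- grepl("^(fixedStep|variableStep|track|browser|#)", lines)
    starts <- which(decl)
    ends <- c(starts[-1] - 1L, length(lines))
    field <- function(header, key) {
        m <- regmatches(header, regexec(paste0(key, "=([^ \t]+)"), header))[[1]]
        if (length(m) == 2) m[2] else NA_character_
    }
    fill <- function(rep, pos, val, span) {
        if (is.na(rep) || !(rep %in% names(seqlengths)))
            fmtStop("%s: coverage on undeclared replicon '%s'", path, rep)
        if (span > 1L) {
            val <- rep(val, each = span)
            pos <- rep(pos, each = span) + seq_len(span) - 1L
        }
        if (length(pos) && (min(pos) < 1L || max(pos) > seqlengths[[rep]]))
            fmtStop("%s: position beyond declared replicon length", path)
        tracks[[rep]][pos] <<- if (sign_fold) abs(val) else val
    }
    for (k in seq_along(starts)) {
        b <- starts[k]
        header <- lines[b]
        if (!grepl("^(fixedStep|variableStep)", header)) next
        body <- if (ends[k] > b) lines[(b + 1L):ends[k]] else character(0)
        body <- body[nzchar(body)]
        if (!length(body)) next
        rep <- field(header, "chrom")
        span <- as.integer(field(header, "span"))
        if (is.na(span)) span <- 1L
        if (startsWith(header, "fixedStep")) {
            from <- as.integer(field(header, "start"))
            step <- as.integer(field(header, "step"))
            if (is.na(step)) step <- 1L
            if (is.na(from))
                fmtStop("%s: fixedStep block without start=", path)
            val <- as.numeric(body)
            fill(rep, from + (seq_along(val) - 1L) * step, val, span)
        } else {
            parts <- strsplit(body, "[ \t]+")
            pos <- as.integer(vapply(parts, `[`, character(1), 1L))
            val <- as.numeric(vapply(parts, `[`, character(1), 2L))
            if (anyNA(pos) || anyNA(val))
                fmtStop("%s: malformed variableStep data line", path)
            fill(rep, pos, val, span)
        }
    }
    tracks
}

#' Write one strand's coverage as wiggle
#'
#' Emits only non-zero runs.  Both standard dialects are supported;
#' `negate = TRUE` writes negative scores (the common encoding for
#' reverse-strand files).
#'
#' @param tracks named list of per-base numeric vectors.
#' @param path output file.
#' @param dataFormat `"fixedStep"` or `"variableStep"`.
#' @param negate write `-value` instead of `value`.
#' @export
writeWiggle <- function(tracks, path,
                        dataFormat = c("fixedStep", "variableStep"),
                        negate = FALSE) {
    dataFormat <- match.arg(dataFormat)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=wiggle_0 name=\"%s\"", basename(path)), con)
    for (rep in names(tracks)) {
        v <- tracks[[rep]]
        if (negate) v <- -v
        nz <- v != 0
        if (!any(nz)) next
        r <- rle(nz)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        if (dataFormat == "fixedStep") {
            for (k in which(r$values)) {
                writeLines(sprintf("fixedStep chrom=%s start=%d step=1", rep, starts[k]), con)
                writeLines(format(v[starts[k]:ends[k]], trim = TRUE, scientific = FALSE), con)
            }
        } else {
            writeLines(sprintf("variableStep chrom=%s", rep), con)
            idx <- which(nz)
            writeLines(sprintf("%d\t%s", idx,
                               format(v[idx], trim = TRUE, scientific = FALSE)), con)
        }
    }
    invisible(path)
}

#' Read a pair of strand-specific wiggle files into a CoverageSet
#'
#' @param fwd_path,rev_path plus- and minus-strand wiggle files.
#' @param seqlengths named replicon lengths.
#' @param sign_fold see [readWiggle()].
#' @return A [CoverageSet-class].
#' @export
readCoverage <- function(fwd_path, rev_path, seqlengths, sign_fold = TRUE) {
    CoverageSet(fwd = readWiggle(fwd_path, seqlengths, sign_fold),
                rev = readWiggle(rev_path, seqlengths, sign_fold))
}

#' Write a CoverageSet as a pair of wiggle files
#' @param covset A [CoverageSet-class].
#' @param fwd_path,rev_path output files.
#' @param dataFormat wiggle dialect, see [writeWiggle()].
#' @param negate_rev encode the reverse strand with negative scores.
#' @export
writeCoverage <- function(covset, fwd_path, rev_path,
                          dataFormat = "fixedStep", negate_rev = FALSE) {
    writeWiggle(as.list(covset@fwd), fwd_path, dataFormat)
    writeWiggle(as.list(covset@rev), rev_path, dataFormat, negate = negate_rev)
    invisible(c(fwd_path, rev_path))
}

#' Read a TSS catalogue
#'
#' @param path TSV with header columns `replicon`, `strand`, `position`
#'   (1-based genomic coordinate of the transcription start site).
#' @param seqlengths optional named replicon lengths for bounds checking.
#' @return data.frame with those three columns.
#' @export
readTssTable <- function(path, seqlengths = NULL) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("replicon", "strand", "position")
    if (!all(need %in% names(d)))
        fmtStop("%s: TSS table needs columns %s", path, paste(need, collapse = ", "))
    if (!all(d$strand %in% c("+", "-")))
        fmtStop("%s: TSS strand must be + or -", path)
    if (!is.null(seqlengths)) {
        bad <- d$position < 1 | d$position > seqlengths[d$replicon]
        if (any(bad %in% TRUE) || anyNA(bad))
            fmtStop("%s: TSS position outside replicon bounds", path)
    }
    d[need]
}

#' Write a TSS catalogue
#' @param tss data.frame with `replicon`, `strand`, `position`.
#' @param path output TSV.
#' @export
writeTssTable <- function(tss, path) {
    utils::write.table(tss[c("replicon", "strand", "position")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## transcript-table columns, in file order
TX_TABLE_COLS <- c("transcript_id", "replicon", "strand", "start", "end",
                   "length", "class", "gene_ids", "n_orfs",
                   "overlapping_3prime", "tss_supported", "mean_coverage")

#' Write the transcript table
#'
#' The on-disk table uses 0-based half-open `start`/`end`, so the
#' `length` column always equals `end - start`.  `gene_ids` is a
#' comma-separated list; logical flags are written as TRUE/FALSE/NA.
#'
#' @param tx A [TranscriptSet-class].
#' @param path output TSV.
#' @export
writeTranscriptTable <- function(tx, path) {
    mc <- S4Vectors::mcols(tx)
    optcol <- function(name, default) if (!is.null(mc[[name]])) mc[[name]] else
        rep(default, length(tx))
    genes <- if (!is.null(mc$coveredGenes))
        vapply(mc$coveredGenes, paste, character(1), collapse = ",")
    else rep("", length(tx))
    d <- data.frame(
        transcript_id = as.character(txId(tx)),
        replicon = as.character(seqnames(tx)),
        strand = as.character(strand(tx)),
        start = start(tx) - 1L,            # 0-based half-open on disk
        end = end(tx),
        length = BiocGenerics::width(tx),
        class = txClass(tx),
        gene_ids = genes,
        n_orfs = optcol("nOrfs", NA_integer_),
        overlapping_3prime = optcol("overlapping3p", NA),
        tss_supported = optcol("tssSupported", NA),
        mean_coverage = mc$meanCoverage,
        stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a transcript table
#'
#' Inverse of [writeTranscriptTable()].  The `length` column is checked
#' against `end - start` (0-based half-open convention on disk).
#'
#' @param path TSV written by [writeTranscriptTable()].
#' @param seqlengths optional named replicon lengths attached as seqinfo.
#' @return A [TranscriptSet-class].
#' @export
readTranscriptTable <- function(path, seqlengths = NULL) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = list(gene_ids = "character"))
    miss <- setdiff(TX_TABLE_COLS, names(d))
    if (length(miss))
        fmtStop("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
    if (nrow(d) && any(d$length != d$end - d$start))
        fmtStop("%s: length column inconsistent with end - start at row %d",
                path, which(d$length != d$end - d$start)[1])
    gr <- GenomicRanges::GRanges(d$replicon,
                                 IRanges::IRanges(d$start + 1L, d$end),
                                 strand = d$strand)
    if (!is.null(seqlengths)) seqlengths(gr) <- seqlengths[seqlevels(gr)]
    gr$txId <- as.character(d$transcript_id)
    gr$meanCoverage <- d$mean_coverage
    gr$txClass <- d$class
    ids <- as.character(d$gene_ids)
    ids[is.na(ids)] <- ""
    gr$coveredGenes <- IRanges::CharacterList(
        lapply(strsplit(ids, ","), function(x) x[nzchar(x)]))
    gr$nOrfs <- as.integer(d$n_orfs)
    gr$overlapping3p <- as.logical(d$overlapping_3prime)
    gr$tssSupported <- as.logical(d$tss_supported)
    TranscriptSet(gr)
}

#' Import a published transcript-catalogue spreadsheet
#'
#' Best-effort importer for the supplementary-table layout that published
#' haloarchaeal transcriptome studies use: one row per predicted RNA with
#' its replicon, strand, genomic start/stop (1-based inclusive), length,
#' class, associated gene identifiers, number of genes on polycistronic
#' transcripts, a 3'-overlap flag and a flag for identification in a
#' previous dRNA-Seq study.  Column names are matched case-insensitively
#' by keyword, so modest layout drift is tolerated.  Requires the
#' `readxl` package for `.xlsx` input; TSV/CSV exports of the same layout
#' are read directly.
#'
#' @param path `.xlsx`, `.tsv` or `.csv` file.
#' @param sheet sheet index or name for xlsx input.
#' @return data.frame with normalised columns `replicon`, `strand`,
#'   `start`, `end`, `length`, `class`, `gene_ids`, `n_orfs`,
#'   `overlapping_3prime`, `drnaseq_flag` (those present in the file).
#' @export
importS2Table <- function(path, sheet = 1) {
    if (!file.exists(path)) fmtStop("no such file: %s", path)
    if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
        if (!requireNamespace("readxl", quietly = TRUE))
            fmtStop("reading xlsx requires the readxl package")
        d <- as.data.frame(readxl::read_excel(path, sheet = sheet))
    } else {
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
        d <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
    }
    pick <- function(...) {
        pats <- c(...)
        for (p in pats) {
            hit <- grep(p, names(d), ignore.case = TRUE)
            if (length(hit)) return(d[[hit[1]]])
        }
        NULL
    }
    num <- function(x) if (is.null(x)) NULL else suppressWarnings(as.numeric(x))
    out <- list(
        replicon = pick("^replicon", "chromosom", "^chr", "^seq"),
        strand   = pick("strand", "orientation"),
        start    = num(pick("^start", "begin", "from")),
        end      = num(pick("^stop", "^end", "to$")),
        length   = num(pick("length", "size")),
        class    = pick("class", "category", "type"),
        gene_ids = pick("hvo", "gene", "locus"),
        n_orfs   = num(pick("n_?orfs", "orfs", "genes.*transcript", "cistron")),
        overlapping_3prime = pick("overlap", "3.?.?utr.*overlap"),
        drnaseq_flag = pick("drna", "dRNA", "previous"))
    out <- out[!vapply(out, is.null, logical(1))]
    if (is.null(out$length) && !is.null(out$start) && !is.null(out$end))
        out$length <- abs(out$end - out$start) + 1
    as.data.frame(out, stringsAsFactors = FALSE)
}
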