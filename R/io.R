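# Readers and writers for the external formats the pipeline touches:
# FASTA, InterProScan TSV, FIMO TSV, MEME minimal motif format, GFF3,
# HMMER domtblout (C-JID hits). Coordinates are 1-based inclusive in every
# format and internally; nothing is converted.

#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet subseq
#' @importFrom utils read.table write.table
NULL

emptySignatureHits <- function() {
    data.frame(seq_id = character(), analysis = character(),
               accession = character(), description = character(),
               start = integer(), end = integer(), score = numeric(),
               extra = character(), stringsAsFactors = FALSE)
}

emptyMotifHits <- function() {
    data.frame(seq_id = character(), motif_id = character(),
               motif_alt_id = character(), start = integer(), end = integer(),
               score = numeric(), pvalue = numeric(), qvalue = numeric(),
               matched_seq = character(), stringsAsFactors = FALSE)
}

#' Read a protein FASTA file
#'
#' Sequences are uppercased, folded lines joined, record order preserved.
#' Genus/subclass metadata, when known, can be attached afterwards via
#' `S4Vectors::mcols()`.
#'
#' @param path FASTA file.
#' @return an `AAStringSet` named by the first whitespace-delimited token of
#'   each header.
#' @export
readProteinFasta <- function(path) {
    aa <- readAAStringSet(path)
    if (length(aa) == 0L) {
        warning("no sequences in ", path)
        return(aa)
    }
    names(aa) <- sub("\\s.*$", "", names(aa))
    dup <- names(aa)[duplicated(names(aa))]
    if (length(dup))
        stop("duplicate sequence ID(s): ", paste(unique(dup), collapse = ", "))
    AAStringSet(toupper(as.character(aa)))
}

#' Write a protein FASTA file
#' @param x named `AAStringSet` or named character vector.
#' @param path output file.
#' @export
writeProteinFasta <- function(x, path) {
    if (!is(x, "XStringSet")) x <- AAStringSet(x)
    writeXStringSet(x, path)
    invisible(path)
}

#' Parse an InterProScan-format TSV file
#'
#' Expects the InterProScan 5 tab-separated dialect with at least 9 columns
#' (protein id, md5, sequence length, analysis, signature accession,
#' description, start, stop, score, ...). Columns beyond 9 are preserved
#' unparsed in `extra`. A `"-"` score is mapped to `NA`.
#'
#' @param path TSV file.
#' @return data.frame with columns seq_id, analysis, accession, description,
#'   start, end, score, extra.
#' @export
parseInterproTsv <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) return(emptySignatureHits())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9L))
        stop(sprintf("malformed InterProScan line %d: %d column(s), need >= 9",
                     which(nf < 9L)[1L], nf[nf < 9L][1L]))
    pick <- function(i) vapply(fields, `[[`, "", i)
    start <- suppressWarnings(as.integer(pick(7)))
    end <- suppressWarnings(as.integer(pick(8)))
    if (anyNA(start) || anyNA(end))
        stop("non-integer start/stop at line ",
             which(is.na(start) | is.na(end))[1L])
    if (any(end < start))
        stop("stop < start at line ", which(end < start)[1L])
    score <- suppressWarnings(as.numeric(pick(9)))
    data.frame(
        seq_id = pick(1), analysis = pick(4), accession = pick(5),
        description = pick(6), start = start, end = end, score = score,
        extra = vapply(fields, function(f)
            paste(f[-seq_len(9L)], collapse = "\t"), ""),
        stringsAsFactors = FALSE)
}

#' Parse a FIMO-format TSV file
#'
#' Expects the meme-suite FIMO tab-separated dialect: motif_id, motif_alt_id,
#' sequence_name, start, stop, strand, score, p-value, q-value,
#' matched_sequence. A header line and `#` comment lines are tolerated.
#' The strand column is ignored (amino-acid scan).
#'
#' @param path TSV file.
#' @return data.frame with columns seq_id, motif_id, motif_alt_id, start,
#'   end, score, pvalue, qvalue, matched_seq.
#' @export
parseFimoTsv <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) && grepl("^motif_id\t", lines[1L])) {
        header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
        if (!any(grepl("^q-?value$", header)))
            stop("q-value column missing: q-values are required by the ",
                 "score/q-value filter (re-run the scan with q-values on)")
        lines <- lines[-1L]
    }
    if (!length(lines)) return(emptyMotifHits())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 10L))
        stop(sprintf("malformed FIMO line %d: %d column(s), need 10 ",
                     which(nf < 10L)[1L], nf[nf < 10L][1L]),
             "(q-values are required by the score/q-value filter)")
    pick <- function(i) vapply(fields, `[[`, "", i)
    data.frame(
        seq_id = pick(3), motif_id = pick(1), motif_alt_id = pick(2),
        start = as.integer(pick(4)), end = as.integer(pick(5)),
        score = as.numeric(pick(7)), pvalue = as.numeric(pick(8)),
        qvalue = as.numeric(pick(9)), matched_seq = pick(10),
        stringsAsFactors = FALSE)
}

#' Write motif hits as a FIMO-compatible TSV
#'
#' Inverse of [parseFimoTsv()]; enables drop-in replacement of a real FIMO
#' run by [scanMotifs()] output.
#'
#' @param hits motif-hit data.frame.
#' @param path output file.
#' @export
writeFimoTsv <- function(hits, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("motif_id", "motif_alt_id", "sequence_name", "start",
                     "stop", "strand", "score", "p-value", "q-value",
                     "matched_sequence", sep = "\t"), con)
    if (nrow(hits))
        writeLines(paste(hits$motif_id, hits$motif_alt_id, hits$seq_id,
                         hits$start, hits$end, "+",
                         format(hits$score, trim = TRUE),
                         format(hits$pvalue, trim = TRUE),
                         format(hits$qvalue, trim = TRUE),
                         hits$matched_seq, sep = "\t"), con)
    invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections. Every
#' matrix row must sum to 1 within 1e-3; alphabet order is preserved.
#'
#' @param path MEME minimal-format file.
#' @param background background distribution passed to [PWMotif()]; default
#'   uniform. A `Background letter frequencies` section in the file, when
#'   present, takes precedence.
#' @param pseudocount pseudocount for log-odds scoring.
#' @return named list of [PWMotif-class] objects (names = motif ids).
#' @export
readMemeMotifs <- function(path, background = NULL, pseudocount = 1e-4) {
    lines <- readLines(path)
    alpha_line <- grep("^ALPHABET\\s*=", lines, value = TRUE)
    alphabet <- if (length(alpha_line)) {
        strsplit(trimws(sub("^ALPHABET\\s*=", "", alpha_line[1L])), "")[[1L]]
    } else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    bg_i <- grep("^Background letter frequencies", lines)
    if (length(bg_i)) {
        toks <- character()
        j <- bg_i[1L] + 1L
        while (j <= length(lines) && !startsWith(lines[j], "MOTIF") &&
               nzchar(trimws(lines[j]))) {
            toks <- c(toks, strsplit(trimws(lines[j]), "\\s+")[[1L]])
            j <- j + 1L
        }
        background <- as.numeric(toks[seq(2, length(toks), 2)])
        names(background) <- toks[seq(1, length(toks), 2)]
    }
    motif_i <- grep("^MOTIF\\b", lines)
    out <- list()
    for (mi in motif_i) {
        toks <- strsplit(trimws(lines[mi]), "\\s+")[[1L]]
        id <- toks[2L]
        alt <- if (length(toks) >= 3L) toks[3L] else NA_character_
        hi <- grep("letter-probability matrix", lines)
        hi <- hi[hi > mi][1L]
        if (is.na(hi))
            stop("motif ", id, ": no letter-probability matrix block")
        w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[hi]))
        rows <- lines[(hi + 1L):(hi + w)]
        m <- t(vapply(rows, function(r)
            as.numeric(strsplit(trimws(r), "\\s+")[[1L]]),
            numeric(length(alphabet))))
        dimnames(m) <- list(NULL, alphabet)
        rs <- rowSums(m)
        bad <- which(abs(rs - 1) > 1e-3)
        if (length(bad))
            stop(sprintf("motif %s: matrix row %d sums to %.4g, not 1",
                         id, bad[1L], rs[bad[1L]]))
        out[[id]] <- PWMotif(id, m, background = background,
                             pseudocount = pseudocount, alt_id = alt)
    }
    out
}

#' Write motifs in MEME minimal format
#' @param pwms list of [PWMotif-class] objects.
#' @param path output file.
#' @export
writeMemeMotifs <- function(pwms, path) {
    con <- file(path, "w")
    on.exit(close(con))
    alphabet <- colnames(pwms[[1L]]@matrix)
    writeLines(c("MEME version 5",
                 "",
                 paste0("ALPHABET= ", paste(alphabet, collapse = "")),
                 ""), con)
    for (pwm in pwms) {
        m <- pwm@matrix
        writeLines(sprintf("MOTIF %s%s", pwm@motif_id,
                           if (is.na(pwm@alt_id)) "" else paste0(" ", pwm@alt_id)),
                   con)
        writeLines(sprintf(
            "letter-probability matrix: alength= %d w= %d nsites= 20 E= 0",
            ncol(m), nrow(m)), con)
        writeLines(apply(m, 1L, function(r)
            paste(sprintf("%.6f", r), collapse = " ")), con)
        writeLines("", con)
    }
    invisible(path)
}

#' Read C-JID hits from a HMMER domtblout table
#'
#' Minimal reader for per-domain HMMER3 `--domtblout` output: only the
#' target name and the alignment coordinates (columns 18-19) are used.
#'
#' @param path domtblout file.
#' @return data.frame with columns seq_id, start, end.
#' @export
readCjidDomtbl <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines))
        return(data.frame(seq_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE))
    fields <- strsplit(trimws(lines), "\\s+")
    if (any(lengths(fields) < 19L))
        stop("domtblout line with fewer than 19 columns")
    data.frame(
        seq_id = vapply(fields, `[[`, "", 1L),
        start = as.integer(vapply(fields, `[[`, "", 18L)),
        end = as.integer(vapply(fields, `[[`, "", 19L)),
        stringsAsFactors = FALSE)
}

#' Write annotation as GFF3
#'
#' One `protein_match` feature per domain call and per retained motif hit,
#' 1-based inclusive coordinates, source column naming the evidence origin,
#' attributes carrying the category and accession. Features are sorted by
#' sequence id then start.
#'
#' @param proteins named `AAStringSet` (or named character vector of
#'   sequences) the calls refer to.
#' @param calls domain-call data.frame (seq_id, category, start, end, and
#'   optionally accession).
#' @param path output file.
#' @param motif_hits optional motif-hit data.frame written as
#'   `sequence_motif` features.
#' @export
writeGff3 <- function(proteins, calls, path, motif_hits = NULL) {
    ids <- names(proteins)
    if (nrow(calls) && !all(calls$seq_id %in% ids))
        stop("domain call references unknown sequence: ",
             paste(setdiff(calls$seq_id, ids), collapse = ", "))
    if (!is.null(motif_hits) && nrow(motif_hits) &&
        !all(motif_hits$seq_id %in% ids))
        stop("motif hit references unknown sequence")
    enc <- function(x) gsub("([;=&,])", "%\\1", x)
    feat <- character()
    if (nrow(calls)) {
        acc <- if ("accession" %in% names(calls)) calls$accession else
            calls$category
        src <- if ("analysis" %in% names(calls)) calls$analysis else
            "plantNLR"
        feat <- c(feat, paste(calls$seq_id, src, "protein_match",
                              calls$start, calls$end, ".", ".", ".",
                              sprintf("Name=%s;category=%s",
                                      enc(acc), enc(calls$category)),
                              sep = "\t"))
        ord <- order(calls$seq_id, calls$start)
        feat <- feat[ord]
    }
    mfeat <- character()
    if (!is.null(motif_hits) && nrow(motif_hits)) {
        mfeat <- paste(motif_hits$seq_id, "motif-scan", "sequence_motif",
                       motif_hits$start, motif_hits$end,
                       format(motif_hits$score, trim = TRUE), ".", ".",
                       sprintf("Name=motif_%s;qvalue=%s",
                               enc(motif_hits$motif_id),
                               format(motif_hits$qvalue, trim = TRUE)),
                       sep = "\t")
        mfeat <- mfeat[order(motif_hits$seq_id, motif_hits$start)]
    }
    writeLines(c("##gff-version 3", feat, mfeat), path)
    invisible(path)
}

#' Parse a GFF3 annotation written by [writeGff3()]
#'
#' @param path GFF3 file.
#' @return data.frame with columns seq_id, source, type, start, end, score,
#'   attributes.
#' @export
parseGff3 <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines))
        return(data.frame(seq_id = character(), source = character(),
                          type = character(), start = integer(),
                          end = integer(), score = character(),
                          attributes = character(), stringsAsFactors = FALSE))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 9L))
        stop("GFF3 line without 9 columns")
    pick <- function(i) vapply(fields, `[[`, "", i)
    data.frame(seq_id = pick(1), source = pick(2), type = pick(3),
               start = as.integer(pick(4)), end = as.integer(pick(5)),
               score = pick(6), attributes = pick(9),
               stringsAsFactors = FALSE)
}
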