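# Alignment preparation for downstream phylogenetics: column-coverage
# trimming, length statistics with 2-SD outlier flagging, grouped counts,
# and relaxed PHYLIP round-trip I/O.

#' @importFrom stats sd
NULL

#' Trim alignment columns by site coverage
#'
#' A column is kept iff its site coverage (fraction of rows with a non-gap
#' character) is at least `min_coverage`; a column at exactly the threshold
#' is kept. `-` and `.` count as gaps; `X` counts as coverage. Row order is
#' preserved and the operation is idempotent.
#'
#' @param aln named `AAStringSet` or named character vector of equal-length
#'   gapped sequences.
#' @param min_coverage minimum fraction of non-gap rows (default 0.95).
#' @return trimmed alignment of the same class as the input rows allow
#'   (`AAStringSet`). A zero-column result triggers a warning.
#' @export
trimColumns <- function(aln, min_coverage = 0.95) {
    seqs <- as.character(aln)
    if (!length(seqs)) stop("empty alignment")
    if (length(unique(nchar(seqs))) != 1L)
        stop("alignment rows differ in length")
    m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
    cov <- 1 - colMeans(m == "-" | m == ".")
    keep <- cov >= min_coverage
    if (!any(keep)) {
        warning("no column reaches ", min_coverage, " coverage; ",
                "empty alignment returned")
        out <- rep("", length(seqs))
    } else {
        out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
    }
    names(out) <- names(aln)
    AAStringSet(out)
}

#' Sequence length statistics with 2-SD outlier flagging
#'
#' Sample mean and standard deviation (denominator n-1) of sequence lengths;
#' sequences with `|length - mean| > 2 * sd` are flagged as outliers.
#'
#' @param records named `AAStringSet` or named character vector.
#' @return list with n, mean, sd, min, max, outlier_ids.
#' @export
lengthStats <- function(records) {
    if (!length(records)) stop("no sequences")
    len <- nchar(as.character(records))
    mu <- mean(len)
    s <- if (length(len) > 1L) sd(len) else 0
    out_ids <- names(records)[abs(len - mu) > 2 * s & s > 0]
    list(n = length(len), mean = mu, sd = s, min = min(len), max = max(len),
         outlier_ids = out_ids)
}

#' Grouped sequence counts
#'
#' Counts per metadata value (e.g. genus or subclass), ordered by
#' descending count then name; missing values are bucketed as "unknown".
#'
#' @param values character vector of per-sequence metadata (genus, subclass,
#'   ...).
#' @return data.frame key, count (counts sum to `length(values)`).
#' @export
groupCounts <- function(values) {
    if (!length(values))
        return(data.frame(key = character(), count = integer(),
                          stringsAsFactors = FALSE))
    values[is.na(values) | !nzchar(values)] <- "unknown"
    tab <- table(values)
    out <- data.frame(key = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$key), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Share of the k largest groups
#'
#' Percentage of sequences falling in the `k` most populous groups, one
#' decimal (half-up).
#'
#' @param values per-sequence metadata vector.
#' @param k number of top groups.
#' @return percentage.
#' @export
topGroupShare <- function(values, k) {
    counts <- groupCounts(values)
    roundHalfUp(100 * sum(counts$count[seq_len(min(k, nrow(counts)))]) /
                    sum(counts$count))
}

#' Write an alignment in relaxed PHYLIP format
#'
#' Header line "n m", then one sequence per line as "ID  SEQUENCE" with full
#' (untruncated) IDs.
#'
#' @param aln named `AAStringSet` or named character vector, equal lengths.
#' @param path output file.
#' @export
writePhylip <- function(aln, path) {
    seqs <- as.character(aln)
    if (length(unique(nchar(seqs))) > 1L)
        stop("alignment rows differ in length")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", length(seqs),
                       if (length(seqs)) nchar(seqs[1L]) else 0L), con)
    writeLines(sprintf("%s  %s", names(aln), seqs), con)
    invisible(path)
}

#' Read a relaxed PHYLIP alignment
#' @param path PHYLIP file as written by [writePhylip()].
#' @return named `AAStringSet`.
#' @export
readPhylip <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
    if (length(hdr) != 2L || anyNA(hdr))
        stop("malformed PHYLIP header")
    n <- hdr[1L]; m <- hdr[2L]
    body <- lines[-1L]
    if (length(body) != n)
        stop("PHYLIP header announces ", n, " rows, file has ", length(body))
    toks <- strsplit(trimws(body), "\\s+")
    ids <- vapply(toks, `[[`, "", 1L)
    seqs <- vapply(toks, function(t) paste(t[-1L], collapse = ""), "")
    if (any(nchar(seqs) != m))
        stop("PHYLIP row length differs from header column count")
    names(seqs) <- ids
    AAStringSet(seqs)
}
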