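# Amino-acid PWM scanner: log2 log-odds window scores, exact p-values by
# dynamic programming over the quantized score distribution under the
# background model, pooled Benjamini-Hochberg q-values, and the score /
# q-value threshold filter with the stricter extraction cutoff for the
# linker and MHD motifs.

#' @importFrom stats p.adjust
NULL

# log-odds matrix: log2((p + pseudocount) / background), positions x letters
logOddsMatrix <- function(pwm) {
    lo <- log2(sweep(pwm@matrix + pwm@pseudocount, 2L,
                     pwm@background[colnames(pwm@matrix)], "/"))
    lo
}

#' Score every window of a sequence against a PWM
#'
#' The window score is the sum over motif positions of
#' `log2((p + pseudocount) / background)`. Letters outside the motif
#' alphabet (e.g. `X`) contribute log-odds 0, i.e. score as background.
#'
#' @param pwm a [PWMotif-class].
#' @param sequence a single amino-acid string (or `AAString`).
#' @return data.frame with one row per start position 1..n-L+1, columns
#'   `position` and `score`; zero rows if the sequence is shorter than the
#'   motif.
#' @export
scoreSequence <- function(pwm, sequence) {
    sequence <- as.character(sequence)
    lo <- logOddsMatrix(pwm)
    L <- nrow(lo)
    letters_ <- strsplit(sequence, "")[[1L]]
    n <- length(letters_)
    if (n < L)
        return(data.frame(position = integer(), score = numeric()))
    col <- match(letters_, colnames(lo))   # NA for out-of-alphabet letters
    nw <- n - L + 1L
    score <- numeric(nw)
    for (j in seq_len(L)) {
        cj <- col[j:(j + nw - 1L)]
        contrib <- ifelse(is.na(cj), 0, lo[j, ifelse(is.na(cj), 1L, cj)])
        score <- score + contrib
    }
    data.frame(position = seq_len(nw), score = score)
}

#' Exact score-to-p-value table for a PWM
#'
#' Computes, by dynamic programming over integer-quantized scores, the full
#' distribution of the window score of a random L-mer drawn from the
#' background model, and returns the upper-tail probability
#' `p(s) = P(score >= s)`. p is monotone non-increasing in s and equals 1 at
#' the minimum attainable score.
#'
#' @param pwm a [PWMotif-class].
#' @param granularity quantization step in bits (default 1/1000 bit).
#' @return data.frame with columns `score` (quantized attainable score) and
#'   `pvalue`, sorted by increasing score; attributes `granularity` is set.
#' @export
scorePvalueTable <- function(pwm, granularity = 0.001) {
    lo <- logOddsMatrix(pwm)
    q <- round(lo / granularity)           # integer scores, positions x letters
    bg <- pwm@background[colnames(lo)]
    lo_min <- sum(apply(q, 1L, min))
    lo_max <- sum(apply(q, 1L, max))
    span <- lo_max - lo_min + 1L
    # dist[k] = P(total quantized score == lo_min + k - 1) after processed rows
    dist <- numeric(span)
    dist[1L] <- 1
    off_min <- 0L                          # current minimum relative to lo_min
    cur_min <- 0L; cur_max <- 0L           # current attainable bounds (relative)
    pos_min <- apply(q, 1L, min)
    for (j in seq_len(nrow(q))) {
        newdist <- numeric(span)
        shift_base <- q[j, ] - pos_min[j]  # non-negative shifts
        width <- cur_max - cur_min + 1L
        idx <- seq_len(width)
        for (a in seq_along(bg)) {
            s <- shift_base[a]
            newdist[idx + s] <- newdist[idx + s] + bg[a] * dist[idx]
        }
        dist <- newdist
        cur_max <- cur_max + max(shift_base)
    }
    probs <- dist[seq_len(cur_max - cur_min + 1L)]
    scores_int <- lo_min + seq_along(probs) - 1L
    keep <- probs > 0
    pv <- rev(cumsum(rev(probs)))
    pv <- pmin(pv, 1)
    out <- data.frame(score = scores_int[keep] * granularity,
                      pvalue = pv[keep])
    attr(out, "granularity") <- granularity
    out
}

#' Look up p-values for observed scores
#'
#' @param table output of [scorePvalueTable()].
#' @param score numeric vector of window scores.
#' @return p-values `P(random window score >= score)` under the background
#'   model, at the table's quantization.
#' @export
pvalueFromScore <- function(table, score) {
    gran <- attr(table, "granularity")
    qs <- round(score / gran) * gran
    # p(s) = pvalue at the smallest attainable score >= s; above the maximum
    # attainable score the tail is empty
    idx <- findInterval(qs - gran / 2, table$score) + 1L
    out <- numeric(length(score))
    inside <- idx <= nrow(table)
    out[inside] <- table$pvalue[idx[inside]]
    out[!inside] <- 0
    # scores at or below the minimum have p = 1
    out[qs <= table$score[1L]] <- 1
    out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment: `q_i = min over p_j >= p_i of p_j * n / rank_j`.
#' q >= p elementwise and q is monotone non-decreasing in p; invariant under
#' input permutation. `n_tests` allows adjusting a retained subset of a
#' larger testing family (as a motif scan does when only top windows are
#' reported).
#'
#' @param pvalues numeric vector, all in (0, 1].
#' @param n_tests size of the testing family (default `length(pvalues)`).
#' @return q-values in input order.
#' @export
bhQvalues <- function(pvalues, n_tests = length(pvalues)) {
    if (!length(pvalues)) return(numeric())
    if (any(pvalues <= 0 | pvalues > 1 | is.na(pvalues)))
        stop("p-values must lie in (0, 1]")
    if (n_tests == length(pvalues))
        return(p.adjust(pvalues, method = "BH"))
    n_tests <- max(n_tests, length(pvalues))
    k <- length(pvalues)
    o <- order(pvalues, decreasing = TRUE)
    ro <- order(o)
    # retained p-values are the k smallest of the family, so the rank of the
    # t-th largest retained p within the full family is k - t + 1
    rank_ <- k - seq_len(k) + 1
    pmin(1, cummin(n_tests / rank_ * pvalues[o]))[ro]
}

#' Scan protein sequences with a set of PWMs
#'
#' FIMO-equivalent scan: every window of every sequence is scored against
#' every motif; exact p-values come from [scorePvalueTable()]; q-values are
#' Benjamini-Hochberg over the pooled testing family of the whole scan (all
#' windows of all sequences and motifs). Hits with p-value at most
#' `report_pmax` are reported.
#'
#' @param pwms list of [PWMotif-class] objects.
#' @param proteins named `AAStringSet` or named character vector.
#' @param report_pmax report windows with p-value <= this (default 1e-4,
#'   the conventional scan report threshold).
#' @param granularity p-value quantization, see [scorePvalueTable()].
#' @return motif-hit data.frame (seq_id, motif_id, motif_alt_id, start, end,
#'   score, pvalue, qvalue, matched_seq) sorted by motif then sequence then
#'   start.
#' @export
scanMotifs <- function(pwms, proteins, report_pmax = 1e-4,
                       granularity = 0.001) {
    seqs <- as.character(proteins)
    ids <- names(proteins)
    hits <- list()
    total_windows <- 0
    for (pwm in pwms) {
        tab <- scorePvalueTable(pwm, granularity)
        L <- motifLength(pwm)
        for (i in seq_along(seqs)) {
            sw <- scoreSequence(pwm, seqs[[i]])
            if (!nrow(sw)) next
            total_windows <- total_windows + nrow(sw)
            pv <- pvalueFromScore(tab, sw$score)
            keep <- pv <= report_pmax
            if (!any(keep)) next
            hits[[length(hits) + 1L]] <- data.frame(
                seq_id = ids[i], motif_id = pwm@motif_id,
                motif_alt_id = pwm@alt_id,
                start = sw$position[keep], end = sw$position[keep] + L - 1L,
                score = sw$score[keep], pvalue = pv[keep],
                qvalue = NA_real_,
                matched_seq = substring(seqs[[i]], sw$position[keep],
                                        sw$position[keep] + L - 1L),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(hits)) return(emptyMotifHits())
    out <- do.call(rbind, hits)
    out$pvalue <- pmax(out$pvalue, .Machine$double.xmin)
    out$qvalue <- bhQvalues(out$pvalue, n_tests = total_windows)
    out[order(out$motif_id, out$seq_id, out$start), , drop = FALSE]
}

#' Filter motif hits by score and q-value thresholds
#'
#' Keeps hits with `score >= score_min` and `qvalue <= q_max`. Hits from the
#' strict motifs (linker and MHD by default) additionally need
#' `score >= strict_score_min` to count as NB-ARC extraction evidence; such
#' sub-threshold hits are kept in the annotation but flagged
#' `extraction_eligible = FALSE` so the classifier ignores them.
#'
#' @param hits motif-hit data.frame.
#' @param score_min minimum log-odds score (default 60).
#' @param q_max maximum BH q-value (default 0.01).
#' @param strict_motifs motif ids under the stricter cutoff (default the
#'   MHD and linker motifs, ids 7 and 8).
#' @param strict_score_min the stricter score cutoff (default 85).
#' @return subset of `hits` with an added logical `extraction_eligible`
#'   column. Filtering is idempotent.
#' @export
filterMotifHits <- function(hits, score_min = 60, q_max = 0.01,
                            strict_motifs = strictMotifIds(),
                            strict_score_min = 85) {
    if (!nrow(hits)) {
        hits$extraction_eligible <- logical()
        return(hits)
    }
    keep <- hits$score >= score_min & hits$qvalue <= q_max
    out <- hits[keep, , drop = FALSE]
    strict <- as.character(out$motif_id) %in% as.character(strict_motifs)
    out$extraction_eligible <- !strict | out$score >= strict_score_min
    rownames(out) <- NULL
    out
}
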