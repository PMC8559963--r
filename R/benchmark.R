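# Benchmarking metrics for NLR annotation tools: retrieval sensitivity,
# annotation specificity, domain-architecture accuracy under the canonical
# comparison rules (only T/C/R/N/L considered, repeats compressed), and
# exact-subset intersection tallies across tools.

#' Round half up to one decimal
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded values (half-up, matching reported percentage style).
#' @export
roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

#' Canonicalize an architecture string for benchmarking
#'
#' Only the TIR (T), Rx-type CC (C), RPW8-type CC (R), NB-ARC (N) and LRR
#' (L) domains are compared: every other letter (late blight R1 "1",
#' C-JID "J", integrated/other "O") is removed, then adjacent duplicate
#' letters are collapsed. Idempotent.
#'
#' @param arch character vector of architecture strings.
#' @return canonical strings.
#' @export
canonicalizeArchitecture <- function(arch) {
    vapply(arch, function(a) {
        if (is.na(a)) return("")
        l <- strsplit(a, "")[[1L]]
        l <- l[l %in% c("T", "C", "R", "N", "L")]
        if (!length(l)) return("")
        keep <- c(TRUE, l[-1L] != l[-length(l)])
        paste(l[keep], collapse = "")
    }, "", USE.NAMES = FALSE)
}

#' Retrieval sensitivity
#'
#' Percentage of the reference set retrieved: `100 * retrieved / total`,
#' reported to one decimal (half-up).
#'
#' @param retrieved,total non-negative counts, `retrieved <= total`,
#'   `total > 0`.
#' @return percentage.
#' @export
sensitivity <- function(retrieved, total) {
    if (total <= 0) stop("total must be positive")
    if (retrieved < 0 || retrieved > total)
        stop("retrieved must be between 0 and total")
    roundHalfUp(100 * retrieved / total)
}

#' Annotation specificity
#'
#' Percentage of retrieved sequences that are genuine:
#' `100 * TP / (TP + FP)`, one decimal (half-up).
#'
#' @param true_positives,false_positives non-negative counts with
#'   `TP + FP > 0`.
#' @return percentage.
#' @export
specificity <- function(true_positives, false_positives) {
    tot <- true_positives + false_positives
    if (tot <= 0) stop("no retrieved sequences: specificity undefined")
    roundHalfUp(100 * true_positives / tot)
}

#' Domain-architecture annotation accuracy
#'
#' Compares predicted to reference architectures after canonicalization.
#' Per reference ID the verdict is: `correct` if retrieved and the canonical
#' strings are equal, `other` if retrieved but flagged as not reliably
#' classified, `incorrect` if retrieved and unequal, `missing` otherwise.
#' Accuracy = 100 * correct / reference size.
#'
#' @param predictions data.frame with columns seq_id, architecture and
#'   optionally `reliable` (logical; FALSE marks the "other" verdict).
#' @param reference data.frame with columns seq_id, architecture and
#'   optionally subclass.
#' @return list with `verdicts` (data.frame seq_id, verdict, and subclass if
#'   supplied), `accuracy_pct`, `counts`, and `by_subclass` (when subclass
#'   labels are present).
#' @export
architectureAccuracy <- function(predictions, reference) {
    ref_arch <- canonicalizeArchitecture(reference$architecture)
    pred_idx <- match(reference$seq_id, predictions$seq_id)
    retrieved <- !is.na(pred_idx)
    pred_arch <- rep(NA_character_, nrow(reference))
    pred_arch[retrieved] <-
        canonicalizeArchitecture(predictions$architecture[pred_idx[retrieved]])
    reliable <- rep(TRUE, nrow(reference))
    if ("reliable" %in% names(predictions))
        reliable[retrieved] <- predictions$reliable[pred_idx[retrieved]]
    verdict <- ifelse(!retrieved, "missing",
                      ifelse(!reliable, "other",
                             ifelse(pred_arch == ref_arch, "correct",
                                    "incorrect")))
    verdicts <- data.frame(seq_id = reference$seq_id, verdict = verdict,
                           stringsAsFactors = FALSE)
    counts <- table(factor(verdict,
                           levels = c("correct", "incorrect", "other",
                                      "missing")))
    out <- list(verdicts = verdicts,
                accuracy_pct = roundHalfUp(100 * counts[["correct"]] /
                                               nrow(reference)),
                counts = counts)
    if ("subclass" %in% names(reference)) {
        verdicts$subclass <- reference$subclass
        out$verdicts <- verdicts
        out$by_subclass <- do.call(rbind, lapply(
            split(verdicts, verdicts$subclass), function(v)
                data.frame(subclass = v$subclass[1L], n = nrow(v),
                           correct = sum(v$verdict == "correct"),
                           accuracy_pct = roundHalfUp(
                               100 * sum(v$verdict == "correct") / nrow(v)),
                           stringsAsFactors = FALSE)))
        rownames(out$by_subclass) <- NULL
    }
    out
}

#' Exact-subset intersection counts across tools
#'
#' For every non-empty subset of tools, the number of IDs retrieved by
#' exactly that subset (the quantity an UpSet plot displays). Counts sum to
#' the union cardinality.
#'
#' @param tool_sets named list of character vectors of retrieved IDs.
#' @return data.frame with columns tools (tool names joined by "+", sorted)
#'   and count; only non-empty subsets with non-zero count appear.
#' @export
intersectionCounts <- function(tool_sets) {
    stopifnot(length(tool_sets) >= 1L)
    all_ids <- unique(unlist(tool_sets, use.names = FALSE))
    if (!length(all_ids))
        return(data.frame(tools = character(), count = integer(),
                          stringsAsFactors = FALSE))
    member <- vapply(tool_sets, function(s) all_ids %in% s,
                     logical(length(all_ids)))
    if (is.null(dim(member))) member <- matrix(member, nrow = 1L)
    pattern <- apply(member, 1L, function(row)
        paste(names(tool_sets)[row], collapse = "+"))
    tab <- table(pattern)
    out <- data.frame(tools = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$tools), , drop = FALSE]
    rownames(out) <- NULL
    out
}
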