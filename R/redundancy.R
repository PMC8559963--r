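# Greedy identity-threshold clustering in the CD-HIT style: sequences sorted
# by length descending, each joining the first cluster whose representative
# it matches at or above the threshold, with exact global alignment instead
# of a word filter, plus per-genus representative assignment.

#' @importFrom Biostrings pairwiseAlignment nmatch
NULL

identitySubstitutionMatrix <- function() {
    letters_ <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X", "*", "-",
                  "B", "Z", "J", "U", "O")
    m <- diag(1, length(letters_))
    dimnames(m) <- list(letters_, letters_)
    m
}

#' Pairwise global sequence identity
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch 0, linear gap
#' penalty 1; identity = identical aligned residue pairs divided by the
#' length of the shorter sequence (the CD-HIT convention). Symmetric.
#'
#' @param a,b amino-acid strings (or `AAString`s).
#' @return identity fraction in \[0, 1\].
#' @export
pairwiseIdentity <- function(a, b) {
    a <- as.character(a); b <- as.character(b)
    aln <- pairwiseAlignment(a, b, type = "global",
                             substitutionMatrix = identitySubstitutionMatrix(),
                             gapOpening = 0, gapExtension = 1)
    nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy identity-threshold clustering
#'
#' Records are sorted by length descending (ties by ID); each record joins
#' the first existing cluster whose representative it matches at
#' `>= threshold` identity, otherwise it seeds a new cluster and becomes its
#' representative. Deterministic and invariant to input order.
#'
#' @param records named `AAStringSet` or named character vector.
#' @param threshold identity threshold in (0.5, 1] (default 0.90).
#' @return data.frame with columns cluster (1-based index), seq_id,
#'   identity (to the representative), representative (logical).
#' @export
greedyCluster <- function(records, threshold = 0.90) {
    stopifnot(threshold > 0.5, threshold <= 1)
    seqs <- as.character(records)
    ids <- names(records)
    ord <- order(-nchar(seqs), ids)
    seqs <- seqs[ord]; ids <- ids[ord]
    rep_seq <- character(); rep_id <- character()
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        assigned <- FALSE
        for (k in seq_along(rep_seq)) {
            idn <- pairwiseIdentity(rep_seq[k], seqs[i])
            if (idn >= threshold) {
                rows[[i]] <- data.frame(cluster = k, seq_id = ids[i],
                                        identity = idn,
                                        representative = FALSE,
                                        stringsAsFactors = FALSE)
                assigned <- TRUE
                break
            }
        }
        if (!assigned) {
            rep_seq <- c(rep_seq, seqs[i]); rep_id <- c(rep_id, ids[i])
            rows[[i]] <- data.frame(cluster = length(rep_seq),
                                    seq_id = ids[i], identity = 1,
                                    representative = TRUE,
                                    stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$cluster, -out$representative, out$seq_id), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-genus cluster representatives
#'
#' For each (cluster, genus) pair one member is retained: the cluster
#' representative for its own genus, and the longest member (ties broken by
#' lexicographic ID) for every other genus present in the cluster. Members
#' without a genus each form their own pseudo-genus.
#'
#' @param clusters output of [greedyCluster()].
#' @param records the clustered sequences (named, for lengths).
#' @param genus named character vector seq_id -> genus (missing/NA allowed).
#' @return data.frame cluster, genus, seq_id of the retained
#'   representatives, one row per (cluster, genus).
#' @export
perGenusRepresentatives <- function(clusters, records, genus = NULL) {
    if (!nrow(clusters))
        return(data.frame(cluster = integer(), genus = character(),
                          seq_id = character(), stringsAsFactors = FALSE))
    len <- nchar(as.character(records))[match(clusters$seq_id,
                                              names(records))]
    g <- if (is.null(genus)) rep(NA_character_, nrow(clusters)) else
        unname(genus[clusters$seq_id])
    g[is.na(g) | !nzchar(g)] <- paste0("unknown:",
                                       clusters$seq_id[is.na(g) | !nzchar(g)])
    df <- cbind(clusters, genus = g, len = len)
    out <- lapply(split(df, df$cluster), function(cl) {
        rep_row <- cl[cl$representative, , drop = FALSE][1L, ]
        do.call(rbind, lapply(split(cl, cl$genus), function(cg) {
            pick <- if (rep_row$genus %in% cg$genus) {
                rep_row$seq_id
            } else {
                cg <- cg[order(-cg$len, cg$seq_id), , drop = FALSE]
                cg$seq_id[1L]
            }
            data.frame(cluster = cl$cluster[1L], genus = cg$genus[1L],
                       seq_id = pick, stringsAsFactors = FALSE)
        }))
    })
    out <- do.call(rbind, out)
    out <- out[order(out$cluster, out$genus), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write clusters in CD-HIT .clstr-like TSV form
#' @param clusters output of [greedyCluster()].
#' @param path output file.
#' @export
writeClusterTsv <- function(clusters, path) {
    write.table(clusters, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
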