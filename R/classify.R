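# Rule-based NLR classification: merge signature evidence into domain calls,
# detect NB-ARC regions as overlap chains of the extraction signature set
# supported by NB-ARC-specific signatures or motifs, assign each protein one
# of the seven categories, build the compressed architecture string, and
# extract the NB-ARC subsequences.

#' @importFrom IRanges IRanges reduce findOverlaps start end width
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Merge evidence intervals of one category into domain calls
#'
#' Overlapping or near-adjacent intervals (gap <= `gap` residues) on the
#' same sequence are merged into a single call; split hits from the same
#' structural domain (common for Gene3D) are thereby joined. Output is
#' sorted by sequence then start and is disjoint beyond the gap tolerance.
#'
#' @param hits data.frame with columns seq_id, start, end (all hits assumed
#'   to belong to one category).
#' @param category category label stamped on the calls.
#' @param gap maximum residue gap bridged when merging (default 20).
#' @return data.frame seq_id, category, start, end, n_evidence.
#' @export
mergeCategoryIntervals <- function(hits, category, gap = 20L) {
    if (!nrow(hits))
        return(data.frame(seq_id = character(), category = character(),
                          start = integer(), end = integer(),
                          n_evidence = integer(), stringsAsFactors = FALSE))
    out <- lapply(split(hits, hits$seq_id), function(h) {
        r <- reduce(IRanges(h$start, h$end), min.gapwidth = gap + 1L,
                    with.revmap = TRUE)
        data.frame(seq_id = h$seq_id[1L], category = category,
                   start = start(r), end = end(r),
                   n_evidence = lengths(S4Vectors::mcols(r)$revmap),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out <- out[order(out$seq_id, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# chains of mutually overlapping NBARC_EXTRACT signatures for one sequence,
# with their support status
nbarcChains <- function(sig, motifs, vocabulary) {
    ex <- sig[sig$accession %in% vocabulary$NBARC_EXTRACT, , drop = FALSE]
    if (!nrow(ex)) return(NULL)
    chains <- reduce(IRanges(ex$start, ex$end), min.gapwidth = 0L)
    nb <- sig[sig$accession %in% vocabulary$NBARC, , drop = FALSE]
    nb_r <- IRanges(nb$start, nb$end)
    mo <- motifs[as.character(motifs$motif_id) %in%
                     as.character(nbarcMotifIds()) &
                     motifs$extraction_eligible, , drop = FALSE]
    mo_r <- IRanges(mo$start, mo$end)
    sig_support <- countOverlapsSimple(chains, nb_r) > 0L
    mot_ov <- findOverlaps(chains, mo_r)
    mot_support <- tabulate(queryHits(mot_ov), length(chains)) > 0L
    st <- start(chains); en <- end(chains)
    if (length(mot_ov)) {
        for (k in seq_along(chains)) {
            mk <- subjectHits(mot_ov)[queryHits(mot_ov) == k]
            if (length(mk)) {
                st[k] <- min(st[k], mo$start[mk])
                en[k] <- max(en[k], mo$end[mk])
            }
        }
    }
    data.frame(start = st, end = en,
               supported = sig_support | mot_support,
               support = ifelse(sig_support, "signature",
                                ifelse(mot_support, "motif", "none")),
               stringsAsFactors = FALSE)
}

countOverlapsSimple <- function(query, subject) {
    tabulate(queryHits(findOverlaps(query, subject)), length(query))
}

#' Detect NB-ARC regions from signature and motif evidence
#'
#' Chains of mutually overlapping extraction-set signatures
#' (P-loop NTPase, winged-helix and helical NB-ARC substructures, PF00931)
#' are merged; a chain is an NB-ARC region if it overlaps at least one
#' NB-ARC-specific signature hit or at least one extraction-eligible
#' RNBS-D / MHD / linker motif hit. The region boundary is the union of the
#' chained signature intervals, extended to include any overlapping
#' diagnostic motif. Regions are ordered by start and numbered.
#'
#' @param sig_hits signature-hit data.frame (one or many sequences).
#' @param motif_hits filtered motif-hit data.frame (with
#'   `extraction_eligible`; see [filterMotifHits()]).
#' @param vocabulary see [domainVocabulary()].
#' @return data.frame seq_id, region (1..k within sequence), start, end,
#'   support ("signature" or "motif").
#' @export
detectNbarc <- function(sig_hits, motif_hits, vocabulary = domainVocabulary()) {
    empty <- data.frame(seq_id = character(), region = integer(),
                        start = integer(), end = integer(),
                        support = character(), stringsAsFactors = FALSE)
    if (!nrow(sig_hits)) return(empty)
    if (!nrow(motif_hits))
        motif_hits <- cbind(emptyMotifHits(), extraction_eligible = logical())
    out <- lapply(unique(sig_hits$seq_id), function(id) {
        ch <- nbarcChains(sig_hits[sig_hits$seq_id == id, , drop = FALSE],
                          motif_hits[motif_hits$seq_id == id, , drop = FALSE],
                          vocabulary)
        if (is.null(ch)) return(NULL)
        ch <- ch[ch$supported, , drop = FALSE]
        if (!nrow(ch)) return(NULL)
        ch <- ch[order(ch$start), , drop = FALSE]
        data.frame(seq_id = id, region = seq_len(nrow(ch)),
                   start = ch$start, end = ch$end, support = ch$support,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) return(empty)
    rownames(out) <- NULL
    out
}

# all domain calls for one sequence: letters + coordinates
buildCallsOneSeq <- function(sig, motifs, regions, cjid, vocabulary,
                             gap = 20L) {
    pieces <- list()
    catmap <- list(R1 = "R1", CC = "CC", RPW8 = "RPW8", TIR = "TIR",
                   LRR = "LRR")
    for (cat in names(catmap)) {
        h <- sig[sig$accession %in% vocabulary[[cat]], , drop = FALSE]
        if (nrow(h))
            pieces[[length(pieces) + 1L]] <-
                mergeCategoryIntervals(h, catmap[[cat]], gap)
    }
    if (nrow(regions))
        pieces[[length(pieces) + 1L]] <- data.frame(
            seq_id = regions$seq_id, category = "NBARC",
            start = regions$start, end = regions$end,
            n_evidence = 1L, stringsAsFactors = FALSE)
    if (!is.null(cjid) && nrow(cjid))
        pieces[[length(pieces) + 1L]] <-
            mergeCategoryIntervals(cbind(cjid, accession = "CJID"),
                                   "CJID", gap)
    # "other": HeLo, tracked integrated-domain signatures, any accession in
    # no category set, and unsupported extraction-set chains
    known <- unlist(vocabulary[c("R1", "CC", "RPW8", "TIR", "NBARC",
                                 "NBARC_EXTRACT", "LRR")], use.names = FALSE)
    oth <- sig[sig$accession %in%
                   c(vocabulary$MLKL_HELO, vocabulary$ID_EXTRA) |
                   (!(sig$accession %in% known) &
                        sig$analysis %in% c("Pfam", "SUPERFAMILY", "Gene3D")),
               , drop = FALSE]
    if (nrow(oth)) {
        for (acc in unique(oth$accession))
            pieces[[length(pieces) + 1L]] <-
                mergeCategoryIntervals(
                    oth[oth$accession == acc, , drop = FALSE], "OTHER", gap)
    }
    ch <- nbarcChains(sig, motifs, vocabulary)
    if (!is.null(ch)) {
        orphan <- ch[!ch$supported, , drop = FALSE]
        if (nrow(orphan)) {
            # suppress orphan chains already inside another call's span
            pieces[[length(pieces) + 1L]] <- data.frame(
                seq_id = sig$seq_id[1L], category = "OTHER",
                start = orphan$start, end = orphan$end, n_evidence = 1L,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(pieces))
        return(data.frame(seq_id = character(), category = character(),
                          start = integer(), end = integer(),
                          n_evidence = integer(), stringsAsFactors = FALSE))
    calls <- do.call(rbind, pieces)
    # order by start, then longer call first (deterministic tie rule)
    calls <- calls[order(calls$start, -(calls$end - calls$start)), ,
                   drop = FALSE]
    rownames(calls) <- NULL
    calls
}

#' Build the compressed architecture string from domain calls
#'
#' One letter per call in start order (ties: longer call first); adjacent
#' identical letters are collapsed. Letter map as in
#' [architectureLetters()].
#'
#' @param calls data.frame of domain calls for one sequence (columns
#'   category, start, end).
#' @return single architecture string (possibly "").
#' @export
buildArchitecture <- function(calls) {
    if (!nrow(calls)) return("")
    calls <- calls[order(calls$start, -(calls$end - calls$start)), ,
                   drop = FALSE]
    letters_ <- architectureLetters()[calls$category]
    keep <- c(TRUE, letters_[-1L] != letters_[-length(letters_)])
    paste(letters_[keep], collapse = "")
}

# classification decision for one sequence
classifyOneSeq <- function(sig, motifs, regions, calls, vocabulary) {
    if (nrow(regions)) {
        rule <- if (any(regions$support == "signature"))
            "nbarc-signature" else "nbarc-motif"
        return(c("NLR", rule))
    }
    sensor <- any(calls$category %in% c("CC", "R1", "RPW8", "TIR"))
    lrr <- any(calls$category == "LRR")
    ploop <- sig[sig$accession %in% vocabulary$PLOOP, , drop = FALSE]
    motif_ev <- nrow(motifs) &&
        any(as.character(motifs$motif_id) %in% as.character(nbarcMotifIds()) &
                motifs$extraction_eligible)
    if (sensor && nrow(ploop)) {
        other_sig <- sig[!(sig$accession %in% vocabulary$PLOOP), ,
                         drop = FALSE]
        clean <- vapply(seq_len(nrow(ploop)), function(i) {
            !any(other_sig$start <= ploop$end[i] &
                     other_sig$end >= ploop$start[i])
        }, logical(1))
        if (any(clean)) return(c("NLR-degenerate", "sensor-ploop"))
    }
    if ((sensor || lrr) && motif_ev)
        return(c("NLR-degenerate", "sensor-motif"))
    if (any(sig$accession %in% vocabulary$MLKL_HELO))
        return(c("MLKL", "helo-domain"))
    if (!nrow(ploop)) {
        if (any(calls$category == "TIR")) return(c("TX", "tir-only"))
        if (any(calls$category %in% c("CC", "R1")))
            return(c("CCX", "cc-only"))
        if (any(calls$category == "RPW8")) return(c("RPW8", "rpw8-only"))
    }
    c("non-NLR", "no-rule")
}

#' Annotate and classify a protein set
#'
#' The full evidence-to-classification pipeline: per-category interval
#' merging, NB-ARC region detection, category assignment (precedence
#' NLR > NLR-degenerate > MLKL > TX/CCX/RPW8 > non-NLR) and architecture
#' strings.
#'
#' @param proteins named `AAStringSet` (or named character vector).
#' @param sig_hits signature-hit data.frame ([parseInterproTsv()]).
#' @param motif_hits motif-hit data.frame, raw ([parseFimoTsv()] or
#'   [scanMotifs()]); the score/q-value filter is applied here unless
#'   `prefiltered = TRUE`.
#' @param cjid optional C-JID hit data.frame ([readCjidDomtbl()]).
#' @param score_min,q_max,strict_score_min thresholds, see
#'   [filterMotifHits()].
#' @param gap residue gap bridged when merging same-category intervals.
#' @param prefiltered set TRUE if `motif_hits` already carries
#'   `extraction_eligible`.
#' @return an [NLRAnnotation-class] object.
#' @examples
#' prot <- Biostrings::AAStringSet(c(P1 = paste(rep("A", 900), collapse = "")))
#' sig <- data.frame(seq_id = "P1", analysis = "Pfam", accession = "PF00931",
#'                   description = "NB-ARC", start = 180L, end = 460L,
#'                   score = 1e-50, extra = "")
#' ann <- annotateNLR(prot, sig, data.frame())
#' classification(ann)
#' @export
annotateNLR <- function(proteins, sig_hits, motif_hits = NULL, cjid = NULL,
                        score_min = 60, q_max = 0.01, strict_score_min = 85,
                        gap = 20L, prefiltered = FALSE) {
    if (!is(proteins, "XStringSet"))
        proteins <- AAStringSet(proteins)
    ids <- names(proteins)
    if (is.null(ids) || anyDuplicated(ids))
        stop("proteins must be uniquely named")
    vocabulary <- domainVocabulary()
    if (is.null(sig_hits) || !nrow(sig_hits)) sig_hits <- emptySignatureHits()
    if (is.null(motif_hits) || !nrow(motif_hits)) {
        motif_hits <- emptyMotifHits()
        motif_hits$extraction_eligible <- logical()
    } else if (!prefiltered) {
        motif_hits <- filterMotifHits(motif_hits, score_min = score_min,
                                      q_max = q_max,
                                      strict_score_min = strict_score_min)
    }
    unknown <- setdiff(c(sig_hits$seq_id, motif_hits$seq_id,
                         if (!is.null(cjid)) cjid$seq_id), ids)
    if (length(unknown))
        stop("evidence references unknown sequence(s): ",
             paste(unknown, collapse = ", "))
    regions_all <- detectNbarc(sig_hits, motif_hits, vocabulary)
    calls_list <- vector("list", length(ids))
    class_rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
        id <- ids[i]
        sig <- sig_hits[sig_hits$seq_id == id, , drop = FALSE]
        mot <- motif_hits[motif_hits$seq_id == id, , drop = FALSE]
        reg <- regions_all[regions_all$seq_id == id, , drop = FALSE]
        cj <- if (!is.null(cjid)) cjid[cjid$seq_id == id, , drop = FALSE]
        calls <- buildCallsOneSeq(sig, mot, reg, cj, vocabulary, gap)
        cat_rule <- classifyOneSeq(sig, mot, reg, calls, vocabulary)
        calls_list[[i]] <- calls
        class_rows[[i]] <- data.frame(
            seq_id = id, category = cat_rule[1L],
            architecture = buildArchitecture(calls),
            n_nbarc = nrow(reg), rule = cat_rule[2L],
            stringsAsFactors = FALSE)
    }
    calls_all <- do.call(rbind, calls_list)
    if (is.null(calls_all))
        calls_all <- data.frame(seq_id = character(), category = character(),
                                start = integer(), end = integer(),
                                n_evidence = integer(),
                                stringsAsFactors = FALSE)
    rownames(calls_all) <- NULL
    classification <- do.call(rbind, class_rows)
    rownames(classification) <- NULL
    new("NLRAnnotation", proteins = proteins, signatureHits = sig_hits,
        motifHits = motif_hits, calls = calls_all,
        nbarcRegions = regions_all, classification = classification)
}

#' Extract NB-ARC domain sequences
#'
#' One record per detected region, by inclusive coordinates. A protein with
#' a single region keeps its own ID; with several, regions are numbered
#' `<id>_1 .. <id>_k` in order of occurrence.
#'
#' @param object an [NLRAnnotation-class], or an `AAStringSet` together with
#'   a region data.frame via `regions`.
#' @param regions region data.frame (seq_id, region, start, end); taken from
#'   `object` when it is an `NLRAnnotation`.
#' @return `AAStringSet` of extracted NB-ARC domains.
#' @export
extractNbarc <- function(object, regions = NULL) {
    if (is(object, "NLRAnnotation")) {
        regions <- nbarcRegions(object)
        seqs <- proteins(object)
    } else {
        seqs <- if (is(object, "XStringSet")) object else AAStringSet(object)
        if (is.null(regions)) stop("regions required")
    }
    if (!nrow(regions)) return(AAStringSet())
    bad <- regions$start < 1L |
        regions$end > width(seqs)[match(regions$seq_id, names(seqs))]
    if (any(bad))
        stop("NB-ARC region out of sequence bounds for ",
             paste(unique(regions$seq_id[bad]), collapse = ", "))
    n_per <- table(regions$seq_id)
    out_names <- ifelse(n_per[regions$seq_id] > 1L,
                        paste0(regions$seq_id, "_", regions$region),
                        regions$seq_id)
    out <- subseq(seqs[regions$seq_id], start = regions$start,
                  end = regions$end)
    names(out) <- out_names
    out
}

#' Exact-string sequence deduplication
#'
#' @param x named `AAStringSet` or named character vector.
#' @return list with `unique` (first-seen representative per distinct
#'   sequence, original order) and `multiplicity` (data.frame rep_id, n,
#'   members).
#' @export
dedupeSequences <- function(x) {
    seqs <- as.character(x)
    ids <- names(x)
    first <- !duplicated(seqs)
    rep_of <- ids[first][match(seqs, seqs[first])]
    mult <- data.frame(
        rep_id = ids[first],
        n = as.integer(table(rep_of)[ids[first]]),
        members = vapply(ids[first], function(r)
            paste(ids[rep_of == r], collapse = ","), ""),
        stringsAsFactors = FALSE)
    rownames(mult) <- NULL
    uniq <- x[first]
    list(unique = if (is(x, "XStringSet")) uniq else
             AAStringSet(structure(seqs[first], names = ids[first])),
         multiplicity = mult)
}

#' Write the classification table as TSV
#' @param object an [NLRAnnotation-class].
#' @param path output file.
#' @export
writeClassificationTsv <- function(object, path) {
    write.table(classification(object), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
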