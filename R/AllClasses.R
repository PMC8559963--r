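#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importClassesFrom Biostrings AAStringSet
NULL

#' Position probability matrix for an amino-acid motif
#'
#' A `PWMotif` holds one position probability matrix (PPM) together with the
#' background letter distribution and the pseudocount used when converting
#' probabilities to log-odds scores. The alphabet is carried by the matrix
#' column names; the canonical case is the 20 amino acids, but reduced
#' alphabets are supported (useful for exhaustive verification of the
#' p-value machinery).
#'
#' @slot motif_id motif identifier (character; numeric ids are kept as
#'   their character form).
#' @slot alt_id optional alternative name (e.g. "MHD"), or `NA`.
#' @slot matrix numeric matrix, one row per motif position, one column per
#'   alphabet letter; every row sums to 1 within 1e-3.
#' @slot background named numeric vector of per-letter background
#'   probabilities over the same alphabet, strictly positive, summing to 1.
#' @slot pseudocount small positive value added to matrix probabilities
#'   before taking log-odds.
#'
#' @examples
#' pwm <- PWMotif("toy", matrix = rbind(c(A = 0.7, C = 0.1, G = 0.1, T = 0.1)))
#' motifLength(pwm)
#' @export
setClass("PWMotif",
    representation(
        motif_id = "character",
        alt_id = "character",
        matrix = "matrix",
        background = "numeric",
        pseudocount = "numeric"
    )
)

setValidity("PWMotif", function(object) {
    m <- object@matrix
    msg <- character()
    if (nrow(m) < 1L)
        msg <- c(msg, "motif must have at least one position")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        msg <- c(msg, "matrix columns must be uniquely named by alphabet letter")
    rs <- rowSums(m)
    bad <- which(abs(rs - 1) > 1e-3)
    if (length(bad))
        msg <- c(msg, sprintf("motif %s: row %d sums to %.4g (must be 1 within 1e-3)",
                              object@motif_id, bad[1L], rs[bad[1L]]))
    bg <- object@background
    if (!identical(sort(names(bg)), sort(colnames(m))))
        msg <- c(msg, "background letters must match matrix alphabet")
    if (any(bg <= 0))
        msg <- c(msg, "background probabilities must be strictly positive")
    if (abs(sum(bg) - 1) > 1e-6)
        msg <- c(msg, "background must sum to 1")
    if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
        msg <- c(msg, "pseudocount must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Construct a PWMotif
#'
#' @param motif_id motif identifier.
#' @param matrix position probability matrix (positions x letters, columns
#'   named by letter).
#' @param background named background probabilities; default uniform over
#'   the matrix alphabet.
#' @param pseudocount probability added to each matrix entry before the
#'   log-odds transform (default 1e-4).
#' @param alt_id optional alternative motif name.
#' @return a validated [PWMotif-class] object.
#' @export
PWMotif <- function(motif_id, matrix, background = NULL,
                    pseudocount = 1e-4, alt_id = NA_character_) {
    if (is.null(colnames(matrix)))
        stop("matrix columns must be named by alphabet letter")
    if (is.null(background)) {
        background <- rep(1 / ncol(matrix), ncol(matrix))
        names(background) <- colnames(matrix)
    }
    new("PWMotif", motif_id = as.character(motif_id),
        alt_id = as.character(alt_id),
        matrix = matrix, background = background[colnames(matrix)],
        pseudocount = pseudocount)
}

#' @describeIn PWMotif-class number of motif positions
#' @param x,object a `PWMotif`
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname PWMotif-class
#' @export
setMethod("motifLength", "PWMotif", function(x) nrow(x@matrix))

setMethod("show", "PWMotif", function(object) {
    cat(sprintf("PWMotif '%s'%s: %d positions over {%s}\n",
                object@motif_id,
                if (is.na(object@alt_id)) "" else sprintf(" (%s)", object@alt_id),
                nrow(object@matrix),
                paste(colnames(object@matrix), collapse = "")))
})

#' Annotated and classified protein set
#'
#' Result container of [annotateNLR()]. Holds the input proteins, the raw
#' evidence tables, the merged per-category domain calls, the detected
#' NB-ARC regions and the per-sequence classification. Use the accessors
#' ([classification()], [domainCalls()], [nbarcRegions()], [motifHits()],
#' [signatureHits()], [proteins()]) rather than slots.
#'
#' @slot proteins `AAStringSet` of the input sequences (genus/subclass in
#'   `mcols()` when supplied).
#' @slot signatureHits data.frame of signature evidence
#'   (seq_id, analysis, accession, description, start, end, score).
#' @slot motifHits data.frame of motif evidence after threshold filtering,
#'   with the `extraction_eligible` flag.
#' @slot calls data.frame of merged domain calls
#'   (seq_id, category, letter, start, end, n_evidence).
#' @slot nbarcRegions data.frame (seq_id, region, start, end, support).
#' @slot classification data.frame
#'   (seq_id, category, architecture, n_nbarc, rule).
#' @export
setClass("NLRAnnotation",
    representation(
        proteins = "AAStringSet",
        signatureHits = "data.frame",
        motifHits = "data.frame",
        calls = "data.frame",
        nbarcRegions = "data.frame",
        classification = "data.frame"
    )
)

setValidity("NLRAnnotation", function(object) {
    msg <- character()
    ids <- names(object@proteins)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "proteins must have unique names")
    cl <- object@classification
    need <- c("seq_id", "category", "architecture", "n_nbarc", "rule")
    if (!all(need %in% names(cl)))
        msg <- c(msg, "classification must have columns seq_id, category, architecture, n_nbarc, rule")
    else {
        if (!setequal(cl$seq_id, ids))
            msg <- c(msg, "classification must cover every input protein exactly once")
        bad <- setdiff(cl$category, nlrCategories())
        if (length(bad))
            msg <- c(msg, paste("unknown category:", paste(bad, collapse = ", ")))
    }
    if (nrow(object@nbarcRegions) &&
        !all(object@nbarcRegions$seq_id %in% ids))
        msg <- c(msg, "NB-ARC region references an unknown sequence")
    if (length(msg)) msg else TRUE
})

setMethod("show", "NLRAnnotation", function(object) {
    cl <- object@classification
    cat(sprintf("NLRAnnotation: %d proteins\n", length(object@proteins)))
    tab <- table(factor(cl$category, levels = nlrCategories()))
    tab <- tab[tab > 0]
    for (nm in names(tab))
        cat(sprintf("  %-14s %d\n", nm, tab[[nm]]))
    cat(sprintf("  NB-ARC regions: %d\n", nrow(object@nbarcRegions)))
})

#' @describeIn NLRAnnotation-class per-sequence classification table
#' @export
setGeneric("classification", function(object) standardGeneric("classification"))
#' @rdname NLRAnnotation-class
#' @export
setMethod("classification", "NLRAnnotation", function(object) object@classification)

#' @describeIn NLRAnnotation-class merged domain-call table
#' @export
setGeneric("domainCalls", function(object) standardGeneric("domainCalls"))
#' @rdname NLRAnnotation-class
#' @export
setMethod("domainCalls", "NLRAnnotation", function(object) object@calls)

#' @describeIn NLRAnnotation-class detected NB-ARC regions
#' @export
setGeneric("nbarcRegions", function(object) standardGeneric("nbarcRegions"))
#' @rdname NLRAnnotation-class
#' @export
setMethod("nbarcRegions", "NLRAnnotation", function(object) object@nbarcRegions)

#' @describeIn NLRAnnotation-class filtered motif-hit table
#' @export
setGeneric("motifHits", function(object) standardGeneric("motifHits"))
#' @rdname NLRAnnotation-class
#' @export
setMethod("motifHits", "NLRAnnotation", function(object) object@motifHits)

#' @describeIn NLRAnnotation-class signature-hit table
#' @export
setGeneric("signatureHits", function(object) standardGeneric("signatureHits"))
#' @rdname NLRAnnotation-class
#' @export
setMethod("signatureHits", "NLRAnnotation", function(object) object@signatureHits)

#' @describeIn NLRAnnotation-class input protein sequences
#' @export
setGeneric("proteins", function(object) standardGeneric("proteins"))
#' @rdname NLRAnnotation-class
#' @export
setMethod("proteins", "NLRAnnotation", function(object) object@proteins)
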