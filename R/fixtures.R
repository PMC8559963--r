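# Synthetic-evidence generator. Emits random-composition proteins with
# planted domain architectures plus matching mock signature (InterProScan
# TSV) and motif (FIMO TSV) evidence, so the whole pipeline is testable
# offline. Domain content is carried entirely by the planted evidence: the
# classifier never re-derives signatures from sequence, so the residues
# themselves are uniform random.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

segmentLengthRange <- function(letter) {
    switch(letter,
           "1" = c(90L, 120L), C = c(40L, 80L), R = c(100L, 150L),
           T = c(150L, 200L), N = c(290L, 330L), L = c(160L, 300L),
           J = c(90L, 130L), O = c(60L, 120L),
           stop("unknown architecture letter: ", letter))
}

letterAccessionPool <- function(letter, vocabulary = domainVocabulary()) {
    switch(letter,
           "1" = vocabulary$R1, C = vocabulary$CC, R = vocabulary$RPW8,
           T = vocabulary$TIR, L = vocabulary$LRR,
           O = c(vocabulary$ID_EXTRA, "PF00069", "SSF56112"),
           stop("no accession pool for letter ", letter))
}

MOTIF_WIDTH <- 15L

defaultMotifPlan <- function() {
    data.frame(motif_id = c("2", "7", "8"),
               motif_alt_id = c("RNBS-D", "MHD", "linker"),
               score = 90, qvalue = 1e-4, stringsAsFactors = FALSE)
}

#' Specification of one synthetic fixture
#'
#' @param id sequence identifier.
#' @param architecture planted domain letter string over \{1,C,R,T,N,L,J,O\}.
#' @param genus genus label carried to the truth table.
#' @param nbarc_mode how N segments are evidenced: "signature" (an
#'   NB-ARC-specific accession spans the segment) or "motif" (only a generic
#'   P-loop NTPase signature plus the planted diagnostic motifs).
#' @param motifs data.frame (motif_id, motif_alt_id, score, qvalue) planted
#'   inside each N segment; default the three diagnostic motifs at score 90,
#'   q-value 1e-4.
#' @param lrr_motif optional motif plan planted inside the first L segment
#'   (exercises the "LRR + diagnostic motif" degenerate route).
#' @param extra_ploop plant an additional standalone P-loop NTPase signature
#'   segment after the architecture (clean, overlapping nothing).
#' @param other_accessions accessions used for O segments (recycled);
#'   default drawn from the integrated-domain pool.
#' @return a `fixture_spec` list.
#' @export
fixtureSpec <- function(id, architecture, genus = "Genusa",
                        nbarc_mode = "signature",
                        motifs = defaultMotifPlan(), lrr_motif = NULL,
                        extra_ploop = FALSE, other_accessions = NULL) {
    letters_ <- strsplit(architecture, "")[[1L]]
    bad <- setdiff(letters_, c("1", "C", "R", "T", "N", "L", "J", "O"))
    if (length(bad))
        stop("invalid architecture letter(s): ", paste(bad, collapse = ""))
    structure(list(id = id, architecture = architecture, genus = genus,
                   nbarc_mode = match.arg(nbarc_mode,
                                          c("signature", "motif")),
                   motifs = motifs, lrr_motif = lrr_motif,
                   extra_ploop = extra_ploop,
                   other_accessions = other_accessions),
              class = "fixture_spec")
}

# does a planted motif hit pass the annotation filter / strict eligibility?
motifPasses <- function(plan, score_min = 60, q_max = 0.01,
                        strict_score_min = 85) {
    if (is.null(plan) || !nrow(plan)) return(logical(0))
    basic <- plan$score >= score_min & plan$qvalue <= q_max
    strict <- as.character(plan$motif_id) %in% strictMotifIds()
    basic & (!strict | plan$score >= strict_score_min)
}

#' Generate one synthetic protein with planted evidence
#'
#' Segments of random residues are concatenated per architecture letter with
#' 5-30 aa linkers; each segment gets one signature hit with an accession
#' from its letter's vocabulary set spanning the segment; planted motif hits
#' carry the spec's scores and q-values. The returned truth record holds the
#' category and (compressed) architecture the classifier is expected to
#' produce.
#'
#' @param spec a [fixtureSpec()].
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with `id`, `sequence`, `genus`, `sig` (signature hits),
#'   `motif` (motif hits), `cjid` (C-JID hits) and `truth`
#'   (list: category, architecture, n_nbarc).
#' @export
generateProtein <- function(spec, seed = 1L) {
    withSeed(seed, {
    letters_ <- strsplit(spec$architecture, "")[[1L]]
    seq_parts <- character(); pos <- 0L
    sig <- emptySignatureHits()[0, c("seq_id", "analysis", "accession",
                                     "description", "start", "end", "score",
                                     "extra")]
    motif <- emptyMotifHits()
    cjid <- data.frame(seq_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
    realized <- character()
    n_nbarc <- 0L
    ploop_standalone <- 0L      # standalone clean P-loop hits planted
    o_i <- 0L
    lrr_planted <- FALSE
    addLinker <- function() {
        k <- sample(5:30, 1L)
        seq_parts[[length(seq_parts) + 1L]] <<-
            paste(sample(AA20, k, replace = TRUE), collapse = "")
        pos <<- pos + k
    }
    addSig <- function(accession, start, end, desc = "") {
        sig[nrow(sig) + 1L, ] <<- list(spec$id, accessionAnalysis(accession),
                                       accession, desc, start, end, 1e-10, "")
    }
    addMotifs <- function(plan, seg_start, seg_len, seqstr) {
        if (is.null(plan) || !nrow(plan)) return()
        usable <- seg_len - MOTIF_WIDTH
        offs <- floor(seq(0.15, 0.85, length.out = nrow(plan)) * usable)
        for (r in seq_len(nrow(plan))) {
            st <- seg_start + offs[r]
            en <- st + MOTIF_WIDTH - 1L
            motif[nrow(motif) + 1L, ] <<- list(
                spec$id, as.character(plan$motif_id[r]),
                plan$motif_alt_id[r], st, en, plan$score[r],
                plan$qvalue[r] / 10, plan$qvalue[r],
                substr(seqstr, st - seg_start + 1L, en - seg_start + 1L))
        }
    }
    addSegment <- function(letter) {
        addLinker()
        rng <- segmentLengthRange(letter)
        len <- sample(rng[1L]:rng[2L], 1L)
        s <- paste(sample(AA20, len, replace = TRUE), collapse = "")
        seg_start <- pos + 1L
        seg_end <- pos + len
        seq_parts[[length(seq_parts) + 1L]] <<- s
        pos <<- pos + len
        if (letter == "J") {
            cjid[nrow(cjid) + 1L, ] <<- list(spec$id, seg_start, seg_end)
            realized <<- c(realized, "J")
        } else if (letter == "N") {
            if (spec$nbarc_mode == "signature") {
                acc <- sample(domainVocabulary()$NBARC, 1L)
                addSig(acc, seg_start, seg_end, "NB-ARC")
                # sometimes a second, overlapping extraction-set hit to
                # exercise chain merging
                if (stats::runif(1) < 0.5)
                    addSig("G3DSA:3.40.50.300", seg_start + 5L,
                           seg_end - 5L, "P-loop NTPase")
                addMotifs(spec$motifs, seg_start, len, s)
                realized <<- c(realized, "N")
                n_nbarc <<- n_nbarc + 1L
            } else {
                addSig("SSF52540", seg_start, seg_end, "P-loop NTPase")
                addMotifs(spec$motifs, seg_start, len, s)
                if (any(motifPasses(spec$motifs))) {
                    realized <<- c(realized, "N")
                    n_nbarc <<- n_nbarc + 1L
                } else {
                    # unsupported chain: surfaces as "other", and the P-loop
                    # hit is clean (overlaps nothing else)
                    realized <<- c(realized, "O")
                    ploop_standalone <<- ploop_standalone + 1L
                }
            }
        } else {
            pool <- if (letter == "O" && !is.null(spec$other_accessions)) {
                o_i <<- o_i + 1L
                spec$other_accessions[(o_i - 1L) %%
                                          length(spec$other_accessions) + 1L]
            } else letterAccessionPool(letter)
            acc <- if (length(pool) == 1L) pool else sample(pool, 1L)
            addSig(acc, seg_start, seg_end, letter)
            if (letter == "L" && !is.null(spec$lrr_motif) && !lrr_planted) {
                lrr_planted <<- TRUE     # only the first L segment
                addMotifs(spec$lrr_motif, seg_start, len, s)
            }
            realized <<- c(realized, letter)
        }
    }
    first_l_plan <- spec$lrr_motif
    for (letter in letters_) addSegment(letter)
    if (spec$extra_ploop) {
        addLinker()
        len <- 180L
        s <- paste(sample(AA20, len, replace = TRUE), collapse = "")
        addSig("SSF52540", pos + 1L, pos + len, "P-loop NTPase")
        seq_parts[[length(seq_parts) + 1L]] <- s
        pos <- pos + len
        realized <- c(realized, "O")
        ploop_standalone <- ploop_standalone + 1L
    }
    addLinker()
    sequence <- paste(seq_parts, collapse = "")

    # intended truth
    sensor <- any(letters_ %in% c("1", "C", "R", "T"))
    lrr <- "L" %in% letters_
    lrr_motif_ok <- any(motifPasses(first_l_plan))
    category <- if (n_nbarc > 0L) "NLR"
        else if (sensor && ploop_standalone > 0L) "NLR-degenerate"
        else if ((sensor || lrr) && lrr_motif_ok) "NLR-degenerate"
        else if (!is.null(spec$other_accessions) &&
                     "PF06760" %in% spec$other_accessions) "MLKL"
        else if ("T" %in% letters_ && ploop_standalone == 0L) "TX"
        else if (any(letters_ %in% c("C", "1")) && ploop_standalone == 0L)
            "CCX"
        else if ("R" %in% letters_ && ploop_standalone == 0L) "RPW8"
        else "non-NLR"
    keep <- c(TRUE, realized[-1L] != realized[-length(realized)])
    truth_arch <- paste(realized[keep], collapse = "")
    list(id = spec$id, sequence = sequence, genus = spec$genus,
         sig = sig, motif = motif, cjid = cjid,
         truth = list(category = category, architecture = truth_arch,
                      n_nbarc = n_nbarc))
    })
}

#' Generate a mutated sequence family
#'
#' `n` copies of a seed sequence with random substitutions placed so that
#' the realized identity to the seed equals the target (no indels, so
#' identity is exactly `1 - substitutions/length` up to rounding).
#'
#' @param seed_record single named character (or `AAStringSet` of length 1).
#' @param n family size.
#' @param identity target identity in (0, 1].
#' @param seed RNG seed.
#' @return named `AAStringSet` of the `n` mutants (`<id>_m1..`).
#' @export
generateFamily <- function(seed_record, n, identity, seed = 1L) {
    stopifnot(identity > 0, identity <= 1)
    s <- as.character(seed_record)[[1L]]
    id <- names(seed_record)[1L]
    len <- nchar(s)
    k <- round((1 - identity) * len)
    withSeed(seed, {
        out <- vapply(seq_len(n), function(i) {
            chars <- strsplit(s, "")[[1L]]
            if (k > 0L) {
                posn <- sample(len, k)
                chars[posn] <- vapply(chars[posn], function(ch)
                    sample(setdiff(AA20, ch), 1L), "")
            }
            paste(chars, collapse = "")
        }, "")
        names(out) <- paste0(id, "_m", seq_len(n))
        AAStringSet(out)
    })
}

#' Write mock evidence files for a set of fixtures
#'
#' Emits a FASTA, an InterProScan-format TSV, a FIMO-format TSV, a C-JID
#' domtblout and a truth TSV (id, genus, category, architecture, n_nbarc)
#' that parse cleanly by the package's own readers.
#'
#' @param fixtures list of [generateProtein()] results.
#' @param dir output directory (created if needed).
#' @return named character vector of the five file paths.
#' @export
emitMockFiles <- function(fixtures, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, "proteins.fasta")
    ipr <- file.path(dir, "interproscan.tsv")
    fimo <- file.path(dir, "fimo.tsv")
    cjid <- file.path(dir, "cjid.domtbl")
    truth <- file.path(dir, "truth.tsv")
    seqs <- vapply(fixtures, `[[`, "", "sequence")
    names(seqs) <- vapply(fixtures, `[[`, "", "id")
    if (length(seqs)) writeProteinFasta(seqs, fasta) else
        writeLines(character(), fasta)
    ipr_lines <- unlist(lapply(fixtures, function(f) {
        if (!nrow(f$sig)) return(character())
        paste(f$sig$seq_id, "md5", nchar(f$sequence), f$sig$analysis,
              f$sig$accession, f$sig$description, f$sig$start, f$sig$end,
              format(f$sig$score, trim = TRUE), "T", "01-01-2026",
              sep = "\t")
    }))
    writeLines(as.character(ipr_lines), ipr)
    mo <- do.call(rbind, lapply(fixtures, `[[`, "motif"))
    if (is.null(mo)) mo <- emptyMotifHits()
    writeFimoTsv(mo, fimo)
    cj <- do.call(rbind, lapply(fixtures, `[[`, "cjid"))
    cj_lines <- if (!is.null(cj) && nrow(cj))
        sprintf("%s - 1000 CJID - 120 1e-30 100.0 0.1 1 1 1e-30 1e-30 100.0 0.1 1 120 %d %d %d %d 0.99 -",
                cj$seq_id, cj$start, cj$end, cj$start, cj$end)
        else character()
    writeLines(c("# target name ...", cj_lines), cjid)
    tr <- data.frame(
        id = vapply(fixtures, `[[`, "", "id"),
        genus = vapply(fixtures, `[[`, "", "genus"),
        category = vapply(fixtures, function(f) f$truth$category, ""),
        architecture = vapply(fixtures, function(f) f$truth$architecture, ""),
        n_nbarc = vapply(fixtures, function(f) f$truth$n_nbarc, 0L),
        stringsAsFactors = FALSE)
    write.table(tr, truth, sep = "\t", quote = FALSE, row.names = FALSE)
    c(fasta = fasta, ipr = ipr, fimo = fimo, cjid = cjid, truth = truth)
}

#' Simulate a classified protein set covering all categories
#'
#' Draws `n` fixtures from a template catalog spanning the seven
#' classification categories and a wide range of architecture strings
#' (including boundary fixtures at the motif score and q-value thresholds:
#' scores 59.9/60.0/84.9/85.0, q-values 0.01/0.011).
#'
#' @param n number of fixtures.
#' @param seed RNG seed; fixtures are deterministic per seed.
#' @return list of [generateProtein()] results.
#' @export
simulateNlrSet <- function(n = 200L, seed = 42L) {
    mk <- function(...) list(...)
    plan1 <- function(id, alt, score, q)
        data.frame(motif_id = id, motif_alt_id = alt, score = score,
                   qvalue = q, stringsAsFactors = FALSE)
    genera <- c("Oryza", "Triticum", "Solanum", "Arabidopsis", "Hordeum")
    templates <- list(
        mk(arch = "CNL"), mk(arch = "TNL"), mk(arch = "NL"), mk(arch = "N"),
        mk(arch = "CN"), mk(arch = "TN"), mk(arch = "RNL"),
        mk(arch = "CONL"), mk(arch = "1NL"), mk(arch = "TNLJ"),
        mk(arch = "CNNL"), mk(arch = "TNLO"),
        mk(arch = "NL", nbarc_mode = "motif"),
        mk(arch = "CNL", nbarc_mode = "motif",
           motifs = plan1("2", "RNBS-D", 60.0, 0.01)),      # at thresholds
        mk(arch = "CNL", nbarc_mode = "motif",
           motifs = plan1("8", "linker", 85.0, 1e-4)),       # strict pass
        mk(arch = "T"), mk(arch = "TL"),                     # TX
        mk(arch = "C"), mk(arch = "1"), mk(arch = "CL"),     # CCX
        mk(arch = "R"),                                      # RPW8
        mk(arch = "O", other_accessions = "PF06760"),        # MLKL
        mk(arch = "T", extra_ploop = TRUE),                  # degenerate
        mk(arch = "R", extra_ploop = TRUE),
        mk(arch = "L", lrr_motif = plan1("7", "MHD", 90, 1e-4)),
        mk(arch = "L", lrr_motif = plan1("7", "MHD", 85.0, 0.01)),
        mk(arch = "O"),                                      # non-NLR
        mk(arch = "L"),
        # boundary fixtures: flips driven purely by the thresholds
        mk(arch = "L", lrr_motif = plan1("7", "MHD", 84.9, 1e-4)),   # non-NLR
        mk(arch = "L", lrr_motif = plan1("2", "RNBS-D", 59.9, 1e-4)),# non-NLR
        mk(arch = "L", lrr_motif = plan1("2", "RNBS-D", 60.0, 0.01)),# degen
        mk(arch = "L", lrr_motif = plan1("2", "RNBS-D", 90, 0.011)), # non-NLR
        mk(arch = "NL", nbarc_mode = "motif",
           motifs = plan1("8", "linker", 84.9, 1e-4)),       # chain unsupported
        mk(arch = "NL", nbarc_mode = "motif",
           motifs = plan1("2", "RNBS-D", 59.9, 1e-4))        # chain unsupported
    )
    withSeed(seed, {
        idx <- c(seq_along(templates),
                 sample(length(templates), max(0L, n - length(templates)),
                        replace = TRUE))[seq_len(n)]
        seeds <- sample.int(1e6, n)
        genus_pick <- sample(genera, n, replace = TRUE)
        lapply(seq_len(n), function(i) {
            t <- templates[[idx[i]]]
            spec <- fixtureSpec(
                id = sprintf("FX%04d", i), architecture = t$arch,
                genus = genus_pick[i],
                nbarc_mode = if (is.null(t$nbarc_mode)) "signature" else
                    t$nbarc_mode,
                motifs = if (is.null(t$motifs)) defaultMotifPlan() else
                    t$motifs,
                lrr_motif = t$lrr_motif,
                extra_ploop = isTRUE(t$extra_ploop),
                other_accessions = t$other_accessions)
            generateProtein(spec, seed = seeds[i])
        })
    })
}
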