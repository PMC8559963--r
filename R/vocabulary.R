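# Signature vocabulary mapping InterPro member-database accessions to the
# NLR-associated domain categories, and the three NB-ARC-diagnostic motifs.

#' NLR domain-signature vocabulary
#'
#' Returns the mapping from domain categories to the signature accessions
#' (Pfam, CATH-Gene3D, SUPERFAMILY, PROSITE profiles, SMART, CDD) that
#' provide evidence for each category:
#'
#' * `R1` — late blight resistance protein R1 N-terminal domain.
#' * `CC` — Rx-type (EDVID) coiled coil.
#' * `RPW8` — RPW8-type coiled coil.
#' * `TIR` — Toll/interleukin-1 receptor domain.
#' * `NBARC` — NB-ARC-specific signatures.
#' * `NBARC_EXTRACT` — the wider signature set whose overlap defines the
#'   NB-ARC region used for extraction and phylogenetics.
#' * `PLOOP` — generic P-loop NTPase superfamily signatures (a subset of
#'   `NBARC_EXTRACT`; presence without NB-ARC-specific evidence marks
#'   potential false positives such as ABC transporters and AAA ATPases).
#' * `LRR` — leucine-rich repeat signatures.
#' * `MLKL_HELO` — HeLo domain of plant MLKL-like proteins (PF06760).
#' * `ID_EXTRA` — selected integrated-domain signatures (ALOG, zinc-finger
#'   BED) tracked in addition to the catch-all "other" class.
#'
#' @return named list of character vectors of accessions.
#' @seealso [nbarcMotifIds()] for the motif side of the evidence.
#' @export
domainVocabulary <- function() {
    list(
        R1 = c("PF12061"),
        CC = c("PF18052", "cd14798", "G3DSA:1.20.5.4130"),
        RPW8 = c("PF05659", "PS51153"),
        TIR = c("PF01582", "PF13676", "G3DSA:3.40.50.10140", "SSF52200",
                "PS50104", "SM00255"),
        NBARC = c("PF00931", "G3DSA:1.10.8.430"),
        NBARC_EXTRACT = c("G3DSA:3.40.50.300", "SSF52540", "G3DSA:1.10.8.430",
                          "SSF46785", "G3DSA:1.10.10.10", "PF00931"),
        PLOOP = c("SSF52540", "G3DSA:3.40.50.300"),
        LRR = c("G3DSA:3.80.10.10", "PF08263", "PF07723", "PF07725",
                "PF12799", "PF13306", "PF00560", "PF13516", "PF13855",
                "SSF52047", "SSF52058", "SM00367", "SM00368", "SM00369",
                "PF18837", "PF01463", "SM00082", "SM00013", "PF01462",
                "PF18831", "PF18805"),
        MLKL_HELO = c("PF06760"),
        ID_EXTRA = c("PS51697", "PS50808", "SM00614")
    )
}

#' NB-ARC-diagnostic motif indices
#'
#' The three conserved NB-ARC motifs (indices in the 20-motif NLR motif set)
#' used as NLR-diagnostic evidence: motif 2 = RNBS-D (CC-type), motif 7 =
#' MHD, motif 8 = linker. The MHD and linker motifs carry a stricter score
#' cutoff when used as extraction evidence (see [filterMotifHits()]).
#'
#' @return named integer vector `c(RNBS-D = 2, MHD = 7, linker = 8)`.
#' @export
nbarcMotifIds <- function() {
    c("RNBS-D" = 2L, "MHD" = 7L, "linker" = 8L)
}

#' Motifs under the strict extraction score cutoff
#' @return character vector of motif ids (as stored in hit tables).
#' @keywords internal
strictMotifIds <- function() c("7", "8")

#' Classification categories
#'
#' The seven mutually exclusive categories assigned by [classifySequences()]:
#' `NLR` (NB-ARC present), `NLR-degenerate` (NLR-associated domains plus
#' indirect NB-ARC evidence), `TX` (TIR-only), `CCX` (CC- or R1-only),
#' `RPW8` (RPW8-only), `MLKL` (HeLo domain), `non-NLR`.
#'
#' @return character vector of category labels in precedence order.
#' @export
nlrCategories <- function() {
    c("NLR", "NLR-degenerate", "MLKL", "TX", "CCX", "RPW8", "non-NLR")
}

#' Architecture letter map
#'
#' One-letter code per domain category used to build architecture strings:
#' 1 = R1, C = Rx-type CC, R = RPW8-type CC, T = TIR, N = NB-ARC,
#' L = LRR, J = C-JID, O = other/integrated domain.
#'
#' @return named character vector category -> letter.
#' @export
architectureLetters <- function() {
    c(R1 = "1", CC = "C", RPW8 = "R", TIR = "T", NBARC = "N",
      LRR = "L", CJID = "J", OTHER = "O")
}

# analysis (member database) name inferred from an accession's syntax
accessionAnalysis <- function(accession) {
    out <- rep("Pfam", length(accession))
    out[startsWith(accession, "G3DSA:")] <- "Gene3D"
    out[startsWith(accession, "SSF")] <- "SUPERFAMILY"
    out[startsWith(accession, "PS5")] <- "ProSiteProfiles"
    out[startsWith(accession, "SM")] <- "SMART"
    out[startsWith(accession, "cd")] <- "CDD"
    out[startsWith(accession, "PR")] <- "PRINTS"
    out
}
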