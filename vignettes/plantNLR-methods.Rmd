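---
title: "plantNLR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plantNLR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantNLR)
```

This vignette documents the models, rules and numerical choices behind
`plantNLR`: what each stage computes, which parameters matter and why
their defaults are what they are, and where the design was genuinely
open and a convention had to be declared.

## Evidence model

The pipeline never predicts domains from sequence itself. It consumes
two kinds of interval evidence on each protein, both 1-based inclusive:

* **Signature hits** from an InterProScan-format table: one hit per
  member-database signature (Pfam, CATH-Gene3D, SUPERFAMILY, PROSITE
  profiles, SMART, CDD, PRINTS). No score or e-value cutoff is applied
  to signature hits; the member databases apply their own curated
  thresholds upstream.
* **Motif hits** from a FIMO-format table or from the package's own
  scanner ([scanMotifs()]): windows matching the conserved NB-ARC
  motifs, with log-odds score, p-value and q-value.

The signature vocabulary ([domainVocabulary()]) maps accessions to
categories: R1, Rx-type CC, RPW8-type CC, TIR, NB-ARC, LRR, the HeLo
domain of MLKL-like proteins, selected integrated-domain signatures
(ALOG, zinc-finger BED), plus two special sets. `NBARC_EXTRACT` is the
wider set of structural signatures whose overlap defines the NB-ARC
region used for extraction (P-loop NTPase, winged-helix and helical
substructures, PF00931); `PLOOP` is its generic NTPase subset, whose
presence *without* NB-ARC-specific support marks the classic false
positives (ABC transporters, AAA ATPases) and, in combination with NLR
signaling domains, degenerate NLRs.

Three motifs are diagnostic: RNBS-D (index 2), MHD (index 7) and the
linker (index 8). C-JID domains, found C-terminal to the LRR in some
TIR-NLRs, come from an optional precomputed HMMER domtblout table;
building the C-JID model itself is out of scope.

## Motif scanner

[scoreSequence()] scores every window of length $L$ as
$\sum_{j=1}^{L} \log_2\frac{p_{j,a_j} + c}{b_{a_j}}$, with position
probabilities $p$, background $b$, and pseudocount $c = 10^{-4}$ added
before the log (the meme-suite convention, close enough for thresholded
use; the printed thresholds are exposed as arguments so users scanning
with real FIMO output bypass the internal scanner entirely). The
background is uniform $1/20$ by default and overridable; letters outside
the motif alphabet (such as `X`) contribute log-odds 0, i.e. score as
background.

[scorePvalueTable()] computes exact p-values the standard way: each
per-position log-odds is quantized to an integer multiple of a
granularity (default $10^{-3}$ bit), and the full distribution of the
window score of a random background $L$-mer is built by dynamic
programming (one convolution per motif position). The upper-tail sum
gives $p(s) = P(\text{score} \ge s)$, monotone non-increasing with
$p = 1$ at the minimum attainable score. At granularity $10^{-3}$ the
table is exact to the quantization for any realistic motif length at
negligible cost; the test suite verifies it against exhaustive word
enumeration for motifs of length up to 3 over reduced alphabets.

q-values are step-up Benjamini–Hochberg over the pooled testing family
of a whole scan — all windows of all sequences and motifs — mirroring
the single-family behavior of a FIMO run. When only windows below a
report threshold are kept (default $p \le 10^{-4}$), the adjustment
still uses the full family size.

[filterMotifHits()] applies the two-stage threshold: hits are kept iff
score $\ge 60.0$ and q-value $\le 0.01$; hits from the linker and MHD
motifs additionally need score $\ge 85.0$ to count as NB-ARC
*extraction* evidence. The strict rule is implemented as an
`extraction_eligible` flag rather than deletion, so annotation output
still shows sub-threshold motif hits while the classifier ignores them.
The filter applies to all motifs in a scan; per-motif overrides are a
matter of passing a different `strict_motifs` set.

## Classification

Per-category evidence intervals are merged when they overlap or are
separated by at most $G = 20$ residues ([mergeCategoryIntervals()]);
split Gene3D hits on one structural domain are common and the gap
tolerance joins them deterministically.

NB-ARC regions ([detectNbarc()]) are chains of mutually overlapping
`NBARC_EXTRACT` signatures. A chain becomes a region iff it overlaps at
least one NB-ARC-specific signature hit **or** at least one
extraction-eligible diagnostic motif; the region boundary is the union
of the chained signature intervals, extended to cover any overlapping
diagnostic motif. Regions are numbered by order in the protein, and
extraction names them `<id>` (single region) or `<id>_k` (multiple).
Unsupported chains — a generic P-loop with no NB-ARC-specific backing —
surface as "other" calls, never as NB-ARC.

Categories are assigned by the first matching rule in the precedence
order **NLR > degenerate NLR > MLKL > TX/CCX/RPW8 > non-NLR** (the rule
list itself does not imply an order; this one makes stronger evidence
win and the partition deterministic):

* **NLR** — at least one NB-ARC region.
* **Degenerate NLR** — an NLR signaling domain (CC, R1, RPW8 or TIR)
  together with a *clean* P-loop NTPase hit (one whose interval overlaps
  no non-P-loop signature hit from any database — this excludes kinases
  and transporters whose P-loop co-annotates with their own domain), or
  any of those domains or an LRR together with an extraction-eligible
  diagnostic motif.
* **MLKL** — a HeLo-domain hit (PF06760).
* **TX / CCX / RPW8** — TIR-only, CC/R1-only or RPW8-only proteins with
  no P-loop hit at all. Read literally this means a TIR protein whose
  P-loop belongs to an overlapping kinase annotation falls through to
  non-NLR rather than TX; within this tier the order TIR > CC/R1 > RPW8
  breaks the (rare) ties where two signaling domains co-occur.
* **non-NLR** — everything else.

The architecture string assigns one letter per call in start order
(ties: longer call first) with adjacent identical letters collapsed —
`1`, `C`, `R`, `T`, `N`, `L`, `J`, `O` for R1, CC, RPW8, TIR, NB-ARC,
LRR, C-JID and other/integrated. Two consequences worth noting: a
protein with two NB-ARC regions separated only by a linker still reads
`...N...` (the repeat compression applies), while extraction still
yields two numbered domains; and degenerate NLRs typically carry an `O`
where their unsupported P-loop chain sits. For tool benchmarking,
[canonicalizeArchitecture()] further drops every letter outside
{T, C, R, N, L} and compresses again, because the compared tools only
annotate the canonical domains.

An open point in the category definitions is whether "NLR" should also
require a second domain besides the NB-ARC (the stricter definition used
for reference-set curation). Here NB-ARC alone suffices, and the
architecture column lets users apply the stricter filter themselves.

## Redundancy reduction

[pairwiseIdentity()] computes a global Needleman–Wunsch alignment with
match $+1$, mismatch $0$ and linear gap penalty $1$ (alignment itself
via Biostrings), and defines identity as identical aligned pairs divided
by the length of the *shorter* sequence — the CD-HIT convention.
[greedyCluster()] sorts records by length descending (ties by ID); each
record joins the first cluster whose representative (its longest member,
i.e. its founder) it matches at or above the threshold, else founds a
new cluster. The default threshold is 0.90. Because the identity here
comes from an exact alignment rather than a word filter, boundary cases
within a fraction of a percent of the threshold can differ from
CD-HIT's heuristic decisions.

[perGenusRepresentatives()] keeps one member per (cluster, genus) pair:
the cluster representative for its own genus and the longest member
(ties by ID) for other genera — the selection rule for non-founder
genera is not externally fixed, so longest-member is the declared
convention here. Members without a genus form their own pseudo-genus.

## Alignment preparation

[trimColumns()] keeps a column iff its site coverage (fraction of
non-gap rows) is at least the threshold; the default 0.95 and the
boundary convention "exactly 95% is kept" follow from the removal rule
being "less than 95%". `-` and `.` are gaps; `X` counts as coverage
(an ambiguous residue is still an observation of the column). The
operation is idempotent and never removes a gap-free column.
[lengthStats()] uses the $n-1$ standard deviation (the printed reference
statistics are integers, so either convention matches after rounding)
and flags outliers beyond mean $\pm$ 2 SD.

## Benchmarking metrics

Sensitivity is $100 \cdot \text{retrieved}/\text{total}$; specificity is
$100 \cdot TP/(TP+FP)$; architecture accuracy is the fraction of the
reference whose canonical predicted string equals the canonical
reference string. All percentages round half-up to one decimal, matching
the printed style of published comparisons. Per-ID verdicts are
`correct`, `incorrect`, `other` (retrieved but flagged as not reliably
classified — the flag is supplied by the tool adapter, since it is not
computable from architectures alone) and `missing`.
[intersectionCounts()] tallies IDs by their exact tool-membership
pattern, the quantity an UpSet plot displays.

## Synthetic fixtures

[generateProtein()] concatenates uniform-random residue segments per
architecture letter with 5–30 aa linkers, emits one signature hit per
segment with an accession drawn from that letter's vocabulary set, and
plants motif hits with chosen scores and q-values inside NB-ARC (or LRR)
segments. Defaults: planted motif score 90 and q-value $10^{-4}$ (clear
of both the 60 and 85 thresholds); [simulateNlrSet()] additionally
includes boundary fixtures at scores 59.9/60.0/84.9/85.0 and q-values
0.01/0.011, whose categories must flip exactly as the thresholds
dictate. The generator is deterministic per seed, byte-identical files
included.

What the fixtures emulate is the *evidence structure* — coordinates,
accession vocabulary, threshold interplay, file dialects. What they do
not emulate: real domain sequence content (residues are uniform), real
member-database disagreement and partial hits, compositional bias, or
the long tail of integrated domains. Passing the synthetic suite
therefore demonstrates that the rule logic, coordinate handling and
format round-trips are correct — not that any particular proteome will
be annotated with a given accuracy, which depends on the upstream
InterProScan and motif evidence.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data:
200 fixtures for the end-to-end suite, exhaustive motif enumeration up
to length 3 over alphabets up to 5 letters, clustering oracles on
families of 200–300 aa sequences. These sizes exercise every rule and
boundary while keeping the whole suite in the tens of seconds on one
CPU. Every stochastic step is seeded; the acceptance script derives all
randomness from its `--seed` argument.

## Known limitations

* Absolute scanner scores are not guaranteed to match meme-suite FIMO
  scores bit-for-bit (background handling and internal scaling differ in
  unpublished details); users who need FIMO-identical scores should scan
  externally and feed the TSV in — every threshold is an argument.
* Greedy clustering is exact but $O(n^2)$ in the worst case; it is meant
  for curated sets of at most a few thousand sequences, not proteome-scale
  clustering.
* The TX/CCX/RPW8 tier reads "lacking a P-loop" literally (see above);
  TIR-kinases therefore land in non-NLR rather than TX.
* PROSITE profile hits are taken as-is with no level filtering, in line
  with applying no extra cutoffs to signature evidence.
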