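sig <- function(id, acc, start, end) {
  data.frame(seq_id = id, analysis = plantNLR:::accessionAnalysis(acc),
             accession = acc, description = "", start = start, end = end,
             score = 1e-10, extra = "", stringsAsFactors = FALSE)
}
mot <- function(id, motif, start, score = 90, q = 1e-4, eligible = TRUE) {
  data.frame(seq_id = id, motif_id = as.character(motif), motif_alt_id = "",
             start = start, end = start + 14L, score = score, pvalue = q / 10,
             qvalue = q, matched_seq = "", extraction_eligible = eligible,
             stringsAsFactors = FALSE)
}
noMotifs <- function() cbind(plantNLR:::emptyMotifHits(),
                             extraction_eligible = logical())

test_that("same-category intervals merge across gaps up to the tolerance", {
  h <- rbind(sig("P", "PF00560", 10, 50), sig("P", "PF00560", 40, 90))
  m <- mergeCategoryIntervals(h, "LRR")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(10L, 90L))
  expect_equal(m$n_evidence, 2L)

  h2 <- rbind(sig("P", "PF00560", 10, 50), sig("P", "PF00560", 200, 260))
  expect_equal(nrow(mergeCategoryIntervals(h2, "LRR")), 2L)

  # gap of exactly 20 merges, 21 does not
  h3 <- rbind(sig("P", "PF00560", 10, 50), sig("P", "PF00560", 71, 90))
  expect_equal(nrow(mergeCategoryIntervals(h3, "LRR")), 1L)
  h4 <- rbind(sig("P", "PF00560", 10, 50), sig("P", "PF00560", 72, 90))
  expect_equal(nrow(mergeCategoryIntervals(h4, "LRR")), 2L)

  # random interval sets vs union-find oracle
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    st <- sample(500, n)
    en <- st + sample(10:80, n, replace = TRUE)
    got <- mergeCategoryIntervals(
      do.call(rbind, lapply(seq_len(n), function(i)
        sig("P", "PF00560", st[i], en[i]))), "LRR")
    want <- unionFindMerge(st, en, 20L)
    expect_equal(got$start, unname(want[, "start"]))
    expect_equal(got$end, unname(want[, "end"]))
  }
})

test_that("NB-ARC regions require a diagnostic signature or motif on the chain", {
  # an NB-ARC-specific signature alone suffices
  r <- detectNbarc(sig("P", "PF00931", 180, 460), noMotifs())
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(180L, 460L))
  expect_equal(r$support, "signature")

  # generic P-loop + diagnostic motif, no NB-ARC signature
  r2 <- detectNbarc(sig("P", "SSF52540", 150, 430), mot("P", 2, 400))
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$end), c(150L, 430L))
  expect_equal(r2$support, "motif")

  # generic P-loop alone: no region
  expect_equal(nrow(detectNbarc(sig("P", "SSF52540", 150, 430), noMotifs())),
               0L)

  # strict-ineligible MHD motif does not rescue the chain
  r3 <- detectNbarc(sig("P", "SSF52540", 150, 430),
                    mot("P", 7, 400, score = 70, eligible = FALSE))
  expect_equal(nrow(r3), 0L)

  # two disjoint chains are numbered by order in the protein
  r4 <- detectNbarc(rbind(sig("P", "PF00931", 600, 880),
                          sig("P", "PF00931", 100, 380)), noMotifs())
  expect_equal(r4$region, c(1L, 2L))
  expect_equal(r4$start, c(100L, 600L))

  # the region boundary extends to include an overlapping motif
  r5 <- detectNbarc(sig("P", "SSF52540", 150, 410), mot("P", 8, 400))
  expect_equal(c(r5$start, r5$end), c(150L, 414L))

  # monotone: adding evidence never removes a region
  base <- rbind(sig("P", "PF00931", 180, 460))
  more <- rbind(base, sig("P", "G3DSA:3.40.50.300", 170, 300),
                sig("P", "SSF46785", 440, 520))
  expect_gte(nrow(detectNbarc(more, mot("P", 2, 200))),
             nrow(detectNbarc(base, noMotifs())))
})

test_that("category rules assign the seven classes with the documented precedence", {
  prot <- setNames(paste(rep("ACDEFGHIKL", 100), collapse = ""), "P")

  cls <- function(sigs, motifs = NULL) {
    ann <- annotateNLR(prot, sigs, motifs,
                       prefiltered = !is.null(motifs) &&
                         "extraction_eligible" %in% names(motifs))
    classification(ann)
  }

  # NB-ARC present -> NLR
  expect_equal(cls(sig("P", "PF00931", 180, 460))$category, "NLR")

  # TIR only, no P-loop, no motif -> TX
  expect_equal(cls(sig("P", "PF01582", 10, 180))$category, "TX")

  # CC only -> CCX; RPW8 only -> RPW8; R1 only -> CCX
  expect_equal(cls(sig("P", "PF18052", 10, 60))$category, "CCX")
  expect_equal(cls(sig("P", "PF05659", 10, 120))$category, "RPW8")
  expect_equal(cls(sig("P", "PF12061", 10, 100))$category, "CCX")

  # RPW8 + clean P-loop NTPase hit -> degenerate NLR
  expect_equal(cls(rbind(sig("P", "PF05659", 10, 120),
                         sig("P", "SSF52540", 200, 400)))$category,
               "NLR-degenerate")

  # the same P-loop overlapped by another annotation is not clean
  expect_equal(cls(rbind(sig("P", "PF05659", 10, 120),
                         sig("P", "SSF52540", 200, 400),
                         sig("P", "PF00069", 180, 420)))$category,
               "non-NLR")

  # LRR + extraction-eligible MHD motif -> degenerate NLR
  expect_equal(cls(sig("P", "PF00560", 500, 700),
                   mot("P", 7, 550, score = 90))$category,
               "NLR-degenerate")
  # same motif below the strict cutoff -> not degenerate
  expect_equal(cls(sig("P", "PF00560", 500, 700),
                   mot("P", 7, 550, score = 70, eligible = FALSE))$category,
               "non-NLR")

  # HeLo domain -> MLKL
  expect_equal(cls(sig("P", "PF06760", 10, 150))$category, "MLKL")

  # no evidence at all -> non-NLR
  expect_equal(cls(plantNLR:::emptySignatureHits())$category, "non-NLR")

  # every sequence receives exactly one category from the seven
  expect_true(cls(sig("P", "PF00931", 180, 460))$category %in%
                nlrCategories())
})

test_that("architecture strings follow start order and compress repeats", {
  calls <- data.frame(category = c("CC", "NBARC", "LRR"),
                      start = c(1, 100, 500), end = c(60, 400, 700))
  expect_equal(buildArchitecture(calls), "CNL")

  calls2 <- data.frame(category = c("TIR", "NBARC", "LRR", "LRR", "LRR"),
                       start = c(1, 200, 500, 600, 700),
                       end = c(180, 480, 590, 690, 790))
  expect_equal(buildArchitecture(calls2), "TNL")

  calls3 <- data.frame(category = c("CC", "OTHER", "NBARC", "LRR"),
                       start = c(1, 70, 200, 500),
                       end = c(60, 150, 480, 700))
  expect_equal(buildArchitecture(calls3), "CONL")

  expect_equal(buildArchitecture(calls3[0, ]), "")
})

test_that("NB-ARC extraction numbers multiple regions and checks bounds", {
  prot <- Biostrings::AAStringSet(setNames(randomProtein(900, 51), "P"))
  reg1 <- data.frame(seq_id = "P", region = 1L, start = 180L, end = 460L,
                     support = "signature")
  out <- extractNbarc(prot, reg1)
  expect_equal(names(out), "P")
  expect_equal(Biostrings::width(out), 281L)
  expect_equal(as.character(out[[1]]),
               substr(as.character(prot[[1]]), 180, 460))

  reg2 <- rbind(reg1, data.frame(seq_id = "P", region = 2L, start = 500L,
                                 end = 800L, support = "signature"))
  expect_equal(names(extractNbarc(prot, reg2)), c("P_1", "P_2"))

  expect_length(extractNbarc(prot, reg1[0, ]), 0L)

  reg_bad <- data.frame(seq_id = "P", region = 1L, start = 180L,
                        end = 1000L, support = "signature")
  expect_error(extractNbarc(prot, reg_bad), "out of sequence bounds")
})

test_that("exact-string dedup keeps first-seen representatives with multiplicities", {
  x <- setNames(c("MKVL", "MKVL", "ACDE"), c("a", "b", "c"))
  d <- dedupeSequences(x)
  expect_equal(names(d$unique), c("a", "c"))
  expect_equal(d$multiplicity$n, c(2L, 1L))
  expect_equal(d$multiplicity$members[1], "a,b")

  y <- setNames(c("MK", "VL", "AC"), c("x", "y", "z"))
  expect_length(dedupeSequences(y)$unique, 3L)
})
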