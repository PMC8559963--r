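test_that("pairwise identity follows the shorter-sequence convention", {
  expect_equal(pairwiseIdentity("MKVL", "MKVL"), 1.0)
  expect_equal(pairwiseIdentity("AAAA", "AAAT"), 0.75)
  # symmetric
  a <- randomProtein(40, 61); b <- randomProtein(35, 62)
  expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
  # denominator is the shorter sequence: a perfect substring scores 1
  expect_equal(pairwiseIdentity("MKVLACDE", "VLAC"), 1.0)
})

test_that("alignment identity agrees with a quadratic-DP oracle on short pairs", {
  set.seed(63)
  for (rep in 1:15) {
    a <- randomProtein(sample(8:30, 1), seed = 1000 + rep)
    b <- randomProtein(sample(8:30, 1), seed = 2000 + rep)
    aln <- Biostrings::pairwiseAlignment(
      a, b, type = "global",
      substitutionMatrix = plantNLR:::identitySubstitutionMatrix(),
      gapOpening = 0, gapExtension = 1)
    # optimal score matches the DP oracle exactly
    expect_equal(Biostrings::score(aln), oracleAlignScore(a, b))
    # identical aligned pairs can never exceed the LCS length
    nid <- pairwiseIdentity(a, b) * min(nchar(a), nchar(b))
    expect_lte(nid, lcsLength(a, b) + 1e-9)
  }
  # substitution-only mutants realize exactly the planted identity
  seed_rec <- setNames(randomProtein(200, 64), "s")
  fam <- generateFamily(seed_rec, n = 5, identity = 0.9, seed = 65)
  for (i in seq_along(fam))
    expect_gte(pairwiseIdentity(seed_rec, as.character(fam[[i]])), 0.9)
})

test_that("greedy clustering joins by representative identity, longest first", {
  x <- setNames(c("MKVLMKVL", "MKVLMKVL", "MKVLMKVL"), c("a", "b", "c"))
  cl <- greedyCluster(x)
  expect_equal(max(cl$cluster), 1L)
  expect_equal(sum(cl$representative), 1L)

  # two unrelated sequences stay apart at 0.9
  y <- setNames(c(randomProtein(100, 71), randomProtein(100, 72)),
                c("u", "v"))
  expect_equal(max(greedyCluster(y)$cluster), 2L)

  # planted family (10 mutants at >= 0.92) + 5 unrelated randoms -> 6 clusters
  seed_rec <- setNames(randomProtein(300, 73), "fam")
  fam <- generateFamily(seed_rec, n = 10, identity = 0.92, seed = 74)
  unrelated <- setNames(
    vapply(1:5, function(i) randomProtein(280 + i, 80 + i), ""),
    paste0("rnd", 1:5))
  all_seq <- c(setNames(as.character(seed_rec), "fam"),
               setNames(as.character(fam), names(fam)), unrelated)
  cl <- greedyCluster(all_seq, threshold = 0.90)
  expect_equal(max(cl$cluster), 6L)
  # all-pairs oracle: every member matches its representative at >= 0.90
  reps <- cl$seq_id[cl$representative]
  for (i in seq_len(nrow(cl))) {
    r <- reps[cl$cluster[i]]
    expect_gte(pairwiseIdentity(all_seq[[r]], all_seq[[cl$seq_id[i]]]), 0.90)
  }
  # order invariance: shuffled input gives identical membership
  perm <- sample(length(all_seq))
  cl2 <- greedyCluster(all_seq[perm], threshold = 0.90)
  key <- function(d) sort(vapply(unname(split(d$seq_id, d$cluster)),
                                 function(v) paste(sort(v), collapse = ","),
                                 ""))
  expect_equal(key(cl), key(cl2))
})

test_that("per-genus representatives: one member per cluster-genus pair", {
  seed_rec <- setNames(randomProtein(200, 91), "o1")
  fam <- generateFamily(seed_rec, 3, identity = 0.95, seed = 92)
  seqs <- c(setNames(as.character(seed_rec), "o1"),
            setNames(as.character(fam), c("o2", "t1", "t2")))
  cl <- greedyCluster(seqs, 0.9)
  expect_equal(max(cl$cluster), 1L)
  genus <- c(o1 = "Oryza", o2 = "Oryza", t1 = "Triticum", t2 = "Triticum")
  reps <- perGenusRepresentatives(cl, seqs, genus)
  expect_equal(nrow(reps), 2L)          # one per genus in the cluster
  expect_setequal(reps$genus, c("Oryza", "Triticum"))
  # the cluster representative serves its own genus
  rep_id <- cl$seq_id[cl$representative]
  expect_true(rep_id %in% reps$seq_id)

  # single-genus clusters: one representative per cluster
  genus2 <- setNames(rep("Oryza", 4), names(seqs))
  expect_equal(nrow(perGenusRepresentatives(cl, seqs, genus2)), 1L)

  # empty input
  expect_equal(nrow(perGenusRepresentatives(cl[0, ], seqs, genus)), 0L)

  # reduced size bounded by clusters and clusters x genera
  expect_gte(nrow(reps), max(cl$cluster))
  expect_lte(nrow(reps), max(cl$cluster) * length(unique(genus)))
})
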