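toyPwm <- function(mat, alphabet = c("A", "C", "G", "T"), pc = 1e-4) {
  colnames(mat) <- alphabet
  PWMotif("toy", mat, pseudocount = pc)
}

test_that("window scores equal the per-position log-odds summation", {
  # closed form: single-position motif with P(A)=1, uniform background 1/20
  m <- matrix(0, 1, 20)
  m[1, 1] <- 1
  colnames(m) <- AA20_TEST
  pwm <- PWMotif("m1", m)
  sw <- scoreSequence(pwm, "AAA")
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$score, rep(log2(20 * (1 + 1e-4)), 3), tolerance = 1e-12)

  # all-low-probability letters give negative scores
  swC <- scoreSequence(pwm, "CCC")
  expect_true(all(swC$score < 0))

  # brute-force oracle on a random 200-aa sequence
  set.seed(11)
  mm <- matrix(runif(20 * 6), 6, 20)
  mm <- mm / rowSums(mm)
  colnames(mm) <- AA20_TEST
  pw <- PWMotif("w", mm)
  s <- randomProtein(200, seed = 12)
  sw <- scoreSequence(pw, s)
  lo <- log2((mm + 1e-4) / (1 / 20))
  ch <- strsplit(s, "")[[1L]]
  brute <- vapply(1:195, function(i)
    sum(vapply(1:6, function(j) lo[j, ch[i + j - 1L]], numeric(1))),
    numeric(1))
  expect_equal(sw$score, brute, tolerance = 1e-12)

  # out-of-alphabet letters contribute zero
  swx <- scoreSequence(pwm, "X")
  expect_equal(swx$score, 0)

  # sequence shorter than motif: empty, not an error
  expect_equal(nrow(scoreSequence(pw, "MK")), 0L)
})

test_that("exact p-values match exhaustive enumeration on small motifs", {
  # single-letter motif: P(score >= max) = 1/20
  m <- matrix(0, 1, 20)
  m[1, 1] <- 1
  colnames(m) <- AA20_TEST
  tab <- scorePvalueTable(PWMotif("m1", m))
  expect_equal(tab$pvalue[nrow(tab)], 1 / 20)
  expect_equal(tab$pvalue[1L], 1)

  # lengths 1..3 over 4- and 5-letter alphabets vs full enumeration
  for (L in 1:3) for (A in c(4L, 5L)) {
    set.seed(100 * L + A)
    mat <- matrix(runif(L * A), L, A)
    mat <- mat / rowSums(mat)
    colnames(mat) <- LETTERS[seq_len(A)]
    pwm <- PWMotif("e", mat)
    tab <- scorePvalueTable(pwm)
    expect_true(all(diff(tab$pvalue) <= 1e-12))       # monotone in score
    probe <- tab$score
    expect_equal(pvalueFromScore(tab, probe), enumPvalues(pwm, probe),
                 tolerance = 1e-6)
  }

  # p-value at the maximum attainable score = background prob of best word
  mat <- rbind(c(0.9, 0.05, 0.03, 0.02), c(0.6, 0.3, 0.05, 0.05))
  colnames(mat) <- c("A", "C", "G", "T")
  pwm <- PWMotif("b", mat)
  tab <- scorePvalueTable(pwm)
  expect_equal(tab$pvalue[nrow(tab)], 1 / 16, tolerance = 1e-9)
})

test_that("BH q-values match hand computation and are permutation-invariant", {
  expect_equal(bhQvalues(c(0.001, 0.01, 0.02, 0.05)),
               c(0.004, 0.02, 4 * 0.02 / 3, 0.05), tolerance = 1e-12)
  expect_equal(bhQvalues(0.5), 0.5)
  expect_error(bhQvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhQvalues(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(21)
  for (rep in 1:5) {
    p <- runif(40)
    q <- bhQvalues(p)
    expect_equal(q, handBH(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    perm <- sample(40)
    expect_equal(bhQvalues(p[perm]), q[perm], tolerance = 1e-12)
    # monotone non-decreasing in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }

  # subset of a larger family: q scales with the family size
  expect_equal(bhQvalues(c(0.001, 0.002), n_tests = 100),
               c(min(0.001 * 100 / 1, 0.002 * 100 / 2), 0.002 * 100 / 2))
})

test_that("score/q-value filter applies thresholds and strict eligibility flags", {
  hits <- data.frame(
    seq_id = "P", motif_id = c("2", "7", "2", "7", "8", "2"),
    motif_alt_id = c("RNBS-D", "MHD", "RNBS-D", "MHD", "linker", "RNBS-D"),
    start = 1L, end = 15L,
    score = c(61, 70, 59.9, 86, 85, 90),
    pvalue = 1e-9,
    qvalue = c(0.005, 0.005, 1e-4, 0.005, 0.01, 0.011),
    matched_seq = "X", stringsAsFactors = FALSE)
  out <- filterMotifHits(hits)
  # 59.9 dropped (score), 0.011 dropped (q)
  expect_equal(out$score, c(61, 70, 86, 85))
  # MHD at 70 kept for annotation but not extraction-eligible (70 < 85)
  expect_equal(out$extraction_eligible, c(TRUE, FALSE, TRUE, TRUE))
  # subset of input, idempotent
  expect_true(all(out$score %in% hits$score))
  expect_equal(filterMotifHits(out), out)
})

test_that("scanMotifs finds a planted exact motif with pooled q-values", {
  set.seed(31)
  L <- 8L
  word <- sample(AA20_TEST, L, replace = TRUE)
  m <- matrix(1e-6, L, 20, dimnames = list(NULL, AA20_TEST))
  for (j in seq_len(L)) m[j, word[j]] <- 1 - 19e-6
  pwm <- PWMotif("planted", m)
  seqs <- c(hit = paste0(randomProtein(80, 32), paste(word, collapse = ""),
                         randomProtein(80, 33)),
            bg = randomProtein(168, 34))
  hits <- scanMotifs(list(pwm), seqs)
  expect_true(any(hits$seq_id == "hit" & hits$start == 81L))
  best <- hits[hits$seq_id == "hit" & hits$start == 81L, ]
  expect_equal(best$matched_seq, paste(word, collapse = ""))
  expect_true(all(hits$qvalue >= hits$pvalue))
  # written output parses back identically
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFimoTsv(hits, f)
  back <- parseFimoTsv(f)
  expect_equal(back$start, hits$start)
  expect_equal(back$score, hits$score, tolerance = 1e-6)
})
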