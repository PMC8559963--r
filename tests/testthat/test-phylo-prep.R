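test_that("column trimming keeps columns at exactly the coverage threshold", {
  # 10 rows, one column with a single gap: coverage 0.90 < 0.95 -> removed
  rows <- c(rep("MK", 9), "M-")
  names(rows) <- paste0("s", 1:10)
  tr <- trimColumns(rows, 0.95)
  expect_equal(unique(Biostrings::width(tr)), 1L)
  expect_equal(as.character(tr[["s1"]]), "M")

  # gap-free alignment unchanged
  clean <- setNames(c("MKV", "ACD"), c("a", "b"))
  expect_equal(as.character(trimColumns(clean)), clean)

  # 100 rows, 5 gaps in a column: coverage exactly 0.95 -> kept
  rows2 <- setNames(c(rep("AC", 95), rep("A-", 5)), paste0("r", 1:100))
  tr2 <- trimColumns(rows2, 0.95)
  expect_equal(unique(Biostrings::width(tr2)), 2L)
  # but 6 gaps (0.94) -> removed
  rows3 <- setNames(c(rep("AC", 94), rep("A-", 6)), paste0("r", 1:100))
  expect_equal(unique(Biostrings::width(trimColumns(rows3, 0.95))), 1L)

  # X counts as coverage, '.' as gap
  rows4 <- setNames(c("AX", "A."), c("a", "b"))
  tr4 <- trimColumns(rows4, 0.95)
  expect_equal(as.character(tr4), c(a = "A", b = "A"))

  # idempotent; never removes a gap-free column; width never grows
  set.seed(77)
  mat <- replicate(30, paste(sample(c(AA20_TEST, "-"), 20, TRUE,
                                    prob = c(rep(1, 20), 3)), collapse = ""))
  names(mat) <- paste0("q", 1:30)
  t1 <- trimColumns(mat, 0.8)
  expect_equal(as.character(trimColumns(as.character(t1), 0.8)),
               as.character(t1))
  expect_lte(unique(Biostrings::width(t1)), nchar(mat[1]))

  # all columns gappy -> warning and empty alignment
  expect_warning(empty <- trimColumns(setNames(c("-A", "A-"), c("a", "b")),
                                      1.0),
                 "no column")
  expect_equal(unique(Biostrings::width(empty)), 0L)

  expect_error(trimColumns(setNames(c("AB", "A"), c("a", "b"))),
               "differ in length")
})

test_that("length statistics use n-1 sd and flag 2-SD outliers", {
  recs <- setNames(strrep("A", c(100, 200, 300)), c("a", "b", "c"))
  st <- lengthStats(recs)
  expect_equal(st$mean, 200)
  expect_equal(st$min, 100)
  expect_equal(st$max, 300)
  expect_equal(st$sd, sd(c(100, 200, 300)))

  one <- lengthStats(setNames("AAAA", "x"))
  expect_equal(one$sd, 0)
  expect_length(one$outlier_ids, 0L)

  # one extreme length among many equal ones is flagged
  recs2 <- setNames(strrep("A", c(rep(300, 30), 100)),
                    c(paste0("n", 1:30), "short"))
  expect_equal(lengthStats(recs2)$outlier_ids, "short")

  expect_error(lengthStats(character()), "no sequences")
})

test_that("group counts order by descending count then name, top-k share sums", {
  g <- c("Oryza", "Oryza", "Oryza", "Triticum", "Triticum")
  gc <- groupCounts(g)
  expect_equal(gc$key, c("Oryza", "Triticum"))
  expect_equal(sum(gc$count), length(g))

  expect_equal(nrow(groupCounts(character())), 0L)
  expect_equal(groupCounts(c("a", NA, ""))$key, c("unknown", "a"))

  # top-k share equals a sort-and-sum oracle
  set.seed(78)
  g2 <- sample(letters[1:12], 500, replace = TRUE,
               prob = c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 1, 1))
  want <- roundHalfUp(100 * sum(sort(table(g2), decreasing = TRUE)[1:7]) /
                        500)
  expect_equal(topGroupShare(g2, 7), want)
})

test_that("relaxed PHYLIP round-trips exactly and validates the header", {
  aln <- setNames(c("MKVL", "AC-E"), c("seq_one", "seq_two"))
  f <- withr::local_tempfile(fileext = ".phy")
  writePhylip(aln, f)
  expect_equal(readLines(f)[1L], "2 4")
  back <- readPhylip(f)
  expect_equal(as.character(back), aln)

  writeLines(c("3 4", "a MKVL", "b ACDE"), f)
  expect_error(readPhylip(f), "announces 3 rows")
  writeLines(c("2 4", "a MKVL", "b ACD"), f)
  expect_error(readPhylip(f), "row length")
})
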