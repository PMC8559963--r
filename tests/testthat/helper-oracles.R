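# Independent oracles used by the test suite. Each deliberately takes the
# slow, direct route (enumeration, brute force, hand formulas) so it shares
# no code with the implementation it checks.

AA20_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

randomProtein <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA20_TEST, n, replace = TRUE), collapse = "")
}

# step-up Benjamini-Hochberg, written from the definition:
# q_i = min over j with p_j >= p_i of p_j * n / rank_j
handBH <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    cand <- which(p >= p[i] - 1e-15)
    min(1, min(p[cand] * n / r[cand]))
  }, numeric(1))
}

# exhaustive p-values for a PWM: enumerate all |alphabet|^L words with their
# background probabilities, quantizing per-position scores exactly as the
# scanner does (quantization is part of the operation's definition), and
# tally the upper tail directly
enumPvalues <- function(pwm, scores, granularity = 0.001) {
  m <- pwm@matrix
  lo <- log2(sweep(m + pwm@pseudocount, 2L, pwm@background[colnames(m)], "/"))
  loq <- round(lo / granularity)
  L <- nrow(m)
  A <- ncol(m)
  grid <- do.call(expand.grid, rep(list(seq_len(A)), L))
  word_scores <- rowSums(vapply(seq_len(L), function(j) loq[j, grid[[j]]],
                                numeric(nrow(grid))))
  word_prob <- apply(vapply(seq_len(L), function(j)
    pwm@background[colnames(m)][grid[[j]]], numeric(nrow(grid))), 1L, prod)
  vapply(round(scores / granularity), function(s)
    sum(word_prob[word_scores >= s]), numeric(1))
}

# brute-force merging of intervals whose overlap-or-gap<=G graph connects
# them: union-find over all pairs
unionFindMerge <- function(start, end, gap) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    # connected iff the gap between the intervals is <= G residues
    # (gap = max(start) - min(end) - 1; overlap gives a non-positive gap)
    if (i < j &&
        max(start[i], start[j]) - min(end[i], end[j]) - 1L <= gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(comp), function(k) {
    idx <- comp == k
    c(start = min(start[idx]), end = max(end[idx]))
  }))
  out[order(out[, "start"]), , drop = FALSE]
}

# optimal global alignment score under match=1, mismatch=0, linear gap -1
oracleAlignScore <- function(a, b) {
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1L, m + 1L)
  M[, 1L] <- -(0:n); M[1L, ] <- -(0:m)
  for (i in seq_len(n)) for (j in seq_len(m))
    M[i + 1L, j + 1L] <- max(M[i, j] + (x[i] == y[j]),
                             M[i, j + 1L] - 1, M[i + 1L, j] - 1)
  M[n + 1L, m + 1L]
}

# longest common subsequence length: upper bound on aligned identical pairs
lcsLength <- function(a, b) {
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  M <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m))
    M[i + 1L, j + 1L] <- max(M[i, j] + (x[i] == y[j]), M[i, j + 1L],
                             M[i + 1L, j])
  M[n + 1L, m + 1L]
}

# per-ID membership-pattern tally for intersection counts
bitmaskIntersections <- function(sets) {
  ids <- unique(unlist(sets))
  pat <- vapply(ids, function(id)
    paste(names(sets)[vapply(sets, function(s) id %in% s, logical(1))],
          collapse = "+"), "")
  as.list(table(pat))
}

# run the full pipeline over emitted mock files and return classification
# merged with the truth table
runPipelineOnFixtures <- function(fixtures, dir = tempfile()) {
  paths <- emitMockFiles(fixtures, dir)
  prot <- readProteinFasta(paths[["fasta"]])
  sig <- parseInterproTsv(paths[["ipr"]])
  mot <- parseFimoTsv(paths[["fimo"]])
  cj <- readCjidDomtbl(paths[["cjid"]])
  truth <- read.table(paths[["truth"]], sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  ann <- annotateNLR(prot, sig, mot, cjid = cj)
  merge(classification(ann), truth, by.x = "seq_id", by.y = "id",
        suffixes = c("", ".truth"))
}
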