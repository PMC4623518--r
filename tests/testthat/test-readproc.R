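pair100 <- function(id = "p1") {
  set.seed(99)
  s <- function() paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  pairRow(id, s(), s())
}

test_that("hard trimming removes the specified bases from each end", {
  pr <- pair100()
  out <- applyTrim(pr, TrimSpec(6, 30, 17, 30))
  expect_equal(nchar(out$pairs$seq1), 64)  # 100 - 6 - 30
  expect_equal(nchar(out$pairs$seq2), 53)  # 100 - 17 - 30
  expect_equal(nchar(out$pairs$qual1), 64)
  expect_equal(out$pairs$seq1, substr(pr$seq1, 7, 70))
  ## zero spec is the identity
  expect_equal(applyTrim(pr, TrimSpec())$pairs, pr)
})

test_that("pairs falling under the minimum length are dropped and counted", {
  short <- pairRow("s", strrep("A", 35), strrep("C", 100))
  both <- rbind(short, pair100("ok"))
  out <- applyTrim(both, TrimSpec(6, 30, 0, 0), minLen = 30)
  expect_equal(out$pairs$id, "ok")
  expect_equal(out$report$input, 2)
  expect_equal(out$report$kept + out$report$dropped, out$report$input)
  ## a trim consuming a whole read also just drops the pair
  out <- applyTrim(short, TrimSpec(0, 40, 0, 0), minLen = 30)
  expect_equal(nrow(out$pairs), 0)
  expect_equal(out$report$dropped, 1)
})

test_that("duplicate removal keeps first occurrences and counts fractions", {
  a <- pairRow("a", "ACGT", "TTTT")
  b <- pairRow("b", "ACGT", "TTTT", q1 = "!!!!", q2 = "!!!!")  # same seqs
  c3 <- pairRow("c", "GGGG", "CCCC")
  d4 <- pairRow("d", "ACGTA", "TTT")
  res <- removeDuplicates(rbind(a, b, a, c3, d4))
  expect_equal(res$pairs$id, c("a", "c", "d"))
  expect_equal(res$report$unique_pairs, 3)
  expect_equal(res$report$duplicate_fraction, 2 / 5)
  ## idempotence
  again <- removeDuplicates(res$pairs)
  expect_equal(again$pairs, res$pairs)
  expect_equal(again$report$duplicate_fraction, 0)
})

test_that("measured duplicate fraction tracks the simulated duplication rate", {
  sim <- simulateLibrary(simParams(nPairs = 20000, dupRate = 0.64, seed = 7))
  f <- removeDuplicates(sim$pairs)$report$duplicate_fraction
  expect_lt(abs(f - 0.64), 0.01)
  ## and tracks the truth table (distinct fragments may rarely collide in
  ## sequence, so agreement is to within a couple of pairs, not exact)
  expect_lt(abs(f - mean(!is.na(sim$truthPairs$duplicate_of))), 3 / 20000)
})

test_that("quality filtering applies mean-quality and N-fraction rules", {
  q40 <- pairRow("good", "ACGT", "ACGT",
                 q1 = phredString(rep(40L, 4)), q2 = phredString(rep(40L, 4)))
  expect_equal(nrow(qualityFilter(q40)$pairs), 1)
  ## mean exactly at the threshold is kept (>= semantics)
  atThr <- pairRow("at", "AC", "AC",
                   q1 = phredString(c(19L, 21L)), q2 = phredString(c(20L, 20L)))
  expect_equal(nrow(qualityFilter(atThr, minMeanQ = 20)$pairs), 1)
  below <- pairRow("below", "AC", "AC",
                   q1 = phredString(c(19L, 20L)), q2 = phredString(c(40L, 40L)))
  expect_equal(nrow(qualityFilter(below, minMeanQ = 20)$pairs), 0)
  ## 50% N is dropped; either failing mate drops the pair
  nn <- pairRow("nn", "ANNT", "ACGT",
                q1 = phredString(rep(40L, 4)), q2 = phredString(rep(40L, 4)))
  expect_equal(nrow(qualityFilter(nn)$pairs), 0)
})

test_that("full read-through pairs merge back to the fragment", {
  set.seed(21)
  frag <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  pr <- pairRow("f", frag, revComp(frag))
  res <- mergeOverlaps(pr)
  expect_equal(nrow(res$merged), 1)
  expect_equal(res$merged$seq, frag)
  expect_equal(nchar(res$merged$seq), 80)
  expect_equal(res$details$overlap_len, 80)
  expect_equal(res$merged$mate, "merged")
})

test_that("pairs without a usable overlap stay paired", {
  set.seed(3)
  frag <- paste(sample(c("A", "C", "G", "T"), 220, TRUE), collapse = "")
  r1 <- substr(frag, 1, 100)
  r2 <- revComp(substr(frag, 121, 220))
  res <- mergeOverlaps(pairRow("np", r1, r2))
  expect_equal(nrow(res$merged), 0)
  expect_equal(nrow(res$pairs), 1)
})

test_that("overlap disagreements resolve to the higher-quality base", {
  frag <- strrep("ACGT", 10)  # 40 bp, full overlap
  r1 <- frag
  r2seq <- frag
  substr(r2seq, 5, 5) <- "T"  # disagree at column 5
  q1 <- phredString(rep(40L, 40))
  q2 <- phredString(c(rep(35L, 35), rep(2L, 5)))  # after RC: low qual at col 1..5
  pr <- pairRow("d", r1, revComp(r2seq), q1 = q1, q2 = q2)
  res <- mergeOverlaps(pr)
  expect_equal(nrow(res$merged), 1)
  expect_equal(res$details$mismatches_in_overlap, 1)
  expect_equal(substr(res$merged$seq, 5, 5), "A")  # the Q40 base wins
  ## merged qualities take the per-column maximum
  expect_equal(phredScores(res$merged$qual)[[1]][5], 40L)
})

test_that("merged read lengths reproduce the truth fragment lengths", {
  sim <- simulateLibrary(simPreset("undamaged", nPairs = 5000, seed = 13))
  res <- mergeOverlaps(sim$pairs)
  fl <- sim$truthPairs$frag_len
  mergeable <- fl <= 2L * sim$params$readLen - 11L
  expect_equal(sum(res$details$merged), sum(mergeable))
  expect_equal(nchar(res$merged$seq), fl[res$details$merged])
  ks <- suppressWarnings(stats::ks.test(nchar(res$merged$seq), fl[mergeable]))
  expect_gt(ks$p.value, 0.01)
})
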