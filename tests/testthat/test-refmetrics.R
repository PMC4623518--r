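test_that("error rate is zero on error-free data and undefined off-target", {
  sim <- simulateLibrary(simParams(nPairs = 500, seed = 1, e0 = 0))
  er <- errorRate(sim$alignments, sim$reference, "ref1")
  expect_equal(er$rate, 0)
  expect_gt(er$aligned_bases, 0)
  ## a region nothing aligns to has no defined rate
  ref2 <- c(sim$reference, other = strrep("A", 2000))
  expect_error(errorRate(sim$alignments, ref2, "other"), "undefined error rate")
})

test_that("error rate recovers the injected baseline error", {
  sim <- simulateLibrary(simParams(nPairs = 20000, seed = 2, e0 = 0.006))
  er <- errorRate(sim$alignments, sim$reference, "ref1")
  sigma <- sqrt(0.006 * 0.994 / er$aligned_bases)
  expect_lt(abs(er$rate - 0.006), 3 * sigma)
  expect_equal(er$rate, er$mismatched_bases / er$aligned_bases)
})

test_that("one read on one bin gives the expected count and depth", {
  ref <- c(chr = strrep("A", 10000))
  aln <- makeAln("r", 0L, "chr", 501L, "100M", strrep("A", 100))
  cv <- coverageBins(aln, ref, binSize = 10000)
  expect_equal(nrow(cv$bins), 1)
  expect_equal(cv$bins$read_count, 1)
  expect_equal(cv$bins$mean_depth, 0.01)
  expect_equal(cv$summary$breadth, 100 / 10000)
})

test_that("a perfect tiling covers every bin at depth 1", {
  ref <- c(chr = strrep("ACGT", 2500))
  starts <- seq(1, 9901, by = 100)
  aln <- do.call(rbind, lapply(starts, function(s)
    makeAln(paste0("t", s), 0L, "chr", s, "100M",
            substr(ref[["chr"]], s, s + 99))))
  cv <- coverageBins(aln, ref, binSize = 1000)
  expect_equal(nrow(cv$bins), 10)
  expect_true(all(cv$bins$mean_depth == 1))
  expect_equal(sum(cv$bins$read_count), nrow(aln))
  expect_equal(cv$summary$breadth, 1)
  expect_equal(cv$summary$mean_depth, 1)
})

test_that("an empty alignment set yields a zero coverage table", {
  ref <- c(chr = strrep("A", 5000))
  aln <- makeAln("x", 0L, "chr", 1L, "4M", "AAAA")[0, ]
  cv <- coverageBins(aln, ref, binSize = 1000)
  expect_true(all(cv$bins$read_count == 0))
  expect_true(all(cv$bins$mean_depth == 0))
  expect_equal(cv$summary$breadth, 0)
})

test_that("binned depth and breadth match the truth-interval oracle", {
  sim <- simulateLibrary(simParams(nPairs = 1500, seed = 9, refLength = 50000))
  cv <- coverageBins(sim$alignments, sim$reference, binSize = 1000)
  d <- oracleDepth(sim$alignments, 50000)
  expect_equal(cv$summary$breadth, mean(d > 0))
  expect_equal(cv$summary$mean_depth, mean(d))
  om <- sapply(seq(1, 50000, by = 1000), function(s) mean(d[s:(s + 999)]))
  expect_equal(cv$bins$mean_depth, om)
})

test_that("pileups count aligned bases per position, depth matching truth", {
  ref <- c(chr = strrep("A", 1200))
  aln <- rbind(
    makeAln("a", 0L, "chr", 101L, "4M", "ACGT"),
    makeAln("b", 0L, "chr", 102L, "4M", "CGTA"),
    makeAln("n", 0L, "chr", 101L, "4M", "ANGT")
  )
  pu <- buildPileup(aln, ref, "chr")
  expect_equal(unname(pu$counts["A", 101]), 2L)  # reads a and n
  expect_equal(unname(pu$counts["C", 102]), 2L)  # both disagreeing reads counted
  expect_equal(unname(pu$depth[102]), 2L)        # N base at 102 in read n excluded
  expect_equal(sum(pu$counts), sum(pu$depth))
  sim <- simulateLibrary(simParams(nPairs = 800, seed = 4, refLength = 20000))
  pu <- buildPileup(sim$alignments, sim$reference, "ref1")
  expect_equal(unname(pu$depth), oracleDepth(sim$alignments, 20000))
})

test_that("consensus calling follows depth, majority and tie rules", {
  ref <- c(chr = paste0("A", strrep("G", 9)))
  mk <- function(counts) {
    m <- matrix(0L, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
    m[, 1] <- counts
    list(region = list(name = "chr", start = 1L, end = 10L),
         counts = m, depth = colSums(m))
  }
  ## depth 10 all A over ref A: called, not a SNP
  cs <- callConsensus(mk(c(10L, 0L, 0L, 0L)), ref)
  expect_equal(substr(cs$sequence, 1, 1), "A")
  expect_equal(nrow(cs$snps), 0)
  ## depth 10 all T over ref A: a SNP
  cs <- callConsensus(mk(c(0L, 0L, 0L, 10L)), ref)
  expect_equal(substr(cs$sequence, 1, 1), "T")
  expect_equal(cs$snps$pos, 1L)
  expect_equal(cs$snps$ref, "A")
  expect_equal(cs$snps$alt, "T")
  ## depth 2 is uncallable regardless of agreement
  cs <- callConsensus(mk(c(2L, 0L, 0L, 0L)), ref)
  expect_equal(substr(cs$sequence, 1, 1), "N")
  ## exact ties are N, not the reference base
  cs <- callConsensus(mk(c(5L, 5L, 0L, 0L)), ref)
  expect_equal(substr(cs$sequence, 1, 1), "N")
  ## below the majority fraction is N
  cs <- callConsensus(mk(c(7L, 3L, 0L, 0L)), ref, majFrac = 0.75)
  expect_equal(substr(cs$sequence, 1, 1), "N")
  expect_equal(cs$called_sites, 0)
})

test_that("consensus dissimilarity recovers an injected substitution rate", {
  ref <- makeReference(15000, 0.4, seed = 31, name = "MT")
  np <- round(40 * 15000 / (2 * 98))
  sim <- simulateLibrary(simParams(reference = ref, nPairs = np,
                                   sampleDivergence = 0.005, seed = 17))
  cs <- callConsensus(buildPileup(sim$alignments, ref, "MT"), ref)
  ## nearly every injected substitution is recovered; a site can drop out
  ## when sampling leaves it under-covered or errors break the majority
  expect_lt(abs(nrow(cs$snps) - nrow(sim$substitutions)), 3)
  sigma <- sqrt(0.005 * 0.995 / cs$called_sites)
  expect_lt(abs(cs$dissimilarity - 0.005), 3 * sigma)
})

test_that("GC content counts G+C over unambiguous bases only", {
  expect_equal(gcContent("GGCC"), 1)
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(gcContent(c("GGNN", "AANN")), 0.5)
  expect_error(gcContent("NNNN"), "undefined GC content")
  gc <- gcContent(makeReference(100000, 0.40, seed = 12))
  expect_lt(abs(gc - 0.40), 0.005)
})

test_that("length filtering and N50 follow the standard definitions", {
  contigs <- c(strrep("A", 100), strrep("C", 200), strrep("G", 300))
  lf <- lengthFilter(contigs, minLen = 200)
  expect_equal(nchar(lf$contigs), c(200, 300))
  expect_equal(lf$n50, 300)
  expect_equal(lengthFilter(strrep("A", 500), 200)$n50, 500)
  expect_warning(lf0 <- lengthFilter(c("ACGT"), 200), "N50 undefined")
  expect_equal(lf0$n50, 0L)
})
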