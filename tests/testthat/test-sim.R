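test_that("reference generation is seeded, composition-true and validated", {
  a <- makeReference(5000, 0.4, seed = 1)
  b <- makeReference(5000, 0.4, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, makeReference(5000, 0.4, seed = 2)))
  expect_error(makeReference(5000, 1.0), "open interval")
  expect_error(makeReference(500, 0.5), "length >= 1000")
})

test_that("presets encode the two specimen regimes and the clean control", {
  expect_equal(simPreset("undamaged")$damage$mode, "none")
  expect_equal(simPreset("undamaged")$dupRate, 0)
  expect_equal(simPreset("good_specimen")$dupRate, 0.64)
  expect_equal(simPreset("failed_specimen")$dupRate, 0.975)
  expect_equal(simPreset("good_specimen")$damage$amplitude, 0.02)
  expect_error(simPreset("nope"))
})

test_that("identical parameters give byte-identical simulator output", {
  p <- simPreset("good_specimen", nPairs = 400, seed = 123)
  d <- withr::local_tempdir()
  writeSimLibrary(simulateLibrary(p), file.path(d, "a"), gzip = FALSE)
  writeSimLibrary(simulateLibrary(p), file.path(d, "b"), gzip = FALSE)
  for (suffix in c("_R1.fastq", "_R2.fastq", "_truth.sam",
                   "_truth_pairs.tsv", "_truth_events.tsv")) {
    expect_identical(readLines(file.path(d, paste0("a", suffix))),
                     readLines(file.path(d, paste0("b", suffix))),
                     label = suffix)
  }
})

test_that("error-free simulations produce reads identical to the reference", {
  sim <- simulateLibrary(simParams(nPairs = 100, seed = 5, e0 = 0))
  ex <- extractMismatches(sim$alignments, sim$reference)
  expect_equal(nrow(ex$observations), 0)
  expect_equal(nrow(sim$truthEvents), 0)
})

test_that("every injected event matches exactly one extracted mismatch", {
  sim <- simulateLibrary(simParams(nPairs = 1500, seed = 6, dupRate = 0.5,
                                   damage = damageModel("formalin", 0.03, 8),
                                   e0 = 0.004))
  ex <- extractMismatches(sim$alignments, sim$reference)
  ev <- sim$truthEvents
  expect_equal(
    sort(paste(ev$pair_id, ev$mate, ev$offset, ev$true_base, ev$emitted_base)),
    obsKey(ex$observations)
  )
})

test_that("duplicates share fragment coordinates and sequences with their
           originals", {
  sim <- simulateLibrary(simParams(nPairs = 3000, seed = 10, dupRate = 0.6))
  tp <- sim$truthPairs
  dups <- which(!is.na(tp$duplicate_of))
  expect_gt(length(dups), 1000)
  orig <- match(tp$duplicate_of[dups], tp$pair_id)
  expect_true(all(orig < dups))               # originals precede duplicates
  expect_true(all(is.na(tp$duplicate_of[orig])))  # and are not duplicates
  expect_equal(tp$start[dups], tp$start[orig])
  expect_equal(tp$end[dups], tp$end[orig])
  expect_equal(sim$pairs$seq1[dups], sim$pairs$seq1[orig])
  expect_equal(sim$pairs$seq2[dups], sim$pairs$seq2[orig])
})

test_that("fragments respect the floor and short fragments give short reads", {
  sim <- simulateLibrary(simParams(nPairs = 2000, seed = 20,
                                   fragMeans = c(60, 120)))
  fl <- sim$truthPairs$frag_len
  expect_true(all(fl >= 35))
  short <- fl < 100
  expect_gt(sum(short), 100)
  expect_equal(nchar(sim$pairs$seq1[short]), fl[short])
  ## R1 and R2 of a sub-read-length fragment are reverse complements
  i <- which(short)[1]
  expect_equal(revComp(sim$pairs$seq2[i]), sim$pairs$seq1[i])
})

test_that("per-type damage frequency at the read start matches enumeration", {
  ## uniform type weights conditioned on the true base put (a + e0)/3 on
  ## each of the 3 alternatives; with a gc=0.5 reference every type then
  ## sits at (a + e0)/12 at offset 0, and near e0/12 deep inside the read
  a <- 0.02; e0 <- 0.002
  sim <- simulateLibrary(simParams(nPairs = 20000, seed = 1, gc = 0.5,
                                   damage = damageModel("formalin", a, 8),
                                   e0 = e0))
  ex <- extractMismatches(sim$alignments, sim$reference)
  p <- accumulateProfile(ex$observations, ex$columnCounts, "R1")
  f <- profileFreq(p, "5")
  den <- profileDenom(p, "5")
  expected0 <- (a + e0) / 12
  sigma0 <- sqrt(expected0 / den[1])
  expect_true(all(abs(f[, "0"] - expected0) < 4 * sigma0))
  expected40 <- (e0 + a * exp(-40 / 8)) / 12
  sigma40 <- sqrt(expected40 / den[41])
  expect_true(all(abs(f[, "40"] - expected40) < 4 * sigma40))
  ## pooled frequency is composition-free: a * exp(-i/lambda) + e0
  pooled <- colSums(f)
  expect_lt(abs(pooled[1] - (a + e0)), 4 * sqrt((a + e0) / den[1]))
})

test_that("aDNA mode concentrates damage types by end", {
  sim <- simulateLibrary(simParams(nPairs = 8000, seed = 2,
                                   damage = damageModel("adna", 0.05, 8),
                                   e0 = 0))
  ex <- extractMismatches(sim$alignments, sim$reference)
  p <- accumulateProfile(ex$observations, ex$columnCounts, "R1")
  c5 <- profileCounts(p, "5")
  c3 <- profileCounts(p, "3")
  expect_gt(c5["C>T", "0"] / max(sum(c5[, "0"]), 1), 0.95)
  expect_gt(c3["G>T", "0"] / max(sum(c3[, "0"]), 1), 0.95)
})

test_that("presets drive the pipeline end to end as expected", {
  good <- simulateLibrary(simPreset("good_specimen", nPairs = 20000, seed = 3))
  ex <- extractMismatches(good$alignments, good$reference)
  det <- detectTrim(accumulateProfile(ex$observations, ex$columnCounts, "R1"),
                    accumulateProfile(ex$observations, ex$columnCounts, "R2"))
  expect_true(all(trimVector(det$spec) > 0))

  clean <- simulateLibrary(simPreset("undamaged", nPairs = 20000, seed = 3))
  exc <- extractMismatches(clean$alignments, clean$reference)
  detc <- detectTrim(accumulateProfile(exc$observations, exc$columnCounts, "R1"),
                     accumulateProfile(exc$observations, exc$columnCounts, "R2"))
  expect_equal(unname(trimVector(detc$spec)), rep(0L, 4))

  failed <- simulateLibrary(simPreset("failed_specimen", nPairs = 20000, seed = 3))
  dd <- removeDuplicates(failed$pairs)
  expect_lt(dd$report$unique_pairs / nrow(failed$pairs), 0.05)
})
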