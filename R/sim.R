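## Index matrix: ALT_IDX[true base, k] = index (into BASES) of the k-th
## alternative base, k = 1..3.
ALT_IDX <- t(vapply(1:4, function(i) setdiff(1:4, i), integer(3)))

#' Describe an end-anchored damage model
#'
#' Damage substitutes a read base with probability `amplitude *
#' exp(-offset/lambda)`, where offset is the 0-based distance from the read
#' end; the 5' and 3' processes act independently. The substituting type is
#' drawn from `typeWeights` conditioned on the true base (a drawn type
#' whose reference base differs from the true base is redrawn, which is
#' equivalent to renormalising the weights over the three types available
#' at that base; a base at which the model places no weight is left
#' untouched).
#'
#' Modes: `formalin` spreads weight uniformly over all 12 substitution
#' types at both ends (all mismatch types rise at both read ends, sharper
#' towards 3'); `adna` places the 5' weight on C->T and the 3' weight on
#' G->T (the classic deamination signature of non-formalin historical DNA);
#' `none` disables damage.
#'
#' @param mode "formalin", "adna" or "none".
#' @param amplitude Extra per-base substitution probability at offset 0.
#' @param lambda Exponential decay length scale in bases.
#' @param typeWeights Optional list with elements `w5` and `w3`, numeric
#'   12-vectors over the lexicographically ordered types (see
#'   [exportProfile()] ordering); overrides the mode's defaults.
#' @return A named list describing the model.
#' @export
damageModel <- function(mode = c("none", "formalin", "adna"),
                        amplitude = NULL, lambda = NULL, typeWeights = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    none = list(amplitude = 0, lambda = 1),
    formalin = list(amplitude = 0.02, lambda = 8),
    adna = list(amplitude = 0.02, lambda = 8)
  )
  amplitude <- if (is.null(amplitude)) defaults$amplitude else amplitude
  lambda <- if (is.null(lambda)) defaults$lambda else lambda
  stopifnot(amplitude >= 0, amplitude <= 0.5, lambda > 0)
  if (is.null(typeWeights)) {
    tt <- mismatchTypes()
    typeWeights <- switch(mode,
      none = ,
      formalin = list(w5 = rep(1 / 12, 12), w3 = rep(1 / 12, 12)),
      adna = list(
        w5 = as.numeric(tt$ref == "C" & tt$alt == "T"),
        w3 = as.numeric(tt$ref == "G" & tt$alt == "T")
      )
    )
  }
  stopifnot(length(typeWeights$w5) == 12, length(typeWeights$w3) == 12)
  list(mode = mode, amplitude = amplitude, lambda = lambda,
       typeWeights = lapply(typeWeights, function(w) w / sum(w)))
}

#' Generate a random reference sequence
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2;
#' deterministic for a given seed.
#'
#' @param length Sequence length (at least 1000).
#' @param gc GC fraction, open interval (0, 1).
#' @param seed Optional RNG seed.
#' @param name Sequence name.
#' @return A reference set (named character vector of length 1).
#' @export
makeReference <- function(length, gc = 0.5, seed = NULL, name = "ref1") {
  stopifnot(length >= 1000)
  if (!(gc > 0 && gc < 1)) stop("gc must lie in the open interval (0, 1)")
  withSeed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    s <- paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
    stats::setNames(s, name)
  })
}

#' Simulation parameters
#'
#' Defaults emulate a short-fragment paired-end library from a
#' formalin-fixed specimen: 100 bp paired-end reads from a bimodal insert
#' distribution (lognormal components around 120 bp and 240 bp, mixed
#' 50/50), constant Q35 base qualities, an i.i.d. baseline sequencing error
#' rate, PCR duplication, and an end-anchored damage model. Duplicates are
#' exact copies of a previously emitted pair: PCR copies share the template
#' (and its damage and polymerase errors), which is what makes them exact
#' sequence duplicates removable by [removeDuplicates()].
#'
#' @param reference A reference set (named character vector, single
#'   sequence), or NULL to generate one with [makeReference()].
#' @param refLength,gc,refName Used when `reference` is NULL.
#' @param nPairs Number of read pairs emitted.
#' @param readLen Read length (default 100; reads from fragments shorter
#'   than this equal the fragment, with no adapter read-through simulated).
#' @param fragMeans,fragSdLog,fragWeights Lognormal fragment-length mixture:
#'   component medians in bp, common log-sd, mixture weights.
#' @param minFrag Minimum fragment length (shorter draws are clamped).
#' @param e0 Baseline per-base sequencing error probability (substitution
#'   to a uniformly chosen different base).
#' @param dupRate Probability that an emitted pair is a PCR duplicate of a
#'   previously emitted pair (in `[0, 1)`).
#' @param damage A model from [damageModel()].
#' @param qual Constant Phred base quality.
#' @param sampleDivergence Per-site substitution rate between the sequenced
#'   individual and the reference (applied to the sequencing template).
#' @param seed RNG seed; identical parameters including the seed give
#'   byte-identical output.
#' @return A named parameter list for [simulateLibrary()].
#' @export
simParams <- function(reference = NULL, refLength = 200000L, gc = 0.40,
                      refName = "ref1", nPairs = 10000L, readLen = 100L,
                      fragMeans = c(120, 240), fragSdLog = 0.25,
                      fragWeights = c(0.5, 0.5), minFrag = 35L,
                      e0 = 0.002, dupRate = 0, damage = damageModel("none"),
                      qual = 35L, sampleDivergence = 0, seed = NULL) {
  stopifnot(nPairs > 0, readLen >= 30, dupRate >= 0, dupRate < 1,
            e0 >= 0, e0 < 1, sampleDivergence >= 0, sampleDivergence < 1,
            length(fragMeans) == length(fragWeights))
  list(reference = reference, refLength = as.integer(refLength), gc = gc,
       refName = refName, nPairs = as.integer(nPairs),
       readLen = as.integer(readLen), fragMeans = fragMeans,
       fragSdLog = fragSdLog, fragWeights = fragWeights / sum(fragWeights),
       minFrag = as.integer(minFrag), e0 = e0, dupRate = dupRate,
       damage = damage, qual = as.integer(qual),
       sampleDivergence = sampleDivergence, seed = seed)
}

#' Preset simulation scenarios
#'
#' `good_specimen`: a library that is damaged but usable — 64% PCR
#' duplication, formalin damage with amplitude 0.02 decaying over ~8 bases,
#' baseline error 0.002. `failed_specimen`: extremely high duplication
#' (97.5%), stronger and longer-range damage, baseline error 0.004 — the
#' low-diversity failure regime. `undamaged`: no duplication, no damage,
#' baseline error 0.002.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [simParams()] (e.g. `nPairs`, `seed`,
#'   `reference`).
#' @return A parameter list (see [simParams()]).
#' @export
simPreset <- function(name = c("good_specimen", "failed_specimen", "undamaged"),
                      ...) {
  name <- match.arg(name)
  base <- switch(name,
    good_specimen = list(dupRate = 0.64, e0 = 0.002,
                         damage = damageModel("formalin", 0.02, 8)),
    failed_specimen = list(dupRate = 0.975, e0 = 0.004,
                           damage = damageModel("formalin", 0.08, 15)),
    undamaged = list(dupRate = 0, e0 = 0.002, damage = damageModel("none"))
  )
  do.call(simParams, utils::modifyList(base, list(...)))
}

## Substitute bytes[at] with a base drawn from `weights` (12 types,
## lexicographic order) conditioned on the current true base. Returns the
## new bytes at those positions; positions whose base has no weight (or is
## N) are returned unchanged.
drawSubstitutions <- function(bytes, at, weights) {
  tt <- mismatchTypes()
  out <- bytes[at]
  cur <- match(rawSplit(bytes[at]), BASES)
  for (b in 1:4) {
    sel <- which(!is.na(cur) & cur == b)
    if (!length(sel)) next
    w <- weights[tt$ref == BASES[b]]
    alts <- tt$alt[tt$ref == BASES[b]]
    if (sum(w) <= 0) next
    pick <- sample.int(3, length(sel), replace = TRUE, prob = w)
    out[sel] <- BASE_RAW[alts[pick]]
  }
  out
}

#' Simulate a formalin-damaged paired-end library with truth
#'
#' Generates unique template fragments (length from the configured
#' mixture, position and strand uniform), reads them from both ends,
#' injects end-anchored damage in read space followed by i.i.d. baseline
#' errors, and emits PCR duplicates as exact copies of previously emitted
#' pairs. Alongside the reads it returns the error-free coordinate ("truth")
#' alignments of every read — all-M CIGARs against the reference — so that
#' downstream profiling, error-rate and consensus code can be exercised and
#' checked against ground truth without an aligner.
#'
#' @param params Parameter list from [simParams()] or [simPreset()].
#' @return An object of (S3) class `SimLibrary`: a list with
#'   \describe{
#'     \item{pairs}{pair table (`id`, `seq1`, `qual1`, `seq2`, `qual2`).}
#'     \item{alignments}{truth alignment table (two rows per pair) in the
#'       format of [readAlignments()].}
#'     \item{truthPairs}{per emitted pair: fragment `rname`, `start`,
#'       `end` (1-based inclusive), `strand`, `frag_len`, `duplicate_of`
#'       (id of the originating pair, NA for originals).}
#'     \item{truthEvents}{per injected event: `pair_id`, `mate`, `offset`
#'       (0-based from the read 5' end), `true_base`, `emitted_base`,
#'       `cause` ("damage" or "error"); one row per read position whose
#'       emitted base differs from the template.}
#'     \item{substitutions}{sample-vs-reference substitution table
#'       (`pos`, `ref`, `alt`) when `sampleDivergence > 0`.}
#'     \item{reference}{the reference set.}
#'     \item{params}{the parameters used.}
#'   }
#' @export
simulateLibrary <- function(params) {
  withSeed(params$seed, simulateLibraryImpl(params))
}

simulateLibraryImpl <- function(params) {
  refset <- params$reference
  if (is.null(refset)) {
    refset <- makeReference(params$refLength, params$gc, seed = NULL,
                            name = params$refName)
  }
  if (length(refset) != 1)
    stop("simulation requires a single reference sequence")
  rname <- names(refset)
  L <- nchar(refset[[1]])

  ## sample individual: substitutions relative to the reference
  tmplBytes <- charToRaw(refset[[1]])
  substitutions <- data.frame(pos = integer(0), ref = character(0),
                              alt = character(0))
  if (params$sampleDivergence > 0) {
    at <- which(stats::runif(L) < params$sampleDivergence &
                  tmplBytes != BASE_RAW[["N"]])
    if (length(at)) {
      old <- tmplBytes[at]
      oi <- match(rawSplit(old), BASES)
      pick <- ALT_IDX[cbind(oi, sample.int(3, length(at), replace = TRUE))]
      tmplBytes[at] <- BASE_RAW[BASES[pick]]
      substitutions <- data.frame(pos = at, ref = rawSplit(old),
                                  alt = BASES[pick])
    }
  }
  template <- rawToChar(tmplBytes)

  ## duplicate structure: an emitted pair duplicates a random earlier pair
  n <- params$nPairs
  dupFlag <- c(FALSE, stats::runif(n - 1) < params$dupRate)
  nU <- sum(!dupFlag)

  ## unique fragments
  comp <- sample.int(length(params$fragMeans), nU, replace = TRUE,
                     prob = params$fragWeights)
  fragLen <- as.integer(pmax(
    round(stats::rlnorm(nU, log(params$fragMeans[comp]), params$fragSdLog)),
    params$minFrag
  ))
  if (max(fragLen) > L)
    stop("reference shorter than the longest sampled fragment (",
         max(fragLen), " > ", L, ")")
  start <- 1L + as.integer(floor(stats::runif(nU) * (L - fragLen + 1)))
  end <- start + fragLen - 1L
  strand <- sample(c("+", "-"), nU, replace = TRUE)

  tpl <- substring(template, start, end)
  sense <- tpl
  minus <- strand == "-"
  sense[minus] <- revComp(tpl[minus])
  m <- pmin(params$readLen, fragLen)
  r1 <- substr(sense, 1L, m)
  r2 <- revComp(substring(sense, fragLen - m + 1L, fragLen))

  ## inject damage then baseline errors on the concatenated unique reads
  reads <- c(r1, r2)
  lens <- c(m, m)
  bytes <- charToRaw(paste(reads, collapse = ""))
  orig <- bytes
  off5 <- sequence(lens) - 1L
  lenPer <- rep.int(lens, lens)
  off3 <- lenPer - 1L - off5
  B <- length(bytes)
  notN <- bytes != BASE_RAW[["N"]]

  dHit <- logical(B)
  dm <- params$damage
  if (dm$mode != "none" && dm$amplitude > 0) {
    h5 <- stats::runif(B) < dm$amplitude * exp(-off5 / dm$lambda) & notN
    h3 <- stats::runif(B) < dm$amplitude * exp(-off3 / dm$lambda) & notN
    both <- h5 & h3
    if (any(both)) {
      to5 <- stats::runif(sum(both)) < 0.5
      h5[both] <- to5
      h3[both] <- !to5
    }
    if (any(h5)) bytes[h5] <- drawSubstitutions(bytes, which(h5), dm$typeWeights$w5)
    if (any(h3)) bytes[h3] <- drawSubstitutions(bytes, which(h3), dm$typeWeights$w3)
    dHit <- h5 | h3
  }
  eHit <- stats::runif(B) < params$e0 & notN
  if (any(eHit)) {
    at <- which(eHit)
    oi <- match(rawSplit(bytes[at]), BASES)
    pick <- ALT_IDX[cbind(oi, sample.int(3, length(at), replace = TRUE))]
    bytes[at] <- BASE_RAW[BASES[pick]]
  }

  ## one truth record per position whose emitted base differs from the
  ## template (a baseline error landing on a damaged base supersedes it;
  ## reverts to the template base leave no record and no mismatch)
  changed <- which(bytes != orig)
  readIdx <- rep.int(seq_along(reads), lens)
  uEvents <- data.frame(
    uidx = ((readIdx[changed] - 1L) %% nU) + 1L,
    mate = ifelse(readIdx[changed] <= nU, "R1", "R2"),
    offset = off5[changed],
    true_base = rawSplit(orig[changed]),
    emitted_base = rawSplit(bytes[changed]),
    cause = ifelse(eHit[changed], "error", "damage")
  )

  all <- rawToChar(bytes)
  ends <- cumsum(lens)
  readsF <- substring(all, ends - lens + 1L, ends)
  r1f <- readsF[seq_len(nU)]
  r2f <- readsF[nU + seq_len(nU)]

  ## emission order; a duplicate copies a uniformly chosen original pair
  ## emitted before it (never a duplicate of a duplicate, so copy numbers
  ## stay near-uniform across fragments)
  uo <- integer(n)           # unique fragment index backing each emitted pair
  rootEmit <- integer(n)     # emitted index of the original pair
  origEmit <- integer(nU)    # emitted index of each original
  nextU <- 0L
  srcDraw <- stats::runif(n)
  for (j in seq_len(n)) {
    if (!dupFlag[j]) {
      nextU <- nextU + 1L
      uo[j] <- nextU
      origEmit[nextU] <- j
      rootEmit[j] <- j
    } else {
      src <- as.integer(ceiling(srcDraw[j] * nextU))
      uo[j] <- src
      rootEmit[j] <- origEmit[src]
    }
  }
  ids <- sprintf("p%06d", seq_len(n))
  qchar <- rawToChar(as.raw(33L + params$qual))
  pairs <- data.frame(
    id = ids,
    seq1 = r1f[uo], qual1 = strrep(qchar, nchar(r1f[uo])),
    seq2 = r2f[uo], qual2 = strrep(qchar, nchar(r2f[uo]))
  )
  truthPairs <- data.frame(
    pair_id = ids,
    rname = rname,
    start = start[uo], end = end[uo],
    strand = strand[uo], frag_len = fragLen[uo],
    duplicate_of = ifelse(dupFlag, ids[rootEmit], NA_character_)
  )
  emap <- split(seq_len(nrow(uEvents)), uEvents$uidx)
  rows <- emap[as.character(uo)]
  reps <- lengths(rows)
  truthEvents <- uEvents[unlist(rows), c("mate", "offset", "true_base",
                                         "emitted_base", "cause"), drop = FALSE]
  truthEvents <- cbind(pair_id = rep.int(ids, reps), truthEvents)
  rownames(truthEvents) <- NULL

  ## truth alignments: all-M CIGARs at the fragment's true coordinates
  eStart <- start[uo]; eEnd <- end[uo]; eM <- m[uo]
  eMinus <- strand[uo] == "-"
  ## R1 reads off the fragment's sequenced strand from its 5' end; R2 off
  ## the opposite strand. Alignment strand and leftmost position follow.
  a1_strand <- ifelse(eMinus, "-", "+")
  a1_pos <- ifelse(eMinus, eEnd - eM + 1L, eStart)
  a2_strand <- ifelse(eMinus, "+", "-")
  a2_pos <- ifelse(eMinus, eStart, eEnd - eM + 1L)
  s1 <- pairs$seq1; s1[eMinus] <- revComp(s1[eMinus])
  s2 <- pairs$seq2; s2[!eMinus] <- revComp(s2[!eMinus])
  flag1 <- 1L + 2L + 64L + 16L * (a1_strand == "-") + 32L * (a2_strand == "-")
  flag2 <- 1L + 2L + 128L + 16L * (a2_strand == "-") + 32L * (a1_strand == "-")
  alignments <- data.frame(
    qname = rep(ids, 2),
    flag = c(flag1, flag2),
    rname = rname,
    pos = c(a1_pos, a2_pos),
    mapq = 60L,
    cigar = paste0(c(eM, eM), "M"),
    strand = c(a1_strand, a2_strand),
    seq = c(s1, s2),
    qual = strrep(qchar, c(eM, eM)),
    md = NA_character_,
    mate = rep(c("R1", "R2"), each = n),
    mapped = TRUE, secondary = FALSE, supplementary = FALSE
  )

  structure(
    list(pairs = pairs, alignments = alignments, truthPairs = truthPairs,
         truthEvents = truthEvents, substitutions = substitutions,
         reference = refset, params = params),
    class = "SimLibrary"
  )
}

#' Write a simulated library to disk
#'
#' Emits `<prefix>_R1.fastq[.gz]`, `<prefix>_R2.fastq[.gz]`,
#' `<prefix>_truth.sam`, `<prefix>_truth_pairs.tsv`,
#' `<prefix>_truth_events.tsv` and `<prefix>_params.json`.
#'
#' @param sim A `SimLibrary` from [simulateLibrary()].
#' @param outPrefix Output path prefix.
#' @param gzip Compress the FASTQ files (default TRUE).
#' @return Character vector of the written paths, invisibly.
#' @export
writeSimLibrary <- function(sim, outPrefix, gzip = TRUE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- paste0(outPrefix, "_R1", ext)
  p2 <- paste0(outPrefix, "_R2", ext)
  writeFastqPair(sim$pairs, p1, p2)
  sam <- paste0(outPrefix, "_truth.sam")
  writeSam(sim$alignments, sim$reference, sam)
  tp <- paste0(outPrefix, "_truth_pairs.tsv")
  utils::write.table(sim$truthPairs, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  te <- paste0(outPrefix, "_truth_events.tsv")
  utils::write.table(sim$truthEvents, te, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pj <- paste0(outPrefix, "_params.json")
  pp <- sim$params
  pp$reference <- if (is.null(pp$reference)) NULL else names(pp$reference)
  jsonlite::write_json(pp, pj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(c(p1, p2, sam, tp, te, pj))
}

#' @export
print.SimLibrary <- function(x, ...) {
  cat("SimLibrary:", nrow(x$pairs), "read pairs on",
      names(x$reference), sprintf("(%d bp)\n", nchar(x$reference[[1]])))
  cat("  duplicates:", sum(!is.na(x$truthPairs$duplicate_of)),
      "| injected events:", nrow(x$truthEvents),
      "| damage mode:", x$params$damage$mode, "\n")
  invisible(x)
}
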