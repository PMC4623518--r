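#' Parameters of the trim-point flatness criterion
#'
#' Formalises "frequencies relatively constant and similar along the read":
#' an offset is considered damaged when its mismatch frequency exceeds a
#' robust baseline estimated from offsets deep inside the read. Both the
#' pooled (all 12 types together) frequency and each per-type frequency are
#' screened; either can flag an offset. The threshold above the baseline
#' median is `max(kMad * 1.4826 * MAD, absFloor)`: scale-free via the MAD
#' term, with an absolute floor so that sampling noise on a tiny baseline
#' cannot flag biologically negligible excursions.
#'
#' @param baselineWindow Integer interval of offsets used for baseline
#'   estimation; NULL (default) means `[maxOffset/2, maxOffset]` of the
#'   profile at hand.
#' @param kMad Robust z threshold (default 3).
#' @param absFloor Absolute frequency floor (default 0.002).
#' @param minDenom Minimum aligned-column denominator for an offset to be
#'   used at all (default 500); guards low-coverage offsets from dominating
#'   via noise.
#' @param maxTrim Scan limit in bases (default 40); caps runaway trimming on
#'   pathological profiles, which should fail loudly rather than silently
#'   trim whole reads.
#' @return A named list of parameters.
#' @export
flatnessParams <- function(baselineWindow = NULL, kMad = 3, absFloor = 0.002,
                           minDenom = 500L, maxTrim = 40L) {
  stopifnot(kMad > 0, absFloor >= 0, minDenom >= 0, maxTrim >= 0)
  list(baselineWindow = baselineWindow, kMad = kMad, absFloor = absFloor,
       minDenom = as.integer(minDenom), maxTrim = as.integer(maxTrim))
}

## Flag damaged offsets for one (mate, end) table and return the trim point.
detectTrimEnd <- function(freq, denom, params, label) {
  k <- ncol(freq)
  offsets <- 0:(k - 1L)
  win <- params$baselineWindow
  if (is.null(win)) win <- c(floor((k - 1L) / 2), k - 1L)
  if (win[1] < 0 || win[2] > k - 1L || win[1] > win[2])
    stop("baseline window outside the profile's offset range")
  inWin <- offsets >= win[1] & offsets <= win[2] & denom >= params$minDenom
  if (!any(inWin))
    stop("insufficient data for baseline estimation at ", label,
         " (all baseline offsets below minDenom)")

  pooled <- colSums(freq)
  thr <- function(x) {
    m <- stats::median(x)
    s <- stats::mad(x, constant = 1)
    m + max(params$kMad * 1.4826 * s, params$absFloor)
  }
  typeThr <- apply(freq[, inWin, drop = FALSE], 1, thr)
  pooledThr <- thr(pooled[inWin])

  scan <- offsets < params$maxTrim & denom >= params$minDenom
  exceed <- sweep(freq, 1, typeThr, ">")
  flagged <- offsets[scan & (pooled > pooledThr | colSums(exceed) > 0)]
  trim <- if (length(flagged)) max(flagged) + 1L else 0L

  list(
    trim = trim,
    flagged = flagged,
    baseline = data.frame(type = rownames(freq),
                          threshold = typeThr, row.names = NULL),
    pooledThreshold = pooledThr
  )
}

#' Detect data-driven hard-trim lengths from mismatch profiles
#'
#' For each of the four (mate, end) combinations independently, estimates a
#' robust per-type and pooled baseline over `baselineWindow` and flags
#' offsets whose frequency exceeds baseline + `max(kMad*1.4826*MAD,
#' absFloor)` (see [flatnessParams()]). The trim length for an end is the
#' smallest i0 such that no offset at or beyond i0 (within the `maxTrim`
#' scan window) is flagged, i.e. one past the largest flagged offset, or 0
#' when nothing is flagged. Contiguity is not required: damage curves may
#' dip under the threshold and re-exceed it closer to the end.
#'
#' @param profileR1,profileR2 [MismatchProfile-class] objects for the two
#'   mates, sharing the same `maxOffset`.
#' @param params Parameters from [flatnessParams()].
#' @return A list with `spec` (a [TrimSpec-class]) and `diagnostics` (per
#'   end: flagged offsets, per-type thresholds, pooled threshold).
#' @export
detectTrim <- function(profileR1, profileR2, params = flatnessParams()) {
  stopifnot(methods::is(profileR1, "MismatchProfile"),
            methods::is(profileR2, "MismatchProfile"))
  if (profileR1@maxOffset != profileR2@maxOffset)
    stop("profiles disagree on maxOffset")
  if (params$maxTrim > profileR1@maxOffset + 1L)
    stop("maxTrim exceeds the profile's offset range")
  ends <- list(
    r1_5p = list(p = profileR1, end = "5", label = "R1 5' end"),
    r1_3p = list(p = profileR1, end = "3", label = "R1 3' end"),
    r2_5p = list(p = profileR2, end = "5", label = "R2 5' end"),
    r2_3p = list(p = profileR2, end = "3", label = "R2 3' end")
  )
  diag <- lapply(ends, function(e)
    detectTrimEnd(profileFreq(e$p, e$end), profileDenom(e$p, e$end),
                  params, e$label))
  trims <- vapply(diag, `[[`, integer(1), "trim")
  list(
    spec = TrimSpec(trims["r1_5p"], trims["r1_3p"],
                    trims["r2_5p"], trims["r2_3p"]),
    diagnostics = diag
  )
}

#' Iterate profile / detect / mask until the profiles are flat
#'
#' Repeats mismatch profiling and trim detection, masking the offsets
#' already marked for trimming instead of re-aligning trimmed reads: the
#' original alignments are kept and columns within the cumulative trim of
#' either read end are excluded, with remaining offsets shifted down.
#' Masking makes iteration deterministic and aligner-free; an externally
#' re-aligned SAM of trimmed reads can simply be fed back through this
#' function when exact re-alignment behaviour is wanted.
#'
#' @inheritParams extractMismatches
#' @param params Parameters from [flatnessParams()].
#' @param maxOffset Profile depth per round (default 50).
#' @param maxRounds Iteration limit (default 5).
#' @return A list with `spec` (cumulative [TrimSpec-class]), `rounds` (one
#'   TrimSpec per round), and `converged` (FALSE when the iteration hit
#'   `maxRounds` or the per-end cap `maxTrim` while offsets were still
#'   flagged).
#' @export
iterateTrim <- function(aln, refset = NULL, params = flatnessParams(),
                        maxOffset = 50L, maxRounds = 5L, minMapq = 20L) {
  ex <- extractMismatches(aln, refset, minMapq)
  cum <- c(r1_5p = 0L, r1_3p = 0L, r2_5p = 0L, r2_3p = 0L)
  rounds <- list()
  converged <- FALSE
  for (round in seq_len(maxRounds)) {
    p1 <- accumulateProfile(ex$observations, ex$columnCounts, "R1", maxOffset,
                            trim5 = cum["r1_5p"], trim3 = cum["r1_3p"])
    p2 <- accumulateProfile(ex$observations, ex$columnCounts, "R2", maxOffset,
                            trim5 = cum["r2_5p"], trim3 = cum["r2_3p"])
    det <- if (round == 1L) detectTrim(p1, p2, params) else tryCatch(
      detectTrim(p1, p2, params),
      error = function(e) {
        if (grepl("insufficient data", conditionMessage(e))) NULL else stop(e)
      }
    )
    if (is.null(det)) break   # masking exhausted the baseline window
    step <- trimVector(det$spec)
    rounds[[round]] <- det$spec
    if (all(step == 0L)) {
      converged <- TRUE
      break
    }
    cum <- pmin(cum + step, params$maxTrim)
  }
  list(spec = TrimSpec(cum["r1_5p"], cum["r1_3p"], cum["r2_5p"], cum["r2_3p"]),
       rounds = rounds, converged = converged)
}
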