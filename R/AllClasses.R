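#' MismatchProfile: misincorporation frequencies by distance from read ends
#'
#' Counts of the 12 ordered reference-to-read substitution types, indexed by
#' 0-based distance from the sequenced read's 5' and 3' ends, together with
#' per-offset denominators (comparable aligned columns). Frequencies are
#' derived lazily as count/denominator via [profileFreq()].
#'
#' Offsets are measured in sequenced-read orientation: reverse-strand
#' alignments are complemented and flipped before accumulation, so an
#' end-of-molecule damage process appears at the same offset regardless of
#' the strand a fragment happened to align to.
#'
#' @slot mate Which mate the profile summarises ("R1" or "R2").
#' @slot maxOffset Largest offset tracked (offsets run 0..maxOffset).
#' @slot counts5,counts3 Integer matrices, 12 types x (maxOffset+1) offsets.
#' @slot denom5,denom3 Integer vectors of comparable aligned columns per offset.
#'
#' @seealso [mismatchProfile()], [accumulateProfile()], [detectTrim()]
#' @export
setClass("MismatchProfile",
  representation(
    mate = "character",
    maxOffset = "integer",
    counts5 = "matrix",
    counts3 = "matrix",
    denom5 = "integer",
    denom3 = "integer"
  )
)

setValidity("MismatchProfile", function(object) {
  k <- object@maxOffset + 1L
  msg <- character(0)
  if (!object@mate %in% c("R1", "R2", "merged"))
    msg <- c(msg, "mate must be one of R1, R2, merged")
  if (object@maxOffset < 0L) msg <- c(msg, "maxOffset must be >= 0")
  for (end in c("5", "3")) {
    cnt <- slot(object, paste0("counts", end))
    den <- slot(object, paste0("denom", end))
    if (!identical(dim(cnt), c(12L, k)))
      msg <- c(msg, sprintf("counts%s must be 12 x %d", end, k))
    if (length(den) != k)
      msg <- c(msg, sprintf("denom%s must have length %d", end, k))
    if (any(cnt < 0) || any(den < 0))
      msg <- c(msg, "counts and denominators must be non-negative")
    if (identical(dim(cnt), c(12L, k)) && length(den) == k &&
        any(colSums(cnt) > den))
      msg <- c(msg, sprintf(
        "total mismatch count exceeds denominator at some offset (%s' end)", end))
  }
  if (length(msg)) msg else TRUE
})

#' TrimSpec: bases to hard-trim from each read end
#'
#' Non-negative base counts to remove from the 5' and 3' ends of the forward
#' (R1) and reverse (R2) mates, as detected by [detectTrim()] or supplied by
#' the user, and applied by [applyTrim()].
#'
#' @slot r1_5p,r1_3p,r2_5p,r2_3p Non-negative integer base counts.
#' @export
setClass("TrimSpec",
  representation(
    r1_5p = "integer", r1_3p = "integer",
    r2_5p = "integer", r2_3p = "integer"
  )
)

setValidity("TrimSpec", function(object) {
  v <- trimVector(object)
  if (any(is.na(v)) || any(v < 0)) "trim lengths must be non-negative integers"
  else TRUE
})

#' Construct a TrimSpec
#'
#' @param r1_5p,r1_3p,r2_5p,r2_3p Bases to remove from each mate/end.
#' @return A [TrimSpec-class] object.
#' @examples
#' TrimSpec(6, 30, 17, 30)
#' @export
TrimSpec <- function(r1_5p = 0, r1_3p = 0, r2_5p = 0, r2_3p = 0) {
  methods::new("TrimSpec",
    r1_5p = as.integer(r1_5p), r1_3p = as.integer(r1_3p),
    r2_5p = as.integer(r2_5p), r2_3p = as.integer(r2_3p)
  )
}

#' @describeIn TrimSpec Trim lengths as a named integer vector.
#' @param spec A TrimSpec.
#' @export
trimVector <- function(spec) {
  c(
    r1_5p = spec@r1_5p, r1_3p = spec@r1_3p,
    r2_5p = spec@r2_5p, r2_3p = spec@r2_3p
  )
}

setMethod("show", "TrimSpec", function(object) {
  v <- trimVector(object)
  cat("TrimSpec: R1 5'=", v["r1_5p"], " 3'=", v["r1_3p"],
      " | R2 5'=", v["r2_5p"], " 3'=", v["r2_3p"], " (bases)\n", sep = "")
})

setMethod("show", "MismatchProfile", function(object) {
  cat("MismatchProfile (", object@mate, "), offsets 0..", object@maxOffset,
      "\n", sep = "")
  cat("  aligned columns: 5' end ", sum(as.numeric(object@denom5)),
      ", 3' end ", sum(as.numeric(object@denom3)), "\n", sep = "")
  cat("  mismatches:      5' end ", sum(object@counts5),
      ", 3' end ", sum(object@counts3), "\n", sep = "")
})

#' Accessors for MismatchProfile tables
#'
#' @param profile A [MismatchProfile-class].
#' @param end Read end, `"5"` or `"3"`.
#' @return `profileCounts`: 12 x (maxOffset+1) integer matrix of mismatch
#'   counts (rows named "ref>alt"). `profileDenom`: integer vector of
#'   comparable aligned columns per offset. `profileFreq`: matrix of
#'   frequencies count/denominator (0 where the denominator is 0).
#' @export
profileCounts <- function(profile, end = c("5", "3")) {
  end <- match.arg(end)
  slot(profile, paste0("counts", end))
}

#' @rdname profileCounts
#' @export
profileDenom <- function(profile, end = c("5", "3")) {
  end <- match.arg(end)
  slot(profile, paste0("denom", end))
}

#' @rdname profileCounts
#' @export
profileFreq <- function(profile, end = c("5", "3")) {
  end <- match.arg(end)
  cnt <- profileCounts(profile, end)
  den <- profileDenom(profile, end)
  f <- sweep(cnt, 2, pmax(den, 1L), "/")
  f[, den == 0L] <- 0
  f
}

#' @rdname profileCounts
#' @export
profileMate <- function(profile) profile@mate

#' @rdname profileCounts
#' @export
profileMaxOffset <- function(profile) profile@maxOffset

## Internal constructor from count tables.
newMismatchProfile <- function(mate, maxOffset, counts5, denom5, counts3, denom3) {
  tn <- typeNames()
  dimnames(counts5) <- dimnames(counts3) <- list(tn, 0:maxOffset)
  methods::new("MismatchProfile",
    mate = mate, maxOffset = as.integer(maxOffset),
    counts5 = counts5, counts3 = counts3,
    denom5 = as.integer(denom5), denom3 = as.integer(denom3)
  )
}

typeNames <- function() {
  tt <- mismatchTypes()
  paste0(tt$ref, ">", tt$alt)
}
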