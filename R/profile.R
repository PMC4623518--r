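#' Accumulate a mismatch profile from extracted observations
#'
#' Bins mismatch observations and aligned-column denominators by 0-based
#' distance from the 5' and 3' read ends, for one mate. Optional trim
#' arguments mask already-trimmed offsets without touching the alignments:
#' columns within `trim5` of the 5' end or `trim3` of the 3' end are
#' excluded and the remaining offsets shifted down, emulating a re-profile
#' of reads hard-trimmed by those amounts (used by [iterateTrim()]).
#'
#' @param obs Observations data.frame from [extractMismatches()].
#' @param columnCounts Column-count data.frame from [extractMismatches()].
#' @param mate Mate to accumulate ("R1" or "R2").
#' @param maxOffset Largest offset tracked (default 50).
#' @param trim5,trim3 Offsets already trimmed from each end (default 0).
#' @return A [MismatchProfile-class].
#' @export
accumulateProfile <- function(obs, columnCounts, mate, maxOffset = 50L,
                              trim5 = 0L, trim3 = 0L) {
  maxOffset <- as.integer(maxOffset)
  k <- maxOffset + 1L
  tt <- mismatchTypes()

  o <- obs[obs$mate == mate, , drop = FALSE]
  keep <- o$offset5 >= trim5 & o$offset3 >= trim3
  o <- o[keep, , drop = FALSE]
  o5 <- o$offset5 - trim5
  o3 <- o$offset3 - trim3
  tidx <- match(paste(o$ref, o$alt), paste(tt$ref, tt$alt))
  if (anyNA(tidx)) stop("invalid mismatch observation (N or unknown base)")

  bin <- function(tix, off) {
    sel <- off <= maxOffset
    m <- matrix(
      tabulate(tix[sel] + 12L * off[sel], nbins = 12L * k),
      nrow = 12L
    )
    storage.mode(m) <- "integer"
    m
  }
  counts5 <- bin(tidx, o5)
  counts3 <- bin(tidx, o3)

  cc <- columnCounts[columnCounts$mate == mate, , drop = FALSE]
  off3cc <- cc$read_len - 1L - cc$offset5
  keep <- cc$offset5 >= trim5 & off3cc >= trim3
  cc <- cc[keep, , drop = FALSE]
  c5 <- cc$offset5 - trim5
  c3 <- off3cc[keep] - trim3
  denomBin <- function(off, n) {
    sel <- off <= maxOffset
    d <- numeric(k)
    if (any(sel)) {
      s <- rowsum(n[sel], off[sel])
      d[as.integer(rownames(s)) + 1L] <- s[, 1]
    }
    as.integer(d)
  }
  denom5 <- denomBin(c5, cc$n)
  denom3 <- denomBin(c3, cc$n)

  newMismatchProfile(mate, maxOffset, counts5, denom5, counts3, denom3)
}

#' Profile mismatches of one mate directly from alignments
#'
#' Convenience wrapper: [extractMismatches()] followed by
#' [accumulateProfile()].
#'
#' @inheritParams extractMismatches
#' @inheritParams accumulateProfile
#' @return A [MismatchProfile-class].
#' @export
mismatchProfile <- function(aln, refset = NULL, mate = "R1", maxOffset = 50L,
                            minMapq = 20L) {
  ex <- extractMismatches(aln, refset, minMapq)
  accumulateProfile(ex$observations, ex$columnCounts, mate, maxOffset)
}

#' Export a mismatch profile as TSV
#'
#' One row per (end, offset, type), ordered 5' end then 3' end, offsets
#' ascending, types lexicographic. Columns: `end` (5p/3p), `offset`, `ref`,
#' `alt`, `count`, `denom`, `freq`. A comment line preserves the mate and
#' maximum offset so [readProfile()] can round-trip the object.
#'
#' @param profile A [MismatchProfile-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportProfile <- function(profile, path) {
  tt <- mismatchTypes()
  k <- profile@maxOffset + 1L
  one <- function(end, lab) {
    cnt <- profileCounts(profile, end)
    den <- profileDenom(profile, end)
    data.frame(
      end = lab,
      offset = rep(0:(k - 1L), each = 12L),
      ref = rep(tt$ref, k),
      alt = rep(tt$alt, k),
      count = as.vector(cnt),
      denom = rep(den, each = 12L),
      freq = ifelse(rep(den, each = 12L) > 0, as.vector(cnt) / rep(den, each = 12L), 0)
    )
  }
  df <- rbind(one("5", "5p"), one("3", "3p"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# mate=%s max_offset=%d", profile@mate,
                     profile@maxOffset), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile TSV written by [exportProfile()]
#'
#' @param path Path to a profile TSV.
#' @return A [MismatchProfile-class] with counts identical to the exported
#'   object.
#' @export
readProfile <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("mate=(\\S+) max_offset=(\\d+)", hdr))[[1]]
  if (length(m) != 3) stop("not a profile TSV (missing metadata line): ", path)
  mate <- m[2]
  maxOffset <- as.integer(m[3])
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  tt <- mismatchTypes()
  k <- maxOffset + 1L
  get <- function(lab) {
    d <- df[df$end == lab, , drop = FALSE]
    d <- d[order(d$offset, match(paste(d$ref, d$alt), paste(tt$ref, tt$alt))), ]
    cnt <- matrix(as.integer(d$count), nrow = 12L)
    den <- as.integer(d$denom[seq(1, nrow(d), by = 12L)])
    list(cnt = cnt, den = den)
  }
  p5 <- get("5p"); p3 <- get("3p")
  newMismatchProfile(mate, maxOffset, p5$cnt, p5$den, p3$cnt, p3$den)
}
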