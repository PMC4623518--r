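#' Extract per-read mismatch observations from alignments
#'
#' Walks every aligned (M/=/X) column of the primary, mapped alignments and
#' compares read to reference base. Columns where either base is N are
#' skipped entirely (they enter neither numerator nor denominator).
#' Observations are reported in sequenced-read orientation: for reverse-
#' strand alignments both bases are complemented and the 5' offset is
#' flipped, so an end-of-molecule damage process lands on the same offset
#' whichever strand the fragment aligned to.
#'
#' @param aln Alignment table from [readAlignments()] (or a simulation's
#'   `alignments` component).
#' @param refset Reference set from [readReference()]; may be NULL if every
#'   record carries an MD tag, from which reference bases are then
#'   reconstructed.
#' @param minMapq MAPQ floor; primary mapped records below it are ignored.
#' @return A list with
#'   \describe{
#'     \item{observations}{data.frame, one row per mismatch: `qname`, `mate`,
#'       `read_len`, `offset5`, `offset3` (0-based distances from the
#'       sequenced read's 5'/3' ends), `ref`, `alt` (read-space bases),
#'       `rname`, `rpos` (1-based reference coordinate).}
#'     \item{aligned}{total number of comparable aligned columns.}
#'     \item{columnCounts}{data.frame `mate`, `read_len`, `offset5`, `n`:
#'       comparable columns per offset, the denominators for profiles.}
#'   }
#' @export
extractMismatches <- function(aln, refset = NULL, minMapq = 20L) {
  aln <- primaryAlignments(aln, minMapq)
  cols <- samColumns(aln, refset)
  comparable <- cols$readb != BASE_RAW[["N"]] & cols$refb != BASE_RAW[["N"]]

  minus <- cols$strand == "-"
  offset5 <- ifelse(minus, cols$read_len - cols$qpos, cols$qpos - 1L)

  cc <- comparable
  colCounts <- countColumns(cols$mate[cc], cols$read_len[cc], offset5[cc])

  mm <- comparable & cols$readb != cols$refb
  refb <- cols$refb[mm]
  altb <- cols$readb[mm]
  flip <- minus[mm]
  refb[flip] <- complementRaw(refb[flip])
  altb[flip] <- complementRaw(altb[flip])
  o5 <- as.integer(offset5[mm])
  rl <- cols$read_len[mm]
  obs <- data.frame(
    qname = aln$qname[cols$aln[mm]],
    mate = cols$mate[mm],
    read_len = rl,
    offset5 = o5,
    offset3 = rl - 1L - o5,
    ref = rawSplit(refb),
    alt = rawSplit(altb),
    rname = cols$rname[mm],
    rpos = cols$rpos[mm]
  )
  list(observations = obs, aligned = sum(cc), columnCounts = colCounts)
}

## raw byte vector -> character vector of single letters
rawSplit <- function(b) {
  if (length(b) == 0) return(character(0))
  strsplit(rawToChar(b), "")[[1]]
}

## Aggregate comparable-column counts by (mate, read_len, offset5).
## offset3 is recoverable as read_len - 1 - offset5, which keeps the
## denominators exact under offset masking (see accumulateProfile).
countColumns <- function(mate, read_len, offset5) {
  if (length(mate) == 0)
    return(data.frame(mate = character(0), read_len = integer(0),
                      offset5 = integer(0), n = integer(0)))
  um <- sort(unique(mate))
  base <- max(read_len) + 1
  key <- (match(mate, um) * base + read_len) * base + offset5
  first <- !duplicated(key)
  idx <- match(key, key[first])
  n <- tabulate(idx, nbins = sum(first))
  out <- data.frame(
    mate = mate[first],
    read_len = read_len[first],
    offset5 = as.integer(offset5[first]),
    n = n
  )
  out[order(out$mate, out$read_len, out$offset5), , drop = FALSE]
}
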