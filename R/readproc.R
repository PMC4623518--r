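#' Apply hard trims to a paired-end library
#'
#' Removes the specified number of bases (and quality values) from each end
#' of each mate. A pair is dropped whenever either trimmed mate is shorter
#' than `minLen`; a trim meeting or exceeding a read's length likewise
#' drops the pair (counted, not an error).
#'
#' @param pairs Pair table (see [readFastqPair()]).
#' @param spec A [TrimSpec-class].
#' @param minLen Minimum post-trim mate length (default 30).
#' @return A list with `pairs` (trimmed pair table) and `report`
#'   (`input`, `kept`, `dropped` pair counts).
#' @export
applyTrim <- function(pairs, spec, minLen = 30L) {
  v <- trimVector(spec)
  n1 <- nchar(pairs$seq1)
  n2 <- nchar(pairs$seq2)
  keep <- (n1 - v["r1_5p"] - v["r1_3p"]) >= minLen &
          (n2 - v["r2_5p"] - v["r2_3p"]) >= minLen
  out <- pairs[keep, , drop = FALSE]
  out$seq1 <- substr(out$seq1, v["r1_5p"] + 1L, nchar(out$seq1) - v["r1_3p"])
  out$qual1 <- substr(out$qual1, v["r1_5p"] + 1L, nchar(out$qual1) - v["r1_3p"])
  out$seq2 <- substr(out$seq2, v["r2_5p"] + 1L, nchar(out$seq2) - v["r2_3p"])
  out$qual2 <- substr(out$qual2, v["r2_5p"] + 1L, nchar(out$qual2) - v["r2_3p"])
  rownames(out) <- NULL
  list(pairs = out,
       report = list(stage = "trim", input = nrow(pairs), kept = nrow(out),
                     dropped = nrow(pairs) - nrow(out)))
}

#' Remove exact duplicate read pairs
#'
#' Pairs are keyed on the concatenated R1 and R2 sequences (qualities and
#' alignment positions are ignored); the first occurrence in file order is
#' kept. Deterministic and usable before alignment.
#'
#' @param pairs Pair table.
#' @return A list with `pairs` (unique pairs, original order) and `report`
#'   (`total_pairs`, `unique_pairs`, `duplicate_fraction`).
#' @export
removeDuplicates <- function(pairs) {
  key <- paste(pairs$seq1, pairs$seq2, sep = "|")
  keep <- !duplicated(key)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  total <- nrow(pairs)
  uniq <- nrow(out)
  list(pairs = out,
       report = list(stage = "dedup", total_pairs = total,
                     unique_pairs = uniq,
                     duplicate_fraction = if (total > 0) 1 - uniq / total else 0))
}

#' Filter pairs on mean base quality and N content
#'
#' A read fails when its mean Phred score is below `minMeanQ` (a mean
#' exactly at the threshold is kept) or its fraction of N bases exceeds
#' `maxNFrac`. Failing either mate drops the whole pair.
#'
#' @param pairs Pair table.
#' @param minMeanQ Minimum mean Phred score (default 20).
#' @param maxNFrac Maximum tolerated N fraction (default 0.1).
#' @return A list with `pairs` and `report` (`input`, `kept`, `dropped`).
#' @export
qualityFilter <- function(pairs, minMeanQ = 20, maxNFrac = 0.1) {
  nFrac <- function(s) {
    n <- nchar(s)
    ifelse(n > 0, nchar(gsub("[^N]", "", s)) / n, 0)
  }
  ok <- meanPhred(pairs$qual1) >= minMeanQ &
        meanPhred(pairs$qual2) >= minMeanQ &
        nFrac(pairs$seq1) <= maxNFrac &
        nFrac(pairs$seq2) <= maxNFrac
  out <- pairs[ok, , drop = FALSE]
  rownames(out) <- NULL
  list(pairs = out,
       report = list(stage = "qfilter", input = nrow(pairs), kept = nrow(out),
                     dropped = nrow(pairs) - nrow(out)))
}

#' Merge overlapping paired-end reads
#'
#' R2 is reverse-complemented and candidate overlaps are scanned from the
#' longest possible down to `minOverlap`; the first candidate whose
#' mismatch fraction is at most `maxMismatchFrac` is accepted. Within the
#' accepted overlap each column takes the higher-quality base (R1 on ties)
#' and the maximum of the two qualities; columns where either base is N do
#' not count as mismatches and resolve by the same quality rule. Pairs with
#' no acceptable overlap are returned unmerged.
#'
#' @param pairs Pair table.
#' @param minOverlap Minimum overlap length in bases (default 11).
#' @param maxMismatchFrac Maximum disagreement fraction within the overlap
#'   (default 0.1).
#' @return A list with `merged` (read table: `id`, `seq`, `qual`, `mate` =
#'   "merged"), `pairs` (unmerged pair table), and `details` (per input
#'   pair: `merged`, `overlap_len`, `mismatches_in_overlap`).
#' @export
mergeOverlaps <- function(pairs, minOverlap = 11L, maxMismatchFrac = 0.1) {
  n <- nrow(pairs)
  rc2 <- revComp(pairs$seq2)
  rq2 <- stringi::stri_reverse(pairs$qual2)
  merged_seq <- character(n)
  merged_qual <- character(n)
  overlap_len <- integer(n)
  mm_in_overlap <- integer(n)
  is_merged <- logical(n)
  rawN <- BASE_RAW[["N"]]
  for (i in seq_len(n)) {
    b1 <- charToRaw(pairs$seq1[i]); q1 <- charToRaw(pairs$qual1[i])
    b2 <- charToRaw(rc2[i]);        q2 <- charToRaw(rq2[i])
    l1 <- length(b1); l2 <- length(b2)
    if (min(l1, l2) < minOverlap) next
    for (o in seq(min(l1, l2), minOverlap, by = -1L)) {
      i1 <- (l1 - o + 1L):l1
      i2 <- 1:o
      x1 <- b1[i1]; x2 <- b2[i2]
      cmp <- x1 != x2 & x1 != rawN & x2 != rawN
      mm <- sum(cmp)
      if (mm <= maxMismatchFrac * o) {
        take2 <- q2[i2] > q1[i1]
        ob <- x1; ob[take2] <- x2[take2]
        oq <- as.raw(pmax(as.integer(q1[i1]), as.integer(q2[i2])))
        merged_seq[i] <- rawToChar(c(b1[seq_len(l1 - o)], ob,
                                     b2[seq.int(o + 1L, length.out = l2 - o)]))
        merged_qual[i] <- rawToChar(c(q1[seq_len(l1 - o)], oq,
                                      q2[seq.int(o + 1L, length.out = l2 - o)]))
        overlap_len[i] <- o
        mm_in_overlap[i] <- mm
        is_merged[i] <- TRUE
        break
      }
    }
  }
  details <- data.frame(id = pairs$id, merged = is_merged,
                        overlap_len = overlap_len,
                        mismatches_in_overlap = mm_in_overlap)
  merged <- data.frame(id = pairs$id[is_merged],
                       seq = merged_seq[is_merged],
                       qual = merged_qual[is_merged],
                       mate = if (any(is_merged)) "merged" else character(0))
  kept <- pairs[!is_merged, , drop = FALSE]
  rownames(kept) <- NULL
  list(merged = merged, pairs = kept, details = details,
       report = list(stage = "merge", input = n, merged = sum(is_merged),
                     unmerged = n - sum(is_merged)))
}
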