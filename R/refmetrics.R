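## Resolve a region argument to (name, start, end), 1-based inclusive.
resolveRegion <- function(region, refset) {
  if (is.character(region) && length(region) == 1) {
    if (!region %in% names(refset)) stop("region not in reference set: ", region)
    list(name = region, start = 1L, end = nchar(refset[[region]]))
  } else if (is.list(region) && all(c("name", "start", "end") %in% names(region))) {
    if (!region$name %in% names(refset))
      stop("region not in reference set: ", region$name)
    region
  } else stop("region must be a reference name or list(name, start, end)")
}

#' Empirical error rate over a reference region
#'
#' The percentage-scale analogue is mismatched aligned bases divided by the
#' total number of comparable aligned bases whose reference position falls
#' in the region, using the same column semantics as
#' [extractMismatches()] (N columns excluded from numerator and
#' denominator; primary mapped alignments with MAPQ at or above the floor).
#'
#' @inheritParams extractMismatches
#' @param region A reference sequence name, or `list(name, start, end)`
#'   (1-based inclusive).
#' @return A list: `region`, `mismatched_bases`, `aligned_bases`, `rate`.
#' @export
errorRate <- function(aln, refset, region, minMapq = 20L) {
  reg <- resolveRegion(region, refset)
  aln <- primaryAlignments(aln, minMapq)
  cols <- samColumns(aln, refset)
  inReg <- cols$rname == reg$name & cols$rpos >= reg$start & cols$rpos <= reg$end
  comparable <- inReg & cols$readb != BASE_RAW[["N"]] & cols$refb != BASE_RAW[["N"]]
  aligned <- sum(comparable)
  if (aligned == 0)
    stop("undefined error rate: no aligned bases in region ", reg$name)
  mism <- sum(comparable & cols$readb != cols$refb)
  list(region = reg, mismatched_bases = mism, aligned_bases = aligned,
       rate = mism / aligned)
}

#' Binned read counts and depth along the reference
#'
#' Each counted alignment is assigned to exactly one bin by its leftmost
#' aligned base, so bin read counts sum to the number of counted
#' alignments. Depth uses the full reference span of each alignment
#' (M/=/X/D consume reference). The genome-wide summary reports breadth
#' (fraction of reference positions covered by at least one read) and mean
#' depth.
#'
#' @inheritParams extractMismatches
#' @param binSize Bin width in bases (default 10000). The last bin of each
#'   reference sequence may be short.
#' @return A list with `bins` (data.frame `ref`, `start`, `end`,
#'   `read_count`, `mean_depth`) and `summary` (`breadth`, `mean_depth`,
#'   `reads`).
#' @export
coverageBins <- function(aln, refset, binSize = 10000L, minMapq = 20L) {
  stopifnot(binSize >= 1)
  aln <- primaryAlignments(aln, minMapq)
  width <- if (nrow(aln)) cigarRefWidth(aln$cigar) else integer(0)
  binList <- list()
  covered <- 0
  depthSum <- 0
  genomeLen <- sum(as.numeric(nchar(refset)))
  for (rn in names(refset)) {
    L <- nchar(refset[[rn]])
    sel <- aln$rname == rn
    starts <- aln$pos[sel]
    ends <- pmin(starts + width[sel] - 1L, L)
    cov <- IRanges::coverage(IRanges::IRanges(starts, ends), width = L)
    bstart <- seq(1L, L, by = binSize)
    bend <- pmin(bstart + binSize - 1L, L)
    v <- IRanges::Views(cov, bstart, bend)
    meanDepth <- IRanges::viewSums(v) / (bend - bstart + 1)
    rc <- tabulate(findInterval(starts, bstart), nbins = length(bstart))
    binList[[rn]] <- data.frame(ref = rn, start = bstart, end = bend,
                                read_count = rc, mean_depth = meanDepth)
    rv <- S4Vectors::runValue(cov)
    rl <- S4Vectors::runLength(cov)
    covered <- covered + sum(as.numeric(rl[rv > 0]))
    depthSum <- depthSum + sum(as.numeric(rl) * as.numeric(rv))
  }
  bins <- do.call(rbind, binList)
  rownames(bins) <- NULL
  list(bins = bins,
       summary = list(breadth = covered / genomeLen,
                      mean_depth = depthSum / genomeLen,
                      reads = nrow(aln)))
}

#' Build a per-position base pileup over a region
#'
#' Per reference position, counts of A, C, G and T from aligned (M/=/X)
#' columns, in reference orientation. N read bases are excluded; deleted
#' reference positions receive no base evidence; insertions are ignored.
#'
#' @inheritParams errorRate
#' @return A list: `region`, `counts` (4 x width integer matrix, rows
#'   A/C/G/T), `depth` (integer vector, `colSums(counts)`).
#' @export
buildPileup <- function(aln, refset, region, minMapq = 20L) {
  reg <- resolveRegion(region, refset)
  width <- reg$end - reg$start + 1L
  aln <- primaryAlignments(aln, minMapq)
  cols <- samColumns(aln, refset)
  keep <- cols$rname == reg$name & cols$rpos >= reg$start &
    cols$rpos <= reg$end & cols$readb != BASE_RAW[["N"]]
  pos <- cols$rpos[keep] - reg$start + 1L
  base <- cols$readb[keep]
  counts <- matrix(0L, nrow = 4, ncol = width,
                   dimnames = list(BASES, NULL))
  for (b in BASES) {
    counts[b, ] <- tabulate(pos[base == BASE_RAW[[b]]], nbins = width)
  }
  list(region = reg, counts = counts, depth = colSums(counts))
}

#' Call a majority consensus from a pileup
#'
#' A site is called as the most frequent base when its depth is at least
#' `minDepth` and the majority base's fraction is at least `majFrac`;
#' otherwise (including exact ties) it is called N, rather than falling
#' back to the reference base, to avoid reference bias in SNP counts. SNPs
#' are called (non-N) sites differing from the reference; dissimilarity is
#' SNPs per called site.
#'
#' @param pileup Pileup from [buildPileup()].
#' @param refset Reference set.
#' @param minDepth Minimum depth to call a site (default 3).
#' @param majFrac Minimum majority fraction (default 0.75).
#' @return A list: `sequence` (consensus over the region, with N at
#'   uncallable sites), `depth`, `snps` (data.frame `pos` (1-based genome
#'   coordinate), `ref`, `alt`, `depth`, `alt_fraction`), `called_sites`,
#'   `dissimilarity`.
#' @export
callConsensus <- function(pileup, refset, minDepth = 3L, majFrac = 0.75) {
  reg <- pileup$region
  counts <- pileup$counts
  depth <- pileup$depth
  width <- ncol(counts)
  top <- max.col(t(counts), ties.method = "first")
  topCount <- counts[cbind(top, seq_len(width))]
  ## exact ties are uncallable: compare against the count profile with the
  ## winner removed
  second <- counts
  second[cbind(top, seq_len(width))] <- -1L
  tie <- topCount == apply(second, 2, max) & depth > 0
  callable <- depth >= minDepth & topCount >= majFrac * depth & !tie
  calls <- rep("N", width)
  calls[callable] <- BASES[top[callable]]
  refSeq <- substr(refset[[reg$name]], reg$start, reg$end)
  refChars <- strsplit(refSeq, "")[[1]]
  isSnp <- callable & calls != refChars & refChars != "N"
  snps <- data.frame(
    pos = which(isSnp) + reg$start - 1L,
    ref = refChars[isSnp],
    alt = calls[isSnp],
    depth = depth[isSnp],
    alt_fraction = topCount[isSnp] / pmax(depth[isSnp], 1L)
  )
  calledSites <- sum(callable)
  list(sequence = paste(calls, collapse = ""),
       depth = depth,
       snps = snps,
       called_sites = calledSites,
       dissimilarity = if (calledSites > 0) nrow(snps) / calledSites else 0)
}

#' GC content of a set of sequences
#'
#' (G+C)/(A+C+G+T); N and other ambiguity codes are excluded from the
#' denominator.
#'
#' @param seqs Character vector of sequences.
#' @return GC fraction in `[0, 1]`.
#' @export
gcContent <- function(seqs) {
  f <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs),
                                     baseOnly = TRUE)
  tot <- sum(f[, c("A", "C", "G", "T")])
  if (tot == 0) stop("undefined GC content: no A/C/G/T bases")
  sum(f[, c("G", "C")]) / tot
}

#' Filter contigs by length and compute the N50
#'
#' Keeps sequences of length at least `minLen`. The N50 is the largest
#' length L such that contigs of length >= L together contain at least half
#' the total filtered length; an empty filtered set yields N50 = 0 with a
#' warning.
#'
#' @param contigs Character vector of contig sequences (possibly named).
#' @param minLen Minimum length kept (default 200).
#' @return A list: `contigs` (filtered), `n50`, `total_length`.
#' @export
lengthFilter <- function(contigs, minLen = 200L) {
  stopifnot(minLen >= 0)
  keep <- nchar(contigs) >= minLen
  out <- contigs[keep]
  if (length(out) == 0) {
    warning("no contigs pass the length filter; N50 undefined, reported as 0")
    return(list(contigs = out, n50 = 0L, total_length = 0L))
  }
  len <- sort(nchar(out), decreasing = TRUE)
  n50 <- len[which(cumsum(as.numeric(len)) >= sum(as.numeric(len)) / 2)[1]]
  list(contigs = out, n50 = n50, total_length = sum(nchar(out)))
}
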