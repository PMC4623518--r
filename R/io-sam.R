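#' Read alignments from a SAM (or BAM) file
#'
#' Plain-text SAM is converted on the fly via Rsamtools; coordinate- and
#' name-sorted input are both accepted. FLAG bits are decoded into logical
#' columns and a mate label; sequences are stored as in the file, i.e. in
#' reference orientation for reverse-strand alignments (the SAM convention).
#'
#' @param path Path to a SAM or BAM file (with header).
#' @param refset Optional reference set from [readReference()]. When given,
#'   every mapped record must name a known reference sequence.
#' @return A data.frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based leftmost), `mapq`, `cigar`, `strand`, `seq`, `qual`, `md`,
#'   `mate`, `mapped`, `secondary`, `supplementary`.
#' @export
readAlignments <- function(path, refset = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (!grepl("\\.bam$", path)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "strand", "seq", "qual"),
    tag = "MD"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  md <- x$tag$MD
  if (is.null(md)) md <- rep(NA_character_, length(x$qname))
  flag <- x$flag
  aln <- data.frame(
    qname = x$qname,
    flag = flag,
    rname = as.character(x$rname),
    pos = x$pos,
    mapq = x$mapq,
    cigar = x$cigar,
    strand = as.character(x$strand),
    seq = as.character(x$seq),
    qual = as.character(x$qual),
    md = md,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, "R1",
                  ifelse(bitwAnd(flag, 128L) > 0L, "R2", "un")),
    mapped = bitwAnd(flag, 4L) == 0L,
    secondary = bitwAnd(flag, 256L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L
  )
  if (!is.null(refset)) {
    unknown <- setdiff(unique(aln$rname[aln$mapped]), names(refset))
    if (length(unknown))
      stop("unknown reference in alignments: ", paste(unknown, collapse = ", "))
  }
  aln
}

#' Write an alignment table to plain-text SAM
#'
#' @param aln Alignment table (see [readAlignments()]).
#' @param refset Named reference set providing the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(aln, refset, path) {
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refset), nchar(refset))
  )
  rec <- character(0)
  if (nrow(aln) > 0) {
    rec <- paste(aln$qname, aln$flag,
                 ifelse(aln$mapped, aln$rname, "*"),
                 ifelse(aln$mapped, aln$pos, 0L),
                 ifelse(aln$mapped, aln$mapq, 0L),
                 ifelse(aln$mapped, aln$cigar, "*"),
                 "*", 0L, 0L, aln$seq, aln$qual,
                 sep = "\t")
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

## Keep only the records that contribute to profiles and error rates:
## primary, mapped, MAPQ at or above the floor. The default floor of 20
## excludes ambiguous placements that inflate apparent mismatch rates.
primaryAlignments <- function(aln, minMapq = 20L) {
  aln[aln$mapped & !aln$secondary & !aln$supplementary &
        !is.na(aln$mapq) & aln$mapq >= minMapq, , drop = FALSE]
}

## Explode CIGAR strings into a long (alignment row, op, length) table.
cigarTable <- function(cigar) {
  tok <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  if (any(nchar(cigar) != vapply(tok, function(t) sum(nchar(t)), numeric(1))))
    stop("malformed CIGAR string")
  flat <- unlist(tok)
  list(
    idx = rep.int(seq_along(cigar), lengths(tok)),
    op = substr(flat, nchar(flat), nchar(flat)),
    len = as.integer(substr(flat, 1, nchar(flat) - 1L))
  )
}

## Reference-consuming width of each CIGAR (M/D/N/=/X).
cigarRefWidth <- function(cigar) {
  ct <- cigarTable(cigar)
  keep <- ct$op %in% c("M", "D", "N", "=", "X")
  w <- numeric(length(cigar))
  s <- rowsum(ct$len[keep], ct$idx[keep])
  w[as.integer(rownames(s))] <- s[, 1]
  as.integer(w)
}

## Within-group inclusive cumulative sum (groups are contiguous in idx).
groupCumsum <- function(v, idx) {
  cs <- cumsum(v)
  f <- !duplicated(idx)
  cs - (cs[f] - v[f])[cumsum(f)]
}

## Reconstruct the reference base for each aligned (M/=/X) column of one
## read from its MD tag. `readb` holds the read bases of those columns in
## file order. Errors out when the MD walk is inconsistent with the CIGAR.
mdRefColumns <- function(md, readb) {
  refb <- readb
  tok <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  p <- 0L
  for (t in tok) {
    if (grepl("^[0-9]+$", t)) {
      p <- p + as.integer(t)
    } else if (startsWith(t, "^")) {
      ## deletion: consumes reference only, no aligned column
    } else {
      p <- p + 1L
      if (p > length(readb)) stop("MD tag inconsistent with CIGAR")
      refb[p] <- charToRaw(t)
    }
  }
  if (p != length(readb)) stop("MD tag inconsistent with CIGAR")
  refb
}

## Core engine: expand every aligned (M/=/X) column of the given alignments
## into flat vectors. Insertions, deletions, clips and skips contribute no
## columns but advance the read/reference cursors per SAM semantics.
##
## Returns a list with one entry per column:
##   aln      index into `aln` rows
##   qpos     1-based position in the stored (reference-orientation) read
##   rpos     1-based reference coordinate
##   readb    read base byte (reference orientation, as stored in SAM)
##   refb     reference base byte
## plus per-column copies of read_len, strand and mate.
samColumns <- function(aln, refset = NULL) {
  n <- nrow(aln)
  empty <- list(aln = integer(0), qpos = integer(0), rpos = integer(0),
                rname = character(0), readb = raw(0), refb = raw(0),
                read_len = integer(0), strand = character(0),
                mate = character(0))
  if (n == 0) return(empty)
  ct <- cigarTable(aln$cigar)
  qcons <- ct$op %in% c("M", "I", "S", "=", "X")
  rcons <- ct$op %in% c("M", "D", "N", "=", "X")
  qlen <- nchar(aln$seq)
  qsum <- rowsum((ct$len * qcons), ct$idx)[, 1]
  if (any(qsum != qlen))
    stop("CIGAR query length disagrees with sequence length")
  qend <- groupCumsum(ct$len * qcons, ct$idx)
  rend <- groupCumsum(ct$len * rcons, ct$idx)
  m <- ct$op %in% c("M", "=", "X")
  if (!any(m)) return(empty)
  mlen <- ct$len[m]
  col_aln <- rep.int(ct$idx[m], mlen)
  within <- sequence(mlen)
  qpos <- rep.int(qend[m] - mlen, mlen) + within
  rpos <- rep.int(aln$pos[ct$idx[m]] + rend[m] - mlen - 1L, mlen) + within

  seqcat <- charToRaw(paste(aln$seq, collapse = ""))
  seqoff <- cumsum(qlen) - qlen
  readb <- seqcat[seqoff[col_aln] + qpos]

  rname <- aln$rname[col_aln]
  if (!is.null(refset)) {
    refcat <- charToRaw(paste(refset, collapse = ""))
    refoff <- cumsum(nchar(refset)) - nchar(refset)
    names(refoff) <- names(refset)
    if (any(!rname %in% names(refset)))
      stop("unknown reference in alignments")
    reflen <- nchar(refset)[rname]
    if (any(rpos < 1L) || any(rpos > reflen))
      stop("alignment extends outside the reference sequence")
    refb <- refcat[refoff[rname] + rpos]
  } else if (!all(is.na(aln$md))) {
    if (any(is.na(aln$md)))
      stop("missing reference: no reference set and some records lack MD tags")
    refb <- raw(length(readb))
    for (i in seq_len(n)) {
      sel <- which(col_aln == i)
      if (length(sel))
        refb[sel] <- mdRefColumns(aln$md[i], readb[sel])
    }
  } else {
    stop("missing reference: supply a reference set or MD tags")
  }

  list(aln = col_aln, qpos = qpos, rpos = rpos, rname = rname,
       readb = readb, refb = refb,
       read_len = qlen[col_aln],
       strand = aln$strand[col_aln],
       mate = aln$mate[col_aln])
}
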