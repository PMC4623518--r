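## Independent brute-force oracles used to cross-check the vectorised
## engine, plus small constructors for hand-built fixtures. Everything here
## deliberately avoids the package's byte-level code paths: plain character
## loops only.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Naive mismatch extraction for all-M alignments: slice the reference,
## compare character by character, flip to read space by hand.
oracleMismatches <- function(aln, refset, minMapq = 20) {
  aln <- aln[aln$mapped & !aln$secondary & !aln$supplementary &
               aln$mapq >= minMapq, , drop = FALSE]
  stopifnot(grepl("^[0-9]+M$", aln$cigar))
  rows <- list()
  aligned <- 0L
  for (i in seq_len(nrow(aln))) {
    len <- nchar(aln$seq[i])
    rd <- strsplit(aln$seq[i], "")[[1]]
    rf <- strsplit(substr(refset[[aln$rname[i]]], aln$pos[i],
                          aln$pos[i] + len - 1L), "")[[1]]
    for (q in seq_len(len)) {
      if (rd[q] == "N" || rf[q] == "N") next
      aligned <- aligned + 1L
      if (rd[q] != rf[q]) {
        if (aln$strand[i] == "-") {
          rows[[length(rows) + 1L]] <- data.frame(
            qname = aln$qname[i], mate = aln$mate[i],
            offset5 = len - q, ref = COMP[[rf[q]]], alt = COMP[[rd[q]]])
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            qname = aln$qname[i], mate = aln$mate[i],
            offset5 = q - 1L, ref = rf[q], alt = rd[q])
        }
      }
    }
  }
  obs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qname = character(0), mate = character(0),
               offset5 = integer(0), ref = character(0), alt = character(0))
  list(observations = obs, aligned = aligned)
}

## Naive depth vector from alignment spans (all-M truth alignments).
oracleDepth <- function(aln, L, minMapq = 20) {
  aln <- aln[aln$mapped & !aln$secondary & !aln$supplementary &
               aln$mapq >= minMapq, , drop = FALSE]
  d <- integer(L)
  for (i in seq_len(nrow(aln))) {
    s <- aln$pos[i]
    e <- min(s + nchar(aln$seq[i]) - 1L, L)
    d[s:e] <- d[s:e] + 1L
  }
  d
}

## Canonical multiset signature of mismatch observations.
obsKey <- function(df) {
  sort(paste(df$qname, df$mate, df$offset5, df$ref, df$alt))
}

## Hand-built alignment table rows in the shape readAlignments() returns.
makeAln <- function(qname, flag, rname, pos, cigar, seq,
                    qual = strrep("I", nchar(seq)), mapq = 60L,
                    md = NA_character_) {
  data.frame(
    qname = qname, flag = flag, rname = rname, pos = pos, mapq = mapq,
    cigar = cigar,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    seq = seq, qual = qual, md = md,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, "R1",
                  ifelse(bitwAnd(flag, 128L) > 0L, "R2", "un")),
    mapped = bitwAnd(flag, 4L) == 0L,
    secondary = bitwAnd(flag, 256L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L
  )
}

## Hand-built mismatch observations / column counts for profile and trim
## tests that need exact frequencies.
makeObs <- function(mate, read_len, offset5, ref, alt, times = 1L) {
  df <- data.frame(qname = "x", mate = mate, read_len = read_len,
                   offset5 = offset5, offset3 = read_len - 1L - offset5,
                   ref = ref, alt = alt, rname = "ref1", rpos = 1L)
  df[rep(seq_len(nrow(df)), each = times), , drop = FALSE]
}

emptyObs <- function() makeObs("R1", 100L, 0L, "A", "C")[0, , drop = FALSE]

colCountsFor <- function(mate, read_len, n) {
  data.frame(mate = mate, read_len = read_len,
             offset5 = 0:(read_len - 1L), n = n)
}

## Uniform baseline observations: every offset of every type at frequency
## count/denom, for constructing exactly flat profiles.
flatObs <- function(mate, read_len, count) {
  tt <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                    stringsAsFactors = FALSE)
  tt <- tt[tt$ref != tt$alt, ]
  do.call(rbind, lapply(seq_len(nrow(tt)), function(k)
    makeObs(mate, read_len, 0:(read_len - 1L), tt$ref[k], tt$alt[k],
            times = count)))
}

## One random read pair table row built from explicit strings.
pairRow <- function(id, seq1, seq2, q1 = strrep("I", nchar(seq1)),
                    q2 = strrep("I", nchar(seq2))) {
  data.frame(id = id, seq1 = seq1, qual1 = q1, seq2 = seq2, qual2 = q2)
}

randomReads <- function(n, seed = 1) {
  set.seed(seed)
  lens <- sample(30:120, n, replace = TRUE)
  data.frame(
    id = sprintf("r%03d", seq_len(n)),
    seq = vapply(lens, function(l)
      paste(sample(c("A", "C", "G", "T", "N"), l, replace = TRUE,
                   prob = c(.24, .24, .24, .24, .04)), collapse = ""),
      character(1)),
    qual = vapply(lens, function(l)
      rawToChar(as.raw(sample(33:73, l, replace = TRUE))), character(1)),
    mate = NA_character_
  )
}
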