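#' Read a FASTQ file
#'
#' Reads Phred+33 FASTQ (gzipped files are auto-detected by the `.gz`
#' suffix) into a data frame of reads. Records are validated: sequence and
#' quality strings must have equal length and sequences may only contain
#' A, C, G, T or N (case-insensitive; sequences are uppercased).
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @param mate Mate label to attach to every record ("R1", "R2", "merged"
#'   or NA). Mates are assigned from the paired file arguments, never
#'   guessed from read headers.
#' @return A data.frame with columns `id`, `seq`, `qual`, `mate`. Quality
#'   strings are kept Phred+33 encoded; use [phredScores()] to decode.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' readFastq(fq)
#' @export
readFastq <- function(path, mate = NA_character_) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), mate = character(0)))
  }
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (", path, "): line count not a multiple of 4")
  hdr <- lines[seq(1, length(lines), by = 4)]
  seq <- toupper(lines[seq(2, length(lines), by = 4)])
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  if (any(substr(hdr, 1, 1) != "@") || any(substr(plus, 1, 1) != "+"))
    stop("malformed FASTQ (", path, "): record structure violated")
  id <- sub("^@", "", vapply(strsplit(hdr, "[ \t]"), `[`, character(1), 1))
  bad <- nchar(seq) != nchar(qual)
  if (any(bad))
    stop("malformed FASTQ record '", id[which(bad)[1]],
         "': sequence and quality lengths differ")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("malformed FASTQ record '", id[which(bad)[1]],
         "': sequence contains symbols outside A/C/G/T/N")
  data.frame(id = id, seq = seq, qual = qual, mate = mate)
}

#' Write reads to FASTQ
#'
#' Round-trip identity with [readFastq()]: reading a written file returns
#' the same records.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("invalid records: sequence and quality lengths differ")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    out <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Read a paired-end FASTQ library
#'
#' Pairs are formed positionally from the two files (R1 record i with R2
#' record i), mirroring how paired FASTQ files are produced by sequencers.
#'
#' @param path1,path2 Paths to the R1 and R2 FASTQ files.
#' @return A pair table: data.frame with columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`. The shared id is taken from the R1 file.
#' @export
readFastqPair <- function(path1, path2) {
  r1 <- readFastq(path1, mate = "R1")
  r2 <- readFastq(path2, mate = "R2")
  if (nrow(r1) != nrow(r2))
    stop("paired FASTQ files differ in record count (",
         nrow(r1), " vs ", nrow(r2), ")")
  data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual)
}

#' Write a pair table to two FASTQ files
#'
#' @param pairs Pair table (see [readFastqPair()]).
#' @param path1,path2 Output paths for the R1 and R2 mates.
#' @return `c(path1, path2)`, invisibly.
#' @export
writeFastqPair <- function(pairs, path1, path2) {
  writeFastq(data.frame(id = pairs$id, seq = pairs$seq1, qual = pairs$qual1),
             path1)
  writeFastq(data.frame(id = pairs$id, seq = pairs$seq2, qual = pairs$qual2),
             path2)
  invisible(c(path1, path2))
}
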