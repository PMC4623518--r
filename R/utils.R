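## Small shared helpers: byte-level base handling, Phred conversion, RNG scoping.

BASES <- c("A", "C", "G", "T")
BASE_RAW <- vapply(c(BASES, "N"), function(b) charToRaw(b), raw(1))

## The 12 ordered substitution types ref->read over {A,C,G,T}, ref != read,
## in lexicographic order (the order used by profile tables and exports).
mismatchTypes <- function() {
  g <- expand.grid(alt = BASES, ref = BASES, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, c("ref", "alt")]
  g <- g[order(g$ref, g$alt), ]
  rownames(g) <- NULL
  g
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences over \{A,C,G,T,N\}.
#' @return Character vector of reverse complements.
#' @export
revComp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Complement of a raw byte vector of base codes (keeps N as N).
complementRaw <- function(b) {
  map <- raw(256)
  map[as.integer(charToRaw("ACGTN")) + 1L] <- charToRaw("TGCAN")
  map[as.integer(b) + 1L]
}

#' Convert between Phred+33 quality strings and integer scores
#'
#' @param qual Character vector of Phred+33 quality strings.
#' @return For `phredScores`, a list of integer vectors; for `phredString`,
#'   a character vector.
#' @export
phredScores <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' @param scores List of integer vectors (or a single integer vector).
#' @rdname phredScores
#' @export
phredString <- function(scores) {
  if (!is.list(scores)) scores <- list(scores)
  vapply(scores, function(s) rawToChar(as.raw(s + 33L)), character(1))
}

## Mean Phred score per read, vectorised over quality strings.
meanPhred <- function(qual) {
  n <- nchar(qual)
  if (length(qual) == 0) return(numeric(0))
  scores <- as.integer(charToRaw(paste(qual, collapse = ""))) - 33L
  cs <- c(0, cumsum(scores))
  ends <- cumsum(n)
  sums <- cs[ends + 1L] - cs[ends - n + 1L]
  sums / n
}

## Run code with a locally seeded RNG, restoring global state afterwards.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Write a stage report as JSON
#'
#' Counts for a processing stage (input, kept, dropped and the dropped
#' fraction), written in a stable structure shared by all cleanup stages.
#'
#' @param report Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
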