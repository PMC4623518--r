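#' Read a reference FASTA file
#'
#' Sequences are uppercased (soft-masking removed) and named by the first
#' whitespace-delimited token of each header. Duplicate names and empty
#' files are errors.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A named character vector of uppercase sequences ("reference
#'   set"); names are unique.
#' @export
readReference <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  nm <- vapply(strsplit(names(ss), "[ \t]"), `[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate sequence name in ", path, ": ",
         nm[duplicated(nm)][1])
  out <- toupper(as.character(ss))
  names(out) <- nm
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
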