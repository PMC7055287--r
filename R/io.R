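# --- small IO helpers -------------------------------------------------------

#' Read a protein FASTA into a named character vector
#' @param path FASTA file (wrapped or single-line).
#' @return named character vector.
#' @export
read_proteins <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a nucleotide FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_nucleotides <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(sequences)
         else Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a data.frame as tab-separated values
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
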