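#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N, uppercase).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.chars_seq <- function(ch) paste(ch, collapse = "")

.substr_seq <- function(s, start, end) substr(s, start, end)

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' uppercase character strings named by record id.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}
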