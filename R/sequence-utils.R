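# Low-level sequence helpers shared by the generator, the annotation stage
# and the target-prediction stage. Sequences are plain uppercase character
# strings internally; Biostrings is used at the FASTA boundary.

STOP_CODONS <- c("TAA", "TAG", "TGA")
RNA_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

dna_complement <- function(x) chartr("ACGTN", "TGCAN", x)

#' Reverse complement of a DNA string
#' @param x character scalar over A,C,G,T,N.
#' @return character scalar.
#' @keywords internal
reverse_complement <- function(x) {
  stopifnot(length(x) == 1L)
  paste(rev(strsplit(dna_complement(x), "", fixed = TRUE)[[1]]), collapse = "")
}

rna_to_dna <- function(x) chartr("Uu", "Tt", x)
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

canonical_seq <- function(x, alphabet, what = "sequence") {
  x <- toupper(x)
  bad <- grepl(sprintf("[^%s]", paste(alphabet, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {%s}", what,
                 paste(alphabet, collapse = ",")), call. = FALSE)
  }
  x
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Split a string into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Read a FASTA file into a name/sequence data frame
#'
#' @param path FASTA file.
#' @return data.frame with columns `name` and `sequence` (uppercase).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  data.frame(name = sub("\\s.*$", "", names(ss)),
             sequence = toupper(as.character(ss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a name/sequence data frame as FASTA (70-column wrap)
#'
#' @param x data.frame with columns `name`, `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::BStringSet(setNames(x$sequence, x$name))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
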