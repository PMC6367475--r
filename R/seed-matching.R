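# Seed derivation and exact seed-complement scanning in 3'UTRs.

#' Derive a miRNA's seed match pattern
#'
#' Under the default `"mirna_seed"` interpretation the seed is miRNA
#' nucleotides 2-8 from the 5' end (1-based, inclusive) and the DNA string
#' searched in UTRs is its reverse complement. The `"literal_revcomp"`
#' variant instead reverse-complements the whole miRNA (as DNA) and takes
#' positions 2-8 of *that* string as the search pattern, which corresponds
#' to the miRNA's 3' end; it is provided for comparison with protocols that
#' phrase seed derivation this way.
#'
#' @param name miRNA name.
#' @param sequence miRNA RNA sequence, 5' to 3', length >= 8.
#' @param interpretation seed interpretation (see Details).
#' @return data.frame with `name`, `seed_rna` (7 nt, 5' to 3') and
#'   `match_dna` (the 7-nt DNA string searched in UTRs).
#' @examples
#' derive_seed("lin-4-like", "UAGCUUAUCAGACUGAUGUUGA")
#' @export
derive_seed <- function(name, sequence,
                        interpretation = c("mirna_seed", "literal_revcomp")) {
  interpretation <- match.arg(interpretation)
  sequence <- canonical_seq(sequence, c("A", "C", "G", "U"), "miRNA")
  if (nchar(sequence) < 8L) {
    stop("input error: miRNA shorter than 8 nt has no seed (positions 2-8)",
         call. = FALSE)
  }
  seed_rna <- substr(sequence, 2L, 8L)
  match_dna <- if (interpretation == "mirna_seed") {
    reverse_complement(rna_to_dna(seed_rna))
  } else {
    substr(reverse_complement(rna_to_dna(sequence)), 2L, 8L)
  }
  data.frame(name = name, seed_rna = seed_rna, match_dna = match_dna,
             stringsAsFactors = FALSE)
}

#' @rdname derive_seed
#' @param mirnas data.frame (`name`, `sequence`).
#' @export
derive_seeds <- function(mirnas, interpretation = c("mirna_seed", "literal_revcomp")) {
  interpretation <- match.arg(interpretation)
  do.call(rbind, lapply(seq_len(nrow(mirnas)), function(i) {
    derive_seed(mirnas$name[i], mirnas$sequence[i], interpretation)
  }))
}

#' Scan 3'UTRs for exact seed complements
#'
#' Reports every exact, possibly overlapping occurrence of each pattern's
#' `match_dna` in each UTR, with both UTR-relative and contig-relative
#' 0-based coordinates.
#'
#' @param utrs UTR table (`contig`, `utr_start`, `sequence`), e.g. from
#'   [annotate_utrs()].
#' @param patterns seed table from [derive_seeds()].
#' @return data.frame (`mirna`, `contig`, `utr_pos`, `contig_pos`), one row
#'   per match.
#' @export
scan_seed_matches <- function(utrs, patterns) {
  if (is.null(patterns) || nrow(patterns) == 0L) {
    stop("input error: no seed patterns supplied", call. = FALSE)
  }
  empty <- data.frame(mirna = character(), contig = character(),
                      utr_pos = integer(), contig_pos = integer())
  if (nrow(utrs) == 0L) return(empty)
  subject <- Biostrings::DNAStringSet(utrs$sequence)
  out <- list()
  for (k in seq_len(nrow(patterns))) {
    hits <- Biostrings::startIndex(
      Biostrings::vmatchPattern(patterns$match_dna[k], subject))
    ns <- lengths(hits)
    if (sum(ns) == 0L) next
    starts <- unlist(hits[ns > 0L], use.names = FALSE)
    idx <- rep(which(ns > 0L), ns[ns > 0L])
    out[[length(out) + 1L]] <- data.frame(
      mirna = patterns$name[k],
      contig = utrs$contig[idx],
      utr_pos = starts - 1L,
      contig_pos = utrs$utr_start[idx] + starts - 1L,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$mirna, res$contig, res$utr_pos), ]
  rownames(res) <- NULL
  res
}
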