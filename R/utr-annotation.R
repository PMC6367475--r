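# ORF discovery and putative 3'UTR extraction from assembled transcriptome
# contigs. Contigs are treated as mRNA-sense, so only forward-strand ORFs
# are scanned; coordinates are 0-based, half-open throughout.

#' Find forward-strand ORFs in a contig
#'
#' Every ATG is walked codon by codon to the first in-frame stop (TAA, TAG,
#' TGA) in each of the three frames. ORFs reaching the end of the sequence
#' without a stop are reported with `complete = FALSE` and `end` at the last
#' full in-frame codon boundary. `min_len_codons` counts coding codons (ATG
#' included, stop excluded). Candidates containing `N` are skipped with a
#' warning.
#'
#' @param sequence DNA string over A,C,G,T,N (case-insensitive).
#' @param min_len_codons minimum ORF length in coding codons.
#' @return data.frame (`start`, `end`, `frame`, `complete`, `n_codons`),
#'   sorted by `start`; 0-based half-open coordinates, stop codon included
#'   in `[start, end)` when complete.
#' @examples
#' find_orfs("ATGTAA", min_len_codons = 1)
#' @export
find_orfs <- function(sequence, min_len_codons = 30L) {
  sequence <- canonical_seq(sequence, c("A", "C", "G", "T", "N"), "contig")
  n <- nchar(sequence)
  empty <- data.frame(start = integer(), end = integer(), frame = integer(),
                      complete = logical(), n_codons = integer())
  if (n < 3L) return(empty)
  out <- list()
  skipped <- 0L
  for (frame in 0:2) {
    if (frame > n - 3L) next
    starts <- seq.int(frame, n - 3L, by = 3L)
    codons <- substring(sequence, starts + 1L, starts + 3L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    has_n <- grepl("N", codons, fixed = TRUE)
    stop_idx <- which(is_stop)
    for (ai in which(is_atg)) {
      nxt <- stop_idx[stop_idx > ai]
      if (length(nxt)) {
        si <- nxt[1]
        span <- ai:si
        complete <- TRUE
        n_codons <- si - ai
        end <- starts[si] + 3L
      } else {
        si <- length(starts)
        span <- ai:si
        complete <- FALSE
        n_codons <- si - ai + 1L
        end <- starts[si] + 3L
      }
      if (any(has_n[span])) {
        skipped <- skipped + 1L
        next
      }
      if (n_codons < min_len_codons) next
      out[[length(out) + 1L]] <- data.frame(
        start = starts[ai], end = end, frame = frame,
        complete = complete, n_codons = n_codons)
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d ORF candidate(s) skipped: N within candidate", skipped),
            call. = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$frame), ]
  rownames(res) <- NULL
  res
}

#' Choose the reference ORF that bounds the 3'UTR
#'
#' The putative 3'UTR is the contig suffix downstream of all confirmed
#' coding sequence, so the reference is the complete ORF with the 3'-most
#' stop (`rule = "threeprime"`, default). Ties are broken by greater length,
#' then smaller start. `rule = "longest"` picks the longest complete ORF
#' instead.
#'
#' @param orfs ORF table from [find_orfs()].
#' @param rule reference selection rule.
#' @return single-row ORF data.frame, or `NULL` if no complete ORF exists.
#' @export
select_reference_orf <- function(orfs, rule = c("threeprime", "longest")) {
  rule <- match.arg(rule)
  if (is.null(orfs) || nrow(orfs) == 0L) return(NULL)
  cand <- orfs[orfs$complete, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  o <- if (rule == "threeprime") {
    order(-cand$end, -(cand$end - cand$start), cand$start)
  } else {
    order(-(cand$end - cand$start), -cand$end, cand$start)
  }
  cand[o[1], , drop = FALSE]
}

#' Extract the putative 3'UTR downstream of a reference ORF
#'
#' @param sequence contig DNA string.
#' @param ref reference ORF row ([select_reference_orf()]).
#' @param min_utr_len minimum UTR length to report (default 7 nt, the seed
#'   length — anything shorter cannot hold a site).
#' @return list (`utr_start`, `sequence`) or `NULL` if the remaining suffix
#'   is shorter than `min_utr_len`.
#' @export
extract_3utr <- function(sequence, ref, min_utr_len = 7L) {
  sequence <- toupper(sequence)
  if (is.null(ref)) return(NULL)
  if (ref$end > nchar(sequence)) {
    stop("integrity error: reference ORF extends past the contig", call. = FALSE)
  }
  utr <- substr(sequence, ref$end + 1L, nchar(sequence))
  if (nchar(utr) < min_utr_len) return(NULL)
  list(utr_start = ref$end, sequence = utr)
}

#' Annotate ORFs and extract 3'UTRs for a whole transcriptome
#'
#' @param contigs data.frame (`name`, `sequence`), e.g. from [read_fasta()].
#' @param min_len_codons minimum ORF length (coding codons).
#' @param min_utr_len minimum UTR length (nt).
#' @param rule reference-ORF rule, see [select_reference_orf()].
#' @return list with `orfs` (contig, start, end, frame, complete, n_codons)
#'   and `utrs` (contig, utr_start, sequence); contigs without a complete
#'   ORF, or whose suffix is too short, contribute no UTR.
#' @export
annotate_utrs <- function(contigs, min_len_codons = 30L, min_utr_len = 7L,
                          rule = c("threeprime", "longest")) {
  rule <- match.arg(rule)
  orf_list <- list(); utr_list <- list()
  for (i in seq_len(nrow(contigs))) {
    orfs <- find_orfs(contigs$sequence[i], min_len_codons)
    if (nrow(orfs)) {
      orf_list[[i]] <- cbind(contig = contigs$name[i], orfs)
    }
    ref <- select_reference_orf(orfs, rule)
    u <- extract_3utr(contigs$sequence[i], ref, min_utr_len)
    if (!is.null(u)) {
      utr_list[[i]] <- data.frame(contig = contigs$name[i],
                                  utr_start = u$utr_start,
                                  sequence = u$sequence,
                                  stringsAsFactors = FALSE)
    }
  }
  orfs <- if (length(Filter(Negate(is.null), orf_list))) {
    do.call(rbind, Filter(Negate(is.null), orf_list))
  } else {
    data.frame(contig = character(), start = integer(), end = integer(),
               frame = integer(), complete = logical(), n_codons = integer())
  }
  utrs <- if (length(Filter(Negate(is.null), utr_list))) {
    do.call(rbind, Filter(Negate(is.null), utr_list))
  } else {
    data.frame(contig = character(), utr_start = integer(),
               sequence = character())
  }
  rownames(orfs) <- rownames(utrs) <- NULL
  list(orfs = orfs, utrs = utrs)
}

#' Write 3'UTRs as FASTA with coordinates in the header
#'
#' Headers encode `contig|utr_start`; [read_utr_fasta()] parses them back.
#'
#' @param utrs UTR table from [annotate_utrs()].
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  write_fasta(data.frame(name = sprintf("%s|%d", utrs$contig, utrs$utr_start),
                         sequence = utrs$sequence), path)
}

#' @rdname write_utr_fasta
#' @export
read_utr_fasta <- function(path) {
  x <- read_fasta(path)
  parts <- strsplit(x$name, "|", fixed = TRUE)
  data.frame(contig = vapply(parts, `[`, "", 1L),
             utr_start = as.integer(vapply(parts, `[`, "", 2L)),
             sequence = x$sequence, stringsAsFactors = FALSE)
}
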