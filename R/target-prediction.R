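# Candidate target construction: seed scan, hybridization confirmation by
# minimum free energy, and biological-process summarisation.

#' Predict miRNA targets in a set of 3'UTRs
#'
#' Derives each miRNA's seed pattern, scans the UTRs for exact seed
#' complements, and confirms each candidate site by the minimum free energy
#' of the miRNA:site hybrid ([duplex_mfe()] with the seed constraint on)
#' over a window of the seed match plus `flank` nt on each side (truncated
#' at the UTR bounds). Sites are retained when `mfe <= mfe_threshold`.
#'
#' @param mirnas data.frame (`name`, `sequence`), RNA 5'->3'.
#' @param utrs UTR table (`contig`, `utr_start`, `sequence`).
#' @param model an [energy_model()].
#' @param mfe_threshold retention threshold, kcal/mol (use `Inf` to keep all
#'   seed matches). The default -20 is a deliberately strict artifact
#'   choice; tune to the question at hand.
#' @param flank nt of UTR context on each side of the seed match.
#' @param interpretation seed interpretation, see [derive_seed()].
#' @return data.frame of class `target_table` (`mirna`, `contig`,
#'   `utr_pos`, `contig_pos`, `site_window`, `mfe`, `n_pairs`); duplex
#'   diagrams for every retained site in `attr(, "diagrams")`.
#' @export
predict_targets <- function(mirnas, utrs, model = default_energy_model(),
                            mfe_threshold = -20, flank = 30L,
                            interpretation = c("mirna_seed", "literal_revcomp")) {
  interpretation <- match.arg(interpretation)
  patterns <- derive_seeds(mirnas, interpretation)
  matches <- scan_seed_matches(utrs, patterns)
  empty <- data.frame(mirna = character(), contig = character(),
                      utr_pos = integer(), contig_pos = integer(),
                      site_window = character(), mfe = numeric(),
                      n_pairs = integer())
  class(empty) <- c("target_table", "data.frame")
  if (nrow(matches) == 0L) {
    attr(empty, "diagrams") <- list()
    return(empty)
  }
  utr_seq <- setNames(utrs$sequence, utrs$contig)
  mir_seq <- setNames(mirnas$sequence, mirnas$name)
  rows <- list(); diagrams <- list()
  for (k in seq_len(nrow(matches))) {
    u <- utr_seq[[matches$contig[k]]]
    p0 <- matches$utr_pos[k]                       # 0-based
    a <- max(0L, p0 - flank)
    b <- min(nchar(u), p0 + 7L + flank)
    window <- substr(u, a + 1L, b)
    dx <- duplex_mfe(mir_seq[[matches$mirna[k]]], dna_to_rna(window),
                     model = model, require_seed = TRUE)
    if (is.na(dx$mfe) || dx$mfe > mfe_threshold) next
    rows[[length(rows) + 1L]] <- data.frame(
      mirna = matches$mirna[k], contig = matches$contig[k],
      utr_pos = p0, contig_pos = matches$contig_pos[k],
      site_window = window, mfe = dx$mfe, n_pairs = nrow(dx$pairs),
      stringsAsFactors = FALSE)
    diagrams[[sprintf("%s:%s:%d", matches$mirna[k], matches$contig[k], p0)]] <-
      dx$diagram
  }
  if (length(rows) == 0L) {
    attr(empty, "diagrams") <- list()
    return(empty)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("target_table", "data.frame")
  attr(out, "diagrams") <- diagrams
  out
}

#' Summarize targets by biological process
#'
#' Counts distinct target contigs per annotated biological process, using a
#' user-supplied contig -> process map (the stand-in for a database lookup).
#' Contigs without an annotation are tallied as `"unannotated"`. Malformed
#' annotation rows (missing contig or process) are skipped and counted in
#' `attr(, "skipped_rows")` with a warning.
#'
#' @param targets target table from [predict_targets()].
#' @param annotation data.frame with columns `contig`, `process`, or a path
#'   to such a TSV.
#' @param group optional named character vector mapping miRNA name -> group
#'   label (e.g. the line in which the miRNA is regulated); counts are then
#'   per (group, process).
#' @return data.frame (`group`, `process`, `n_contigs`).
#' @export
summarize_by_process <- function(targets, annotation = NULL, group = NULL) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- read.delim(annotation, comment.char = "#")
  }
  skipped <- 0L
  amap <- character(0)
  if (!is.null(annotation) && nrow(annotation)) {
    if (!all(c("contig", "process") %in% names(annotation))) {
      stop("input error: annotation needs columns 'contig' and 'process'",
           call. = FALSE)
    }
    bad <- is.na(annotation$contig) | !nzchar(trimws(as.character(annotation$contig))) |
      is.na(annotation$process) | !nzchar(trimws(as.character(annotation$process)))
    skipped <- sum(bad)
    if (skipped > 0L) {
      warning(sprintf("%d malformed annotation row(s) skipped", skipped),
              call. = FALSE)
    }
    annotation <- annotation[!bad, , drop = FALSE]
    amap <- setNames(as.character(annotation$process),
                     as.character(annotation$contig))
  }
  if (nrow(targets) == 0L) {
    out <- data.frame(group = character(), process = character(),
                      n_contigs = integer())
    attr(out, "skipped_rows") <- skipped
    return(out)
  }
  grp <- if (is.null(group)) rep("all", nrow(targets)) else {
    unname(ifelse(targets$mirna %in% names(group), group[targets$mirna], "other"))
  }
  proc <- ifelse(targets$contig %in% names(amap), amap[targets$contig],
                 "unannotated")
  key <- unique(data.frame(group = grp, process = unname(proc),
                           contig = targets$contig, stringsAsFactors = FALSE))
  agg <- stats::aggregate(contig ~ group + process, data = key,
                          FUN = function(v) length(unique(v)))
  names(agg)[3] <- "n_contigs"
  agg <- agg[order(agg$group, -agg$n_contigs, agg$process), ]
  rownames(agg) <- NULL
  attr(agg, "skipped_rows") <- skipped
  agg
}
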