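#' Raw microarray intensity container
#'
#' Holds foreground and (optionally) background probe intensities on the
#' linear fluorescence scale, together with the probe -> miRNA map. Probes
#' are printed in triplicate per miRNA; the `probes` table records which.
#'
#' @param foreground numeric matrix, probes x samples, nonnegative.
#' @param background numeric matrix of the same shape, or `NULL` once
#'   background has been subtracted.
#' @param probes data.frame with columns `probe_id`, `mirna`,
#'   `replicate_probe`, one row per foreground row.
#' @return an object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(foreground, background, probes) {
  if (!is.matrix(foreground) || !is.numeric(foreground)) {
    stop("input error: foreground must be a numeric matrix", call. = FALSE)
  }
  if (!is.null(background) &&
      !identical(dim(background), dim(foreground))) {
    stop("input error: foreground/background shape mismatch", call. = FALSE)
  }
  if (nrow(probes) != nrow(foreground)) {
    stop("input error: probe table does not match intensity rows", call. = FALSE)
  }
  if (anyNA(foreground) || any(foreground < 0) ||
      (!is.null(background) && (anyNA(background) || any(background < 0)))) {
    stop("input error: intensities must be nonnegative and complete", call. = FALSE)
  }
  if (anyNA(probes$mirna) || any(!nzchar(probes$mirna))) {
    stop("input error: every probe must map to a miRNA", call. = FALSE)
  }
  structure(list(foreground = foreground, background = background,
                 probes = probes, samples = colnames(foreground)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d probes (%d miRNAs) x %d samples; background %s\n",
              nrow(x$foreground), length(unique(x$probes$mirna)),
              ncol(x$foreground),
              if (is.null(x$background)) "subtracted" else "present"))
  invisible(x)
}

#' Write / read the intensity table TSV dialect
#'
#' Columns: `probe_id`, `mirna_name`, `replicate_probe`, then one foreground
#' (`<sample>.F`) and one background (`<sample>.B`) column per sample.
#' After background subtraction only `.F` columns are written.
#'
#' @param m an [intensity_matrix()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_intensities <- function(m, path) {
  stopifnot(inherits(m, "intensity_matrix"))
  fg <- m$foreground
  colnames(fg) <- paste0(m$samples, ".F")
  out <- cbind(data.frame(probe_id = m$probes$probe_id,
                          mirna_name = m$probes$mirna,
                          replicate_probe = m$probes$replicate_probe),
               as.data.frame(fg, check.names = FALSE))
  if (!is.null(m$background)) {
    bg <- m$background
    colnames(bg) <- paste0(m$samples, ".B")
    out <- cbind(out, as.data.frame(bg, check.names = FALSE))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  d <- read.delim(path, check.names = FALSE, comment.char = "#")
  fg_cols <- grep("\\.F$", names(d), value = TRUE)
  bg_cols <- grep("\\.B$", names(d), value = TRUE)
  samples <- sub("\\.F$", "", fg_cols)
  fg <- as.matrix(d[, fg_cols, drop = FALSE])
  colnames(fg) <- samples
  rownames(fg) <- d$probe_id
  bg <- NULL
  if (length(bg_cols)) {
    bg <- as.matrix(d[, bg_cols, drop = FALSE])
    colnames(bg) <- sub("\\.B$", "", bg_cols)
    bg <- bg[, samples, drop = FALSE]
    rownames(bg) <- d$probe_id
  }
  intensity_matrix(fg, bg,
                   data.frame(probe_id = d$probe_id, mirna = d$mirna_name,
                              replicate_probe = d$replicate_probe,
                              stringsAsFactors = FALSE))
}

#' Validate and read a design table
#'
#' @param path TSV with columns `sample_id`, `cohort`, `tissue`, `replicate`.
#' @return validated design data.frame.
#' @export
read_design <- function(path) {
  d <- read.delim(path, check.names = FALSE, comment.char = "#")
  validate_design(d)
}

validate_design <- function(d) {
  need <- c("sample_id", "cohort", "tissue", "replicate")
  if (!all(need %in% names(d))) {
    stop("input error: design table must have columns sample_id, cohort, tissue, replicate",
         call. = FALSE)
  }
  if (anyDuplicated(d[, c("cohort", "tissue", "replicate")])) {
    stop("input error: (cohort, tissue, replicate) must be unique", call. = FALSE)
  }
  if (!all(d$cohort %in% COHORTS)) {
    stop(sprintf("input error: unknown cohort label(s): %s",
                 paste(setdiff(unique(d$cohort), COHORTS), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(d$tissue %in% TISSUES)) {
    stop(sprintf("input error: unknown tissue label(s): %s",
                 paste(setdiff(unique(d$tissue), TISSUES), collapse = ", ")),
         call. = FALSE)
  }
  d
}
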