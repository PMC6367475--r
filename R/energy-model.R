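# Nearest-neighbor energy model for intermolecular RNA:RNA hybrids:
# stacked base-pair doublet free energies plus a duplex initiation penalty
# and affine bulge/internal-loop penalties.

#' Construct a hybrid energy model
#'
#' @param stacks data.frame with columns `top`, `bottom`, `dg_kcal_mol`:
#'   `top` is the 5'->3' dinucleotide of one strand, `bottom` the two bases
#'   paired under it read 3'->5', so `top = "GC", bottom = "CG"` is the
#'   doublet 5'-GC-3' / 3'-CG-5'.
#' @param initiation helix initiation penalty (kcal/mol).
#' @param loop_open affine opening penalty for a bulge/internal loop
#'   (kcal/mol).
#' @param loop_extend penalty per unpaired nucleotide in a loop, both
#'   strands counted (kcal/mol).
#' @return object of class `energy_model`.
#' @export
energy_model <- function(stacks, initiation = 4.09, loop_open = 3.0,
                         loop_extend = 0.5) {
  stopifnot(all(c("top", "bottom", "dg_kcal_mol") %in% names(stacks)))
  if (initiation < 0 || loop_open < 0 || loop_extend < 0) {
    stop("configuration error: penalties must be nonnegative", call. = FALSE)
  }
  wc <- c("AU", "UA", "CG", "GC")
  key <- paste(stacks$top, stacks$bottom, sep = "/")
  dg <- setNames(stacks$dg_kcal_mol, key)
  is_wc_doublet <- function(top, bottom) {
    all(paste0(seq_chars(top), seq_chars(bottom)) %in% wc)
  }
  wc_rows <- mapply(is_wc_doublet, stacks$top, stacks$bottom)
  if (any(stacks$dg_kcal_mol[wc_rows] > 0)) {
    stop("configuration error: Watson-Crick stack energies must be <= 0",
         call. = FALSE)
  }
  structure(list(stacks = dg, initiation = initiation,
                 loop_open = loop_open, loop_extend = loop_extend,
                 pairs = RNA_PAIRS, wc_pairs = wc),
            class = "energy_model")
}

#' Read an energy model from a stack-table TSV
#'
#' @param path TSV with columns `top`, `bottom`, `dg_kcal_mol`.
#' @param ... passed to [energy_model()].
#' @return an `energy_model`.
#' @export
read_energy_model <- function(path, ...) {
  energy_model(read.delim(path, comment.char = "#"), ...)
}

#' The packaged default energy model
#'
#' Turner-style RNA/RNA nearest-neighbor stack free energies (37 degrees C,
#' kcal/mol, G:U wobbles included) shipped as an editable TSV in
#' `extdata/stack_energies_turner2004.tsv`, with a duplex initiation penalty
#' of +4.09 kcal/mol and affine loop penalties (open 3.0, extend 0.5 per
#' unpaired nt).
#'
#' @return an `energy_model`.
#' @export
default_energy_model <- function() {
  read_energy_model(system.file("extdata", "stack_energies_turner2004.tsv",
                                package = "gallmir", mustWork = TRUE))
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("energy_model: %d stack doublets; initiation %+.2f; loop open %+.2f, extend %+.2f kcal/mol\n",
              length(x$stacks), x$initiation, x$loop_open, x$loop_extend))
  invisible(x)
}

# stack energy for consecutive pairs (miRNA i-1 with site j+1) then
# (miRNA i with site j); key: top = miRNA dinucleotide 5'->3',
# bottom = site bases read 3'->5' under it
stack_energy <- function(model, m_prev, m_cur, s_prev, s_cur) {
  key <- paste0(m_prev, m_cur, "/", s_prev, s_cur)
  e <- model$stacks[key]
  if (is.na(e)) {
    stop(sprintf("configuration error: energy model missing doublet %s", key),
         call. = FALSE)
  }
  unname(e)
}
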