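# Minimum free energy of an intermolecular miRNA:mRNA hybrid.
#
# A hybrid structure is an antiparallel, order-preserving matching: miRNA
# positions i1 < i2 < ... pair with site positions j1 > j2 > ... (both
# strands 5'->3'; no intramolecular pairs, no pseudoknots). Its energy is
#
#   initiation
#   + stack(doublet)                     for consecutive pairs adjacent on
#                                        both strands
#   + loop_open + loop_extend * u        otherwise, u = total unpaired
#                                        nucleotides bridged on both strands
#
# The minimum over all structures is found by dynamic programming over
# "structure ends with pair (i, j)" states. For each cell the best loop
# predecessor is taken from per-row suffix minima of
# F[i', j'] = E[i', j'] + loop_extend * (j' - i'), which makes the loop cost
# open + extend * (i - j - 2) + F independent of the particular (i', j'),
# so the whole DP is O(M * L * M) for miRNA length M and site length L.

pair_ok <- function(a, b, pairs) paste0(a, b) %in% pairs

#' Hybridization minimum free energy by dynamic programming
#'
#' Computes the minimum free energy over all intermolecular hybrid
#' structures of a miRNA and a target-site window under a nearest-neighbor
#' stacking model with affine bulge/internal-loop penalties (see
#' [energy_model()]), and returns one optimal structure.
#'
#' With `require_seed = TRUE` only structures in which miRNA positions 2-8
#' (1-based from the 5' end) form a contiguous helix of Watson-Crick pairs
#' are admissible — the "complete seed complementarity" rule; G:U wobbles
#' are still allowed outside the seed. If the window admits no such
#' structure the result carries `mfe = NA`.
#'
#' @param mirna miRNA sequence, RNA 5'->3'.
#' @param site target site window, 5'->3'; DNA input is transcribed.
#' @param model an [energy_model()].
#' @param require_seed require full Watson-Crick pairing of miRNA
#'   positions 2-8.
#' @return object of class `duplex_result`: `mirna`, `site`, `mfe`
#'   (kcal/mol), `pairs` (two-column matrix of 1-based miRNA/site positions)
#'   and `diagram` (ASCII duplex sketch).
#' @examples
#' m <- default_energy_model()
#' duplex_mfe("UAGCUUAUCAGACUGAUGUUGA", "UCAACAUCAGUCUGAUAAGCUA", m)
#' @export
duplex_mfe <- function(mirna, site, model = default_energy_model(),
                       require_seed = FALSE) {
  stopifnot(inherits(model, "energy_model"))
  mirna <- canonical_seq(dna_to_rna(mirna), c("A", "C", "G", "U"), "miRNA")
  site <- canonical_seq(dna_to_rna(site), c("A", "C", "G", "U"), "site")
  M <- nchar(mirna); L <- nchar(site)
  if (L < 1L) stop("input error: empty site window", call. = FALSE)
  if (require_seed) {
    if (M < 8L) stop("input error: miRNA shorter than 8 nt has no seed", call. = FALSE)
    if (L < 7L) stop("input error: window shorter than 7 nt cannot pair a full seed",
                     call. = FALSE)
  }
  mc <- seq_chars(mirna); sc <- seq_chars(site)
  init <- model$initiation; open <- model$loop_open; ext <- model$loop_extend

  pairable <- outer(mc, sc, function(a, b) paste0(a, b) %in% model$pairs)
  if (require_seed) {
    wc <- outer(mc, sc, function(a, b) paste0(a, b) %in% model$wc_pairs)
    seed_rows <- 2:8
    pairable[seed_rows, ] <- pairable[seed_rows, , drop = FALSE] &
      wc[seed_rows, , drop = FALSE]
  }

  E <- matrix(Inf, M, L)
  bp_type <- matrix(0L, M, L)  # 0 init, 1 stack, 2 loop
  bp_i <- matrix(0L, M, L); bp_j <- matrix(0L, M, L)
  # per-row suffix minima of F with argmin positions
  sufF <- matrix(Inf, M, L + 1L)
  sufJ <- matrix(0L, M, L + 1L)

  init_allowed <- function(i) !require_seed || i <= 2L
  loop_preds <- function(i) {
    if (!require_seed) return(seq_len(i - 1L))
    if (i == 2L) return(1L)
    if (i >= 9L) return(seq(8L, i - 1L))
    integer(0)
  }
  stack_allowed <- function(i) i > 1L

  for (i in seq_len(M)) {
    for (j in seq_len(L)) {
      if (!pairable[i, j]) next
      best <- if (init_allowed(i)) init else Inf
      bt <- 0L; bi <- 0L; bj <- 0L
      if (stack_allowed(i) && j < L && pairable[i - 1L, j + 1L] &&
          is.finite(E[i - 1L, j + 1L])) {
        e <- E[i - 1L, j + 1L] +
          stack_energy(model, mc[i - 1L], mc[i], sc[j + 1L], sc[j])
        if (e < best) { best <- e; bt <- 1L; bi <- i - 1L; bj <- j + 1L }
      }
      base_loop <- open + ext * (i - j - 2L)
      for (ip in loop_preds(i)) {
        jq <- if (ip == i - 1L) j + 2L else j + 1L  # adjacency is a stack, not a loop
        if (jq > L) next
        f <- sufF[ip, jq]
        if (is.finite(f)) {
          e <- f + base_loop
          if (e < best) { best <- e; bt <- 2L; bi <- ip; bj <- sufJ[ip, jq] }
        }
      }
      if (is.finite(best)) {
        E[i, j] <- best
        bp_type[i, j] <- bt; bp_i[i, j] <- bi; bp_j[i, j] <- bj
      }
    }
    # suffix minima of F over this row
    for (j in seq(L, 1L)) {
      f <- if (is.finite(E[i, j])) E[i, j] + ext * (j - i) else Inf
      if (f < sufF[i, j + 1L]) {
        sufF[i, j] <- f; sufJ[i, j] <- j
      } else {
        sufF[i, j] <- sufF[i, j + 1L]; sufJ[i, j] <- sufJ[i, j + 1L]
      }
    }
  }

  final_rows <- if (require_seed) seq(8L, M) else seq_len(M)
  Ef <- E[final_rows, , drop = FALSE]
  if (!any(is.finite(Ef))) {
    return(structure(list(mirna = mirna, site = site, mfe = NA_real_,
                          pairs = cbind(mirna_pos = integer(0), site_pos = integer(0)),
                          diagram = "", model = model),
                     class = "duplex_result"))
  }
  k <- arrayInd(which.min(Ef), dim(Ef))
  ci <- final_rows[k[1]]; cj <- k[2]
  mfe <- E[ci, cj]
  # traceback
  pr <- list()
  while (ci != 0L) {
    pr[[length(pr) + 1L]] <- c(ci, cj)
    ty <- bp_type[ci, cj]
    if (ty == 0L) break
    ni <- bp_i[ci, cj]; nj <- bp_j[ci, cj]
    ci <- ni; cj <- nj
  }
  pairs <- do.call(rbind, rev(pr))
  colnames(pairs) <- c("mirna_pos", "site_pos")
  structure(list(mirna = mirna, site = site, mfe = mfe, pairs = pairs,
                 diagram = duplex_diagram(mirna, site, pairs),
                 model = model),
            class = "duplex_result")
}

#' Re-sum the energy of a hybrid structure
#'
#' Evaluates the nearest-neighbor energy of an explicit structure (pair
#' list) under a model; `duplex_mfe()$mfe` always equals the re-summed
#' energy of its reported structure.
#'
#' @param pairs two-column matrix of 1-based (miRNA, site) positions, miRNA
#'   positions increasing.
#' @param mirna,site the two sequences (RNA, 5'->3').
#' @param model an [energy_model()].
#' @return energy in kcal/mol.
#' @export
duplex_energy <- function(pairs, mirna, site, model = default_energy_model()) {
  mirna <- dna_to_rna(toupper(mirna)); site <- dna_to_rna(toupper(site))
  mc <- seq_chars(mirna); sc <- seq_chars(site)
  k <- nrow(pairs)
  stopifnot(k >= 1L)
  if (is.unsorted(pairs[, 1], strictly = TRUE) ||
      is.unsorted(rev(pairs[, 2]), strictly = TRUE)) {
    stop("input error: pairs must be antiparallel and order-preserving", call. = FALSE)
  }
  for (t in seq_len(k)) {
    if (!pair_ok(mc[pairs[t, 1]], sc[pairs[t, 2]], model$pairs)) {
      stop("input error: structure contains a non-pairable position", call. = FALSE)
    }
  }
  e <- model$initiation
  if (k > 1L) {
    for (t in seq_len(k - 1L)) {
      i1 <- pairs[t, 1]; j1 <- pairs[t, 2]
      i2 <- pairs[t + 1L, 1]; j2 <- pairs[t + 1L, 2]
      if (i2 == i1 + 1L && j2 == j1 - 1L) {
        e <- e + stack_energy(model, mc[i1], mc[i2], sc[j1], sc[j2])
      } else {
        u <- (i2 - i1 - 1L) + (j1 - j2 - 1L)
        e <- e + model$loop_open + model$loop_extend * u
      }
    }
  }
  unname(e)
}

# ASCII duplex sketch: site 5'->3' on top, miRNA 3'->5' underneath,
# '|' marking paired columns
duplex_diagram <- function(mirna, site, pairs) {
  mc <- seq_chars(mirna); sc <- seq_chars(site)
  M <- length(mc); L <- length(sc)
  ord <- order(pairs[, 2])        # ascending site position = left to right
  top <- character(0); mid <- character(0); bot <- character(0)
  si <- 1L; mi <- M
  for (t in ord) {
    i <- pairs[t, 1]; j <- pairs[t, 2]
    while (si < j) { top <- c(top, sc[si]); mid <- c(mid, " "); bot <- c(bot, "-"); si <- si + 1L }
    while (mi > i) { top <- c(top, "-"); mid <- c(mid, " "); bot <- c(bot, mc[mi]); mi <- mi - 1L }
    top <- c(top, sc[j]); mid <- c(mid, "|"); bot <- c(bot, mc[i])
    si <- j + 1L; mi <- i - 1L
  }
  while (si <= L) { top <- c(top, sc[si]); mid <- c(mid, " "); bot <- c(bot, "-"); si <- si + 1L }
  while (mi >= 1L) { top <- c(top, "-"); mid <- c(mid, " "); bot <- c(bot, mc[mi]); mi <- mi - 1L }
  paste0("site  5' ", paste(top, collapse = ""), " 3'\n",
         "         ", paste(mid, collapse = ""), "\n",
         "miRNA 3' ", paste(bot, collapse = ""), " 5'")
}

#' @export
print.duplex_result <- function(x, ...) {
  if (is.na(x$mfe)) {
    cat("duplex_result: no admissible hybrid structure\n")
  } else {
    cat(sprintf("duplex_result: mfe %.2f kcal/mol, %d pairs\n%s\n",
                x$mfe, nrow(x$pairs), x$diagram))
  }
  invisible(x)
}
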