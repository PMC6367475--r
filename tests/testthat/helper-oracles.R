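# Independent oracles used across the suite. Each re-derives its quantity
# from the definition, without reusing package internals.

# --- Benjamini-Hochberg step-up, straight from the definition -------------
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) {
    adj[o[r]] <- min(1, min(m * p[o[r:m]] / seq(r, m)))
  }
  adj
}

# --- naive overlapping substring search -----------------------------------
naive_search <- function(text, pattern) {
  n <- nchar(text); k <- nchar(pattern)
  if (n < k) return(integer(0))
  which(substring(text, seq_len(n - k + 1L), k:n) == pattern) - 1L
}

# --- brute-force ORF walk: every ATG, codon by codon to the first stop ----
orf_oracle <- function(sequence, min_len_codons) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  p <- 0L
  while (p <= n - 3L) {
    if (substr(sequence, p + 1L, p + 3L) == "ATG") {
      q <- p
      end <- NA_integer_; complete <- FALSE
      while (q <= n - 3L) {
        cod <- substr(sequence, q + 1L, q + 3L)
        if (q > p && cod %in% stops) {
          end <- q + 3L; complete <- TRUE; break
        }
        q <- q + 3L
      }
      if (!complete) end <- p + 3L * ((n - p) %/% 3L)
      n_codons <- if (complete) (end - p) %/% 3L - 1L else (end - p) %/% 3L
      region <- substr(sequence, p + 1L, end)
      if (!grepl("N", region, fixed = TRUE) && n_codons >= min_len_codons) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = p, end = end, frame = p %% 3L,
          complete = complete, n_codons = n_codons)
      }
    }
    p <- p + 1L
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      complete = logical(), n_codons = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$frame), ]
  rownames(out) <- NULL
  out
}

# --- hybrid structure energy, summed independently from the model lists ---
oracle_pair_ok <- function(a, b) paste0(a, b) %in% c("AU","UA","CG","GC","GU","UG")

oracle_energy <- function(chain, mc, sc, model) {
  # chain: matrix of (i, j), i ascending / j descending
  e <- model$initiation
  k <- nrow(chain)
  if (k > 1L) for (t in seq_len(k - 1L)) {
    i1 <- chain[t, 1]; j1 <- chain[t, 2]; i2 <- chain[t + 1L, 1]; j2 <- chain[t + 1L, 2]
    if (i2 == i1 + 1L && j2 == j1 - 1L) {
      e <- e + unname(model$stacks[paste0(mc[i1], mc[i2], "/", sc[j1], sc[j2])])
    } else {
      e <- e + model$loop_open +
        model$loop_extend * ((i2 - i1 - 1L) + (j1 - j2 - 1L))
    }
  }
  e
}

# direct-definition DP: min over all predecessors for every ending pair
duplex_oracle_dp <- function(mirna, site, model) {
  mc <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  sc <- strsplit(chartr("T", "U", toupper(site)), "")[[1]]
  M <- length(mc); L <- length(sc)
  E <- matrix(Inf, M, L)
  for (i in seq_len(M)) for (j in seq_len(L)) {
    if (!oracle_pair_ok(mc[i], sc[j])) next
    best <- model$initiation
    if (i > 1L) for (ip in seq_len(i - 1L)) for (jp in seq(j + 1L, length.out = L - j)) {
      if (!is.finite(E[ip, jp])) next
      step <- if (ip == i - 1L && jp == j + 1L) {
        unname(model$stacks[paste0(mc[ip], mc[i], "/", sc[jp], sc[j])])
      } else {
        model$loop_open + model$loop_extend * ((i - ip - 1L) + (jp - j - 1L))
      }
      best <- min(best, E[ip, jp] + step)
    }
    E[i, j] <- best
  }
  if (all(!is.finite(E))) NA_real_ else min(E)
}

# full exhaustive enumeration of every hybrid structure (small inputs only).
# Chains are carried as preallocated index vectors; energy is accumulated
# incrementally so each structure costs O(1) beyond its parent.
duplex_oracle_enum <- function(mirna, site, model, require_seed = FALSE) {
  mc <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  sc <- strsplit(chartr("T", "U", toupper(site)), "")[[1]]
  M <- length(mc); L <- length(sc)
  wc <- c("AU", "UA", "CG", "GC")
  best <- Inf
  ci <- integer(M); cj <- integer(M)
  admissible <- function(k) {
    if (!require_seed) return(TRUE)
    sel <- which(ci[1:k] >= 2L & ci[1:k] <= 8L)
    if (length(sel) != 7L) return(FALSE)
    if (any(diff(ci[sel]) != 1L) || any(diff(cj[sel]) != -1L)) return(FALSE)
    all(paste0(mc[ci[sel]], sc[cj[sel]]) %in% wc)
  }
  recurse <- function(k, e) {
    # e: energy of the chain of length k (including initiation)
    if (k > 0L && e < best && admissible(k)) best <<- e
    i0 <- if (k) ci[k] else 0L
    j0 <- if (k) cj[k] else L + 1L
    for (i in seq(i0 + 1L, length.out = M - i0)) {
      for (j in seq_len(j0 - 1L)) {
        if (!oracle_pair_ok(mc[i], sc[j])) next
        step <- if (k == 0L) 0 else if (i == i0 + 1L && j == j0 - 1L) {
          unname(model$stacks[paste0(mc[i0], mc[i], "/", sc[j0], sc[j])])
        } else {
          model$loop_open + model$loop_extend * ((i - i0 - 1L) + (j0 - j - 1L))
        }
        ci[k + 1L] <<- i; cj[k + 1L] <<- j
        recurse(k + 1L, e + step)
      }
    }
  }
  recurse(0L, model$initiation)
  if (is.finite(best)) best else NA_real_
}

# --- misc fixture helpers -------------------------------------------------
random_nt <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

empty_planted_de <- function() {
  data.frame(mirna = character(), cohort = character(),
             tissue = character(), log2_fc = numeric())
}

small_sim_config <- function(seed = 7, n_contigs = 12, n_mirnas = 30,
                             n_de_per_comparison = 6, ...) {
  gallmir::sim_config(rng_seed = seed, n_contigs = n_contigs,
                      n_mirnas = n_mirnas,
                      n_de_per_comparison = n_de_per_comparison, ...)
}
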