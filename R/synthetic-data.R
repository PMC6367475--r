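# Synthetic-data generator: transcriptome, miRNA set, design table and
# microarray intensities with planted, machine-readable ground truth.
#
# Determinism contract: every stage seeds its own RNG stream from
# config$rng_seed plus a fixed stage offset (miRNAs +0, transcriptome +1,
# microarray +2) and draws in a documented order, so identical configs give
# byte-identical FASTA/TSV artifacts regardless of which stages are run.

COHORTS <- c("R+", "R-", "S+", "S-")
TISSUES <- c("cuticle", "fat_body")

# uniform integer draw(s) on [lo, hi], safe for degenerate ranges
rint <- function(lo, hi, n = 1L) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

# overlapping occurrence count of a fixed-width pattern in a string
count_occurrences <- function(text, pattern) {
  n <- nchar(text); k <- nchar(pattern)
  if (n < k) return(0L)
  sum(substring(text, seq_len(n - k + 1L), k:n) == pattern)
}

#' Generate a synthetic mature miRNA set
#'
#' Draws `n_mirnas` RNA sequences with lengths from `config$mirna_len`.
#' Seed heptamers (positions 2-8) are unique across the set by construction,
#' so every planted target site identifies exactly one miRNA.
#'
#' Draw order (stream `rng_seed + 0`): lengths, then sequence letters; any
#' seed collision triggers a redraw of the offending sequence.
#'
#' @param config a [sim_config()].
#' @param alphabet residue alphabet; only the RNA alphabet A,C,G,U is valid.
#' @return data.frame with columns `name`, `sequence`.
#' @export
make_mirna_set <- function(config, alphabet = c("A", "C", "G", "U")) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(sort(alphabet), sort(c("A", "C", "G", "U")))) {
    stop("configuration error: miRNA alphabet must be {A,C,G,U}", call. = FALSE)
  }
  set.seed(config$rng_seed)
  n <- config$n_mirnas
  if (n > 4^7 / 4) {
    stop("configuration error: too many miRNAs for unique seed heptamers",
         call. = FALSE)
  }
  lens <- rint(config$mirna_len[1], config$mirna_len[2], n)
  seqs <- character(n)
  seen_seeds <- character(0)
  for (i in seq_len(n)) {
    repeat {
      s <- random_seq(lens[i], alphabet = c("A", "C", "G", "U"))
      seed7 <- substr(s, 2L, 8L)
      if (!(seed7 %in% seen_seeds)) break
    }
    seqs[i] <- s
    seen_seeds <- c(seen_seeds, substr(s, 2L, 8L))
  }
  data.frame(name = sprintf("syn-mir-%04d", seq_len(n)),
             sequence = seqs, stringsAsFactors = FALSE)
}

# miRNAs whose planted site sequence contains no other miRNA's seed
# complement, and its own exactly once; planting only these keeps the
# site truth table exhaustive (no accidental extra matches inside sites).
clean_plantable <- function(mirnas, patterns, site_context) {
  pat_set <- patterns$match_dna
  vapply(seq_len(nrow(mirnas)), function(i) {
    site <- site_sequence(mirnas$sequence[i], site_context, pat_set[i])
    n <- nchar(site)
    win <- substring(site, seq_len(n - 6L), 7:n)
    hits <- win[win %in% pat_set]
    length(hits) == 1L && hits == pat_set[i]
  }, logical(1))
}

site_sequence <- function(mirna_seq, site_context, match_dna) {
  if (site_context == "full") reverse_complement(rna_to_dna(mirna_seq)) else match_dna
}

# offset of the seed 7-mer within the planted site sequence
seed_offset_in_site <- function(mirna_seq, site_context) {
  if (site_context == "full") nchar(mirna_seq) - 8L else 0L
}

# mutate accidental seed-complement occurrences in a 3' tail, leaving the
# planted window [plant_start, plant_end) untouched (0-based, half-open)
scrub_tail <- function(tail, pat_set, plant_start = -1L, plant_end = -1L,
                       allowed_offset = -1L, allowed_pattern = "") {
  chars <- seq_chars(tail)
  n <- length(chars)
  for (iter in seq_len(400L)) {
    txt <- paste(chars, collapse = "")
    if (n < 7L) return(txt)
    win <- substring(txt, seq_len(n - 6L), 7:n)
    hit <- which(win %in% pat_set) - 1L          # 0-based offsets
    hit <- hit[!(hit == allowed_offset & win[hit + 1L] == allowed_pattern)]
    if (length(hit) == 0L) return(txt)
    h <- hit[1]
    pos <- setdiff(seq(h, h + 6L), seq(plant_start, length.out = max(plant_end - plant_start, 0L)))
    if (length(pos) == 0L) return(NA_character_)  # unfixable; caller resamples
    p <- if (length(pos) == 1L) pos else sample(pos, 1L)
    chars[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"), chars[p + 1L]), 1L)
  }
  NA_character_
}

#' Generate a synthetic transcriptome with planted ORFs and target sites
#'
#' Each contig is assembled as 5' pad + ORF (ATG ... stop, no internal
#' in-frame stop) + 3' tail. With probability `config$site_plant_prob` the
#' tail carries a target site for one designated miRNA: either the exact
#' 7-mer seed complement (`site_context = "seed"`) or the reverse complement
#' of the whole miRNA (`"full"`, the default; the seed 7-mer is exact either
#' way). Tails are scrubbed of accidental seed complements for *any* miRNA
#' in the set, and resampled if a complete ORF of `orf_guard_codons` or more
#' would end downstream of the planted stop, so the recorded truth is
#' exhaustive: downstream seed scanning over extracted 3'UTRs recovers the
#' planted sites exactly.
#'
#' Draw order (stream `rng_seed + 1`), per contig: contig length, ORF length,
#' ORF codons, pad length, plant coin, designated miRNA, site offset, pad
#' letters, tail letters, scrub mutations.
#'
#' @param config a [sim_config()].
#' @param mirnas miRNA set from [make_mirna_set()].
#' @return list with `contigs` (data.frame `name`, `sequence`) and `truth`,
#'   a list of two data.frames: `orfs` (contig, start, end, frame; 0-based
#'   half-open) and `sites` (contig, mirna, utr_offset, site_start,
#'   site_end; offsets relative to the 3'UTR, i.e. to the ORF end).
#' @export
make_transcriptome <- function(config, mirnas) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(mirnas) < 1L) stop("miRNA set is empty", call. = FALSE)
  set.seed(config$rng_seed + 1L)
  patterns <- derive_seeds(mirnas)
  plantable <- which(clean_plantable(mirnas, patterns, config$site_context))
  if (config$site_plant_prob > 0 && length(plantable) == 0L) {
    stop("configuration error: no miRNA has a plantable (collision-free) site",
         call. = FALSE)
  }
  pat_set <- patterns$match_dna

  contigs <- vector("list", config$n_contigs)
  orf_truth <- vector("list", config$n_contigs)
  site_truth <- vector("list", config$n_contigs)
  non_stop <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                        c("A","C","G","T")), 1, paste, collapse = ""),
                      STOP_CODONS)
  for (ci in seq_len(config$n_contigs)) {
    id <- sprintf("contig_%04d", ci)
    ok <- FALSE
    for (attempt in seq_len(80L)) {
      L <- rint(config$contig_len[1], config$contig_len[2])
      oc_hi <- min(config$orf_len[2], (L - MIN_TAIL_NT - 3L) %/% 3L)
      oc <- rint(config$orf_len[1], max(config$orf_len[1], oc_hi))
      orf <- paste0("ATG", paste(sample(non_stop, oc - 1L, replace = TRUE),
                                 collapse = ""), sample(STOP_CODONS, 1L))
      orf_nt <- nchar(orf)
      pad_len <- rint(0L, L - orf_nt - MIN_TAIL_NT)
      tail_len <- L - orf_nt - pad_len
      plant <- runif(1) < config$site_plant_prob
      site <- NULL; site_off <- NA_integer_
      if (plant) {
        mi <- plantable[rint(1L, length(plantable))]
        site <- site_sequence(mirnas$sequence[mi], config$site_context, pat_set[mi])
        site_off <- rint(0L, tail_len - nchar(site))
      }
      pad <- random_seq(pad_len)
      tail <- random_seq(tail_len)
      ps <- pe <- -1L
      if (plant) {
        ps <- site_off; pe <- site_off + nchar(site)
        tail <- paste0(substr(tail, 1L, ps), site,
                       substr(tail, pe + 1L, tail_len))
      }
      allowed_off <- if (plant) ps + seed_offset_in_site(mirnas$sequence[mi], config$site_context) else -1L
      allowed_pat <- if (plant) pat_set[mi] else ""
      tail <- scrub_tail(tail, pat_set, ps, pe, allowed_off, allowed_pat)
      if (is.na(tail)) next
      contig <- paste0(pad, orf, tail)
      planted_end <- pad_len + orf_nt
      # guard: no complete ORF ending beyond the planted stop
      orfs <- find_orfs(contig, min_len_codons = config$orf_guard_codons)
      if (any(orfs$complete & orfs$end > planted_end)) next
      contigs[[ci]] <- data.frame(name = id, sequence = contig,
                                  stringsAsFactors = FALSE)
      orf_truth[[ci]] <- data.frame(contig = id, start = pad_len,
                                    end = planted_end, frame = pad_len %% 3L)
      if (plant) {
        site_truth[[ci]] <- data.frame(
          contig = id, mirna = mirnas$name[mi],
          utr_offset = allowed_off,
          site_start = ps, site_end = pe)
      }
      ok <- TRUE
      break
    }
    if (!ok) stop(sprintf("could not assemble a clean contig (%s) in 80 attempts", id),
                  call. = FALSE)
  }
  sites <- if (length(Filter(Negate(is.null), site_truth))) {
    do.call(rbind, Filter(Negate(is.null), site_truth))
  } else {
    data.frame(contig = character(), mirna = character(),
               utr_offset = integer(), site_start = integer(),
               site_end = integer())
  }
  list(contigs = do.call(rbind, contigs),
       truth = list(orfs = do.call(rbind, orf_truth), sites = sites))
}

#' Generate the sample design table
#'
#' Four cohorts (infected/uninfected resistant and susceptible lines:
#' R+, R-, S+, S-) crossed with two tissues (cuticle, fat body) and
#' `config$replicates` replicates.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `sample_id`, `cohort`, `tissue`,
#'   `replicate`.
#' @export
make_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- expand.grid(replicate = seq_len(config$replicates),
                   tissue = TISSUES, cohort = COHORTS,
                   stringsAsFactors = FALSE)
  g <- g[, c("cohort", "tissue", "replicate")]
  g$sample_id <- sprintf("%s_%s_r%d", g$cohort, g$tissue, g$replicate)
  rownames(g) <- NULL
  g[, c("sample_id", "cohort", "tissue", "replicate")]
}

# default planted differential-expression table: for each tissue, each test
# cohort (S+, R+, R-) receives n_de_per_comparison miRNAs with alternating
# up/down effects of magnitude log2_fc, relative to the untouched S- cell
default_planted_de <- function(config, mirnas) {
  out <- list()
  for (ti in TISSUES) {
    for (co in c("S+", "R+", "R-")) {
      n <- min(config$n_de_per_comparison, nrow(mirnas))
      idx <- sample(nrow(mirnas), n)
      sgn <- rep(c(1, -1), length.out = n)
      out[[paste(ti, co)]] <- data.frame(
        mirna = mirnas$name[idx], cohort = co, tissue = ti,
        log2_fc = sgn * config$log2_fc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Generate synthetic microarray intensities with planted effects
#'
#' Probes are printed in triplicate per miRNA. On the log2 scale the
#' foreground signal is per-probe baseline + planted cohort x tissue effect
#' + smooth intensity-dependent bias + Normal(0, `noise_sd`) replicate
#' noise; intensities are emitted on the linear scale with an additive
#' per-probe background channel. The bias is
#' `a_s * bias_amplitude * sin(pi * (baseline - min) / range)` with
#' `a_s = +1` for odd and `-1` for even replicate indices, so it cancels in
#' replicate-paired contrasts but shows as an MA trend against the
#' median pseudo-reference.
#'
#' Draw order (stream `rng_seed + 2`): per-probe baselines, per-probe
#' backgrounds, planted-effect tables (per tissue/cohort cell), noise matrix.
#'
#' @param config a [sim_config()].
#' @param mirnas miRNA set.
#' @param design design table from [make_design()].
#' @param planted_de optional data.frame (`mirna`, `cohort`, `tissue`,
#'   `log2_fc`) of effects to plant; by default one is drawn per
#'   cohort-vs-S- cell (see [sim_config()]).
#' @return list with `intensities` (an [intensity_matrix()]) and `truth_de`,
#'   the planted table augmented with `comparison` and `direction` columns.
#' @export
make_microarray <- function(config, mirnas, design, planted_de = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 2L)
  n_probe <- 3L * nrow(mirnas)
  probes <- data.frame(
    probe_id = sprintf("%s_p%d", rep(mirnas$name, each = 3L), rep(1:3, nrow(mirnas))),
    mirna = rep(mirnas$name, each = 3L),
    replicate_probe = rep(1:3, nrow(mirnas)),
    stringsAsFactors = FALSE)
  baseline <- runif(n_probe, 6, 14)
  background <- pmax(rnorm(n_probe, config$background_mean,
                           0.1 * config$background_mean), 0)
  if (is.null(planted_de)) planted_de <- default_planted_de(config, mirnas)
  if (nrow(planted_de) && !all(planted_de$mirna %in% mirnas$name)) {
    stop("configuration error: planted_de names a miRNA absent from the set",
         call. = FALSE)
  }
  ns <- nrow(design)
  signal <- matrix(baseline, n_probe, ns)
  if (nrow(planted_de)) {
    for (k in seq_len(nrow(planted_de))) {
      pr <- probes$mirna == planted_de$mirna[k]
      sm <- design$cohort == planted_de$cohort[k] &
        design$tissue == planted_de$tissue[k]
      signal[pr, sm] <- signal[pr, sm] + planted_de$log2_fc[k]
    }
  }
  if (config$bias_amplitude > 0) {
    rng <- range(baseline)
    g <- config$bias_amplitude * sin(pi * (baseline - rng[1]) / diff(rng))
    a <- ifelse(design$replicate %% 2L == 1L, 1, -1)
    signal <- signal + outer(g, a)
  }
  signal <- signal + matrix(rnorm(n_probe * ns, 0, config$noise_sd), n_probe, ns)
  fg <- 2^signal + background            # background recycles down columns
  bg <- matrix(background, n_probe, ns)
  dimnames(fg) <- dimnames(bg) <- list(probes$probe_id, design$sample_id)
  truth_de <- planted_de
  if (nrow(truth_de)) {
    truth_de$comparison <- comparison_label(truth_de$cohort, "S-", truth_de$tissue)
    truth_de$direction <- ifelse(truth_de$log2_fc > 0, "up", "down")
  }
  list(intensities = intensity_matrix(fg, bg, probes), truth_de = truth_de)
}

#' Run the full synthetic-data generator
#'
#' @param config a [sim_config()].
#' @return list with `mirnas`, `contigs`, `design`, `intensities` and
#'   `truth` (`orfs`, `sites`, `de`).
#' @examples
#' sim <- simulate_study(sim_config(rng_seed = 3, n_contigs = 5,
#'                                  n_mirnas = 20, n_de_per_comparison = 4))
#' names(sim$truth)
#' @export
simulate_study <- function(config) {
  mirnas <- make_mirna_set(config)
  tx <- make_transcriptome(config, mirnas)
  design <- make_design(config)
  ma <- make_microarray(config, mirnas, design)
  list(mirnas = mirnas, contigs = tx$contigs, design = design,
       intensities = ma$intensities,
       truth = list(orfs = tx$truth$orfs, sites = tx$truth$sites,
                    de = ma$truth_de))
}
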