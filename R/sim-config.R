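#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulated study: a transcriptome of contigs
#' (5' pad + planted ORF + 3' tail), a mature miRNA set, a 4-cohort x
#' 2-tissue x replicate design, and a triplicate-probe microarray with
#' planted cohort-specific fold changes, smooth intensity-dependent bias and
#' replicate noise. The defaults are the study conditions used throughout
#' the package's tests: three replicates per cohort/tissue cell, planted
#' effects of 2 log2 units against replicate noise of 0.25 log2 units, and
#' an intensity-dependent bias of amplitude 0.8 log2 units.
#'
#' @param rng_seed integer seed. Each generator stage seeds its own stream
#'   as `rng_seed + <stage offset>` (miRNAs +0, transcriptome +1,
#'   microarray +2), so a stage is reproducible regardless of call order.
#' @param n_contigs number of transcriptome contigs.
#' @param contig_len length-2 integer range of contig lengths (nt).
#' @param orf_len length-2 integer range of planted ORF lengths, in coding
#'   codons (ATG included, stop excluded).
#' @param n_mirnas number of mature miRNAs.
#' @param mirna_len length-2 integer range of miRNA lengths (nt); mature
#'   insect miRNAs run about 18-24 nt.
#' @param site_plant_prob probability that a contig's 3' tail carries a
#'   target site for one randomly designated miRNA.
#' @param site_context `"full"` plants the reverse complement of the whole
#'   miRNA (a strong canonical site whose seed 7-mer is exact);
#'   `"seed"` plants only the exact 7-mer seed complement.
#' @param n_de_per_comparison miRNAs planted as differential in each
#'   cohort-vs-S- cell (per tissue).
#' @param log2_fc magnitude of each planted effect (log2 units).
#' @param noise_sd replicate noise standard deviation (log2 units),
#'   independent per probe entry.
#' @param bias_amplitude amplitude of the smooth intensity-dependent bias
#'   (log2 units); the bias sign alternates with replicate index, emulating
#'   hybridization-batch effects.
#' @param background_mean mean of the per-probe additive background channel
#'   (linear fluorescence units).
#' @param replicates replicates per cohort x tissue cell (>= 2).
#' @param orf_guard_codons minimum length (codons) at which an accidental
#'   complete ORF downstream of the planted stop would disturb 3'UTR
#'   recovery; tails are resampled until no such ORF exists.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(rng_seed = 7, n_contigs = 10, n_mirnas = 20)
#' cfg$replicates
#' @export
sim_config <- function(rng_seed = 1L,
                       n_contigs = 80L,
                       contig_len = c(500L, 900L),
                       orf_len = c(60L, 120L),
                       n_mirnas = 300L,
                       mirna_len = c(18L, 24L),
                       site_plant_prob = 0.5,
                       site_context = c("full", "seed"),
                       n_de_per_comparison = 40L,
                       log2_fc = 2,
                       noise_sd = 0.25,
                       bias_amplitude = 0.8,
                       background_mean = 100,
                       replicates = 3L) {
  site_context <- match.arg(site_context)
  cfg <- list(
    rng_seed = as.integer(rng_seed),
    n_contigs = as.integer(n_contigs),
    contig_len = as.integer(contig_len),
    orf_len = as.integer(orf_len),
    n_mirnas = as.integer(n_mirnas),
    mirna_len = as.integer(mirna_len),
    site_plant_prob = site_plant_prob,
    site_context = site_context,
    n_de_per_comparison = as.integer(n_de_per_comparison),
    log2_fc = log2_fc,
    noise_sd = noise_sd,
    bias_amplitude = bias_amplitude,
    background_mean = background_mean,
    replicates = as.integer(replicates),
    orf_guard_codons = 30L
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2] || r[1] < 1L) {
      stop(sprintf("configuration error: '%s' must be a nonempty range", nm),
           call. = FALSE)
    }
  }
  counts <- c(n_contigs = cfg$n_contigs, n_mirnas = cfg$n_mirnas,
              replicates = cfg$replicates,
              n_de_per_comparison = cfg$n_de_per_comparison)
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("configuration error: all counts must be positive", call. = FALSE)
  }
  if (cfg$replicates < 2L) {
    stop("configuration error: at least 2 replicates are required", call. = FALSE)
  }
  chk_range(cfg$contig_len, "contig_len")
  chk_range(cfg$orf_len, "orf_len")
  chk_range(cfg$mirna_len, "mirna_len")
  if (cfg$mirna_len[1] < 8L) {
    stop("configuration error: miRNAs must be at least 8 nt (seed 2-8)",
         call. = FALSE)
  }
  if (cfg$site_plant_prob < 0 || cfg$site_plant_prob > 1) {
    stop("configuration error: site_plant_prob must lie in [0,1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0 || cfg$bias_amplitude < 0 || cfg$background_mean < 0) {
    stop("configuration error: noise_sd, bias_amplitude and background_mean must be nonnegative",
         call. = FALSE)
  }
  # every draw of the largest ORF must fit the smallest contig with a tail
  # long enough to host a planted site
  if (3L * cfg$orf_len[2] + 3L + MIN_TAIL_NT > cfg$contig_len[1]) {
    stop("configuration error: orf_len incompatible with contig_len",
         call. = FALSE)
  }
  cfg
}

# minimum 3' tail so that a site (up to 24 nt) plus margin always fits
MIN_TAIL_NT <- 30L

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d contigs (%d-%d nt), %d miRNAs (%d-%d nt), %d replicates",
              x$n_contigs, x$contig_len[1], x$contig_len[2],
              x$n_mirnas, x$mirna_len[1], x$mirna_len[2], x$replicates),
      sprintf("planted |log2FC| %.2g, noise sd %.2g, bias amplitude %.2g",
              x$log2_fc, x$noise_sd, x$bias_amplitude), sep = "\n  ")
  invisible(x)
}
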