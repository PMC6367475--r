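# Pipeline orchestration: stages run in dependency order against a single
# structured config; every tabular artifact carries a '#'-prefixed metadata
# header (package version, config hash, rng seed) and reruns are
# byte-identical.

#' Default pipeline configuration
#'
#' @param rng_seed seed for every stochastic stage.
#' @param sim named list of [sim_config()] overrides.
#' @param span normalization lowess span.
#' @param alpha_mirna significance level for miRNA differential expression.
#' @param alpha_other significance level for other tests.
#' @param seed_interpretation see [derive_seed()].
#' @param mfe_threshold target retention threshold (kcal/mol).
#' @param flank UTR context around seed matches (nt).
#' @param min_len_codons minimum ORF length (coding codons).
#' @param min_utr_len minimum 3'UTR length (nt).
#' @param energy_model_path stack-table TSV; `NULL` uses the packaged table.
#' @param annotation_path optional contig -> process TSV for the report.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(rng_seed = 1L, sim = list(), span = 0.3,
                            alpha_mirna = 0.01, alpha_other = 0.05,
                            seed_interpretation = "mirna_seed",
                            mfe_threshold = -20, flank = 30L,
                            min_len_codons = 30L, min_utr_len = 7L,
                            energy_model_path = NULL,
                            annotation_path = NULL) {
  for (a in c(alpha_mirna, alpha_other)) {
    if (a <= 0 || a >= 1) stop("input error: thresholds must lie in (0,1)", call. = FALSE)
  }
  cfg <- list(rng_seed = as.integer(rng_seed), sim = sim, span = span,
              alpha_mirna = alpha_mirna, alpha_other = alpha_other,
              seed_interpretation = seed_interpretation,
              mfe_threshold = mfe_threshold, flank = as.integer(flank),
              min_len_codons = as.integer(min_len_codons),
              min_utr_len = as.integer(min_utr_len),
              energy_model_path = energy_model_path,
              annotation_path = annotation_path)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys take the
#' defaults, unknown keys are an error.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop(sprintf("input error: unknown config key(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

# polynomial rolling hash of the deparsed config, for artifact headers
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg[order(names(unclass(cfg)))]), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

artifact_header <- function(cfg) {
  c(sprintf("# gallmir %s", as.character(packageVersion("gallmir"))),
    sprintf("# config_hash %s", config_hash(cfg)),
    sprintf("# rng_seed %d", cfg$rng_seed))
}

write_tsv_artifact <- function(x, path, cfg) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(artifact_header(cfg), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

artifact_paths <- function(out_dir) {
  file.path(out_dir, c(
    mirnas = "mirnas.fasta", contigs = "contigs.fasta",
    design = "design.tsv", intensities = "intensities.tsv",
    truth_orfs = "truth_orfs.tsv", truth_sites = "truth_sites.tsv",
    truth_de = "truth_de.tsv",
    normalized = "normalized.tsv",
    comparison_counts = "comparison_counts.tsv",
    de_dir = "de", venn = "venn_cells.tsv",
    orfs = "orfs.tsv", utrs = "utrs.fasta",
    targets = "targets.tsv", duplexes = "duplex_diagrams.txt",
    report = "report.txt")) |>
    setNames(c("mirnas", "contigs", "design", "intensities", "truth_orfs",
               "truth_sites", "truth_de", "normalized", "comparison_counts",
               "de_dir", "venn", "orfs", "utrs", "targets", "duplexes",
               "report"))
}

need_artifact <- function(path, producing_stage) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s': run stage '%s' first",
                 basename(path), producing_stage), call. = FALSE)
  }
  path
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (synthetic inputs + truth tables), `normalize`
#' (background subtraction + MA lowess), `de` (all pairwise comparisons),
#' `sets` (Venn partitions per tissue/direction), `annotate-utr` (ORFs +
#' 3'UTRs), `targets` (seed scan + hybridization MFE), `report`, or `all`.
#' Stages read their inputs from `out_dir`, so externally produced files in
#' the same TSV/FASTA dialects can replace the simulated ones.
#'
#' @param stage stage name (see Details).
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_dir artifact directory (created if needed).
#' @param verbose log per-stage row counts to stderr.
#' @return named list of artifact paths written, invisibly.
#' @export
run_pipeline <- function(stage = "all", config = pipeline_config(),
                         out_dir = "gallmir_out", verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "normalize", "de", "sets", "annotate-utr",
              "targets", "report")
  stage <- match.arg(stage, c("all", stages))
  todo <- if (stage == "all") stages else stage
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- artifact_paths(out_dir)
  written <- character(0)

  sim_cfg <- do.call(sim_config, c(list(rng_seed = config$rng_seed), config$sim))

  if ("simulate" %in% todo) {
    sim <- simulate_study(sim_cfg)
    write_fasta(sim$mirnas, p["mirnas"])
    write_fasta(sim$contigs, p["contigs"])
    write_tsv_artifact(sim$design, p["design"], config)
    write_intensities(sim$intensities, p["intensities"])
    write_tsv_artifact(sim$truth$orfs, p["truth_orfs"], config)
    write_tsv_artifact(sim$truth$sites, p["truth_sites"], config)
    write_tsv_artifact(sim$truth$de, p["truth_de"], config)
    pipeline_log(verbose, "simulate: %d contigs, %d miRNAs, %d samples",
                 nrow(sim$contigs), nrow(sim$mirnas), nrow(sim$design))
    written <- c(written, p[c("mirnas", "contigs", "design", "intensities",
                              "truth_orfs", "truth_sites", "truth_de")])
  }

  if ("normalize" %in% todo) {
    m <- read_intensities(need_artifact(p["intensities"], "simulate"))
    norm <- lowess_normalize(subtract_background(m), span = config$span)
    out <- cbind(data.frame(probe_id = m$probes$probe_id,
                            mirna_name = m$probes$mirna,
                            replicate_probe = m$probes$replicate_probe),
                 as.data.frame(norm, check.names = FALSE))
    write_tsv_artifact(out, p["normalized"], config)
    pipeline_log(verbose, "normalize: %d probes x %d samples", nrow(norm), ncol(norm))
    written <- c(written, p["normalized"])
  }

  read_normalized <- function() {
    d <- read.delim(need_artifact(p["normalized"], "normalize"),
                    check.names = FALSE, comment.char = "#")
    x <- as.matrix(d[, -(1:3), drop = FALSE])
    rownames(x) <- d$probe_id
    attr(x, "probes") <- data.frame(probe_id = d$probe_id,
                                    mirna = d$mirna_name,
                                    replicate_probe = d$replicate_probe,
                                    stringsAsFactors = FALSE)
    x
  }

  if ("de" %in% todo) {
    x <- read_normalized()
    design <- read_design(need_artifact(p["design"], "simulate"))
    cmp <- run_all_comparisons(x, design, alpha = config$alpha_mirna)
    write_tsv_artifact(cmp$counts, p["comparison_counts"], config)
    dir.create(p["de_dir"], showWarnings = FALSE)
    for (lbl in names(cmp$results)) {
      fn <- file.path(p["de_dir"], paste0(gsub("[^A-Za-z0-9+-]+", "_", lbl), ".tsv"))
      write_tsv_artifact(cmp$results[[lbl]], fn, config)
      written <- c(written, fn)
    }
    pipeline_log(verbose, "de: %d comparisons, %d total DE calls",
                 nrow(cmp$counts), sum(cmp$counts$n_de, na.rm = TRUE))
    written <- c(written, p["comparison_counts"])
  }

  if ("sets" %in% todo) {
    x <- read_normalized()
    design <- read_design(need_artifact(p["design"], "simulate"))
    cells <- list()
    for (ti in TISSUES) {
      vp <- de_venn(x, design, ti, alpha = config$alpha_mirna)
      for (dir in c("up", "down")) {
        v <- vp[[dir]]
        cells[[paste(ti, dir)]] <- cbind(tissue = ti, direction = dir, v)
      }
    }
    venn <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
    write_tsv_artifact(venn, p["venn"], config)
    pipeline_log(verbose, "sets: %d Venn cells, %d memberships",
                 nrow(venn), sum(venn$size))
    written <- c(written, p["venn"])
  }

  if ("annotate-utr" %in% todo) {
    contigs <- read_fasta(need_artifact(p["contigs"], "simulate"))
    ann <- annotate_utrs(contigs, config$min_len_codons, config$min_utr_len)
    write_tsv_artifact(ann$orfs, p["orfs"], config)
    write_utr_fasta(ann$utrs, p["utrs"])
    pipeline_log(verbose, "annotate-utr: %d ORFs, %d UTRs",
                 nrow(ann$orfs), nrow(ann$utrs))
    written <- c(written, p[c("orfs", "utrs")])
  }

  if ("targets" %in% todo) {
    mirnas <- read_fasta(need_artifact(p["mirnas"], "simulate"))
    utrs <- read_utr_fasta(need_artifact(p["utrs"], "annotate-utr"))
    model <- if (is.null(config$energy_model_path)) default_energy_model() else
      read_energy_model(config$energy_model_path)
    tg <- predict_targets(mirnas, utrs, model,
                          mfe_threshold = config$mfe_threshold,
                          flank = config$flank,
                          interpretation = config$seed_interpretation)
    write_tsv_artifact(tg, p["targets"], config)
    dia <- attr(tg, "diagrams")
    con <- file(p["duplexes"], "wt")
    writeLines(artifact_header(config), con)
    for (nm in names(dia)) writeLines(c(paste0(">", nm), dia[[nm]], ""), con)
    close(con)
    pipeline_log(verbose, "targets: %d retained sites for %d miRNAs",
                 nrow(tg), length(unique(tg$mirna)))
    written <- c(written, p[c("targets", "duplexes")])
  }

  if ("report" %in% todo) {
    written <- c(written, pipeline_report(out_dir, config))
  }
  invisible(written)
}

#' Assemble the human-readable pipeline report
#'
#' Emits the per-comparison DE counts, the Venn cell sizes per tissue and
#' direction, and targets-per-miRNA counts into one text file. Regeneration
#' is idempotent.
#'
#' @param out_dir artifact directory of a previous [run_pipeline()] run.
#' @param config the `pipeline_config` used (for the artifact header).
#' @return path of the report, invisibly.
#' @export
pipeline_report <- function(out_dir, config = pipeline_config()) {
  p <- artifact_paths(out_dir)
  counts <- read.delim(need_artifact(p["comparison_counts"], "de"),
                       check.names = FALSE, comment.char = "#")
  venn <- read.delim(need_artifact(p["venn"], "sets"),
                     check.names = FALSE, comment.char = "#")
  targets <- read.delim(need_artifact(p["targets"], "targets"),
                        check.names = FALSE, comment.char = "#")
  lines <- c(artifact_header(config), "",
             "== Differentially expressed miRNAs per comparison ==",
             sprintf("%-28s %6s %6s %6s", "comparison", "n_DE", "up", "down"),
             sprintf("%-28s %6s %6s %6s", counts$comparison,
                     ifelse(is.na(counts$n_de), "n/a", counts$n_de),
                     ifelse(is.na(counts$n_up), "n/a", counts$n_up),
                     ifelse(is.na(counts$n_down), "n/a", counts$n_down)),
             "",
             "== Venn cells (each set is DE vs S-, R+/S+ duplicates excluded) ==",
             sprintf("%-10s %-6s %-12s %5s", "tissue", "dir", "cell", "size"),
             sprintf("%-10s %-6s %-12s %5d", venn$tissue, venn$direction,
                     venn$cell, venn$size),
             "",
             "== Retained hybridization-confirmed targets ==",
             sprintf("total sites: %d; miRNAs with >= 1 target: %d",
                     nrow(targets), length(unique(targets$mirna))))
  if (nrow(targets)) {
    tab <- sort(table(targets$mirna), decreasing = TRUE)
    lines <- c(lines, sprintf("%-16s %4d sites", names(tab), as.integer(tab)))
  }
  writeLines(lines, p["report"])
  invisible(p["report"])
}
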