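# Expression analysis: background subtraction, MA-plot lowess normalization,
# paired t / one-way ANOVA, Benjamini-Hochberg adjustment, qPCR relative
# expression.

#' Subtract the background channel
#'
#' Corrected intensity is `max(foreground - background, floor)` on the
#' linear scale; the background channel is dropped. The floor keeps every
#' value strictly positive so log2 is always defined.
#'
#' @param m an [intensity_matrix()] with a background channel.
#' @param floor minimum corrected intensity (fluorescence units).
#' @return an [intensity_matrix()] with `background = NULL`.
#' @export
subtract_background <- function(m, floor = 1.0) {
  stopifnot(inherits(m, "intensity_matrix"))
  bg <- if (is.null(m$background)) 0 else m$background
  corrected <- pmax(m$foreground - bg, floor)
  intensity_matrix(corrected, NULL, m$probes)
}

# robust lowess fit of M on A, fitted on the central A-quantiles and
# extended as a constant beyond them (edge windows hold few probes and, on
# arrays with strong effects, can be occupied exclusively by differential
# probes, which a trend fit must not absorb)
ma_fit <- function(A, M, span, trim = c(0.025, 0.975)) {
  qs <- stats::quantile(A, trim)
  keep <- A >= qs[1] & A <= qs[2]
  fit <- lowess(A[keep], M[keep], f = span, iter = 3L)
  approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
}

#' MA-plot lowess normalization against a median pseudo-reference
#'
#' For each sample, `M = log2(sample) - log2(reference)` and
#' `A = (log2(sample) + log2(reference)) / 2`, where the reference
#' pseudo-array is the per-probe median across samples. A locally weighted
#' linear regression of M on A (span `span`, degree 1, 3 robustness
#' iterations, fitted on the central 95% of the A-range and extended as a
#' constant beyond it) is subtracted from the sample.
#'
#' The pass is iterated until the trend is gone: within a *round* the
#' reference and A are frozen and fit-subtract passes repeat while the
#' largest fitted trend keeps shrinking; between rounds the reference and A
#' are recomputed from the current values. Iteration stops as soon as a
#' freshly recomputed design fits a trend below `tol` — at that point the
#' operation is idempotent, since renormalizing the output would start from
#' exactly such a design — or when a round no longer improves (its fits are
#' then not applied). The latter happens on noise-dominated data, where
#' shared noise correlates M with A (regression to the mean) and a small
#' irreducible trend remains.
#'
#' @param m background-corrected [intensity_matrix()] (all entries >= the
#'   subtraction floor), or a bare positive matrix.
#' @param span lowess span (fraction of probes per local window).
#' @param tol convergence tolerance on the fitted trend (log2 units).
#' @param max_pass maximum fit-and-subtract passes per round.
#' @param max_rounds maximum design-refresh rounds.
#' @return log2 intensity matrix (probes x samples) with the probe table in
#'   `attr(, "probes")`.
#' @export
lowess_normalize <- function(m, span = 0.3, tol = 1e-4, max_pass = 40L,
                             max_rounds = 10L) {
  probes <- NULL
  if (inherits(m, "intensity_matrix")) {
    probes <- m$probes
    m <- m$foreground
  }
  if (nrow(m) < 10L) {
    stop("input error: fewer than 10 probes; insufficient support for local regression",
         call. = FALSE)
  }
  if (any(m <= 0)) {
    stop("input error: intensities must be positive (run subtract_background first)",
         call. = FALSE)
  }
  x <- log2(m)
  sample_fits <- function(x, ref, A) {
    fits <- vapply(seq_len(ncol(x)),
                   function(s) ma_fit(A[, s], x[, s] - ref, span),
                   numeric(nrow(x)))
    if (!is.matrix(fits)) fits <- matrix(fits, nrow = nrow(x))
    fits
  }
  best_x <- x
  best_measure <- Inf
  fresh_worst <- Inf
  done <- FALSE
  for (round in seq_len(max_rounds)) {
    ref <- apply(x, 1L, median)
    A <- (x + ref) / 2
    prev <- Inf
    for (pass in seq_len(max_pass)) {
      fits <- sample_fits(x, ref, A)
      worst <- max(abs(fits))
      if (worst < best_measure) {   # x currently carries the flattest trend
        best_measure <- worst
        best_x <- x
      }
      if (pass == 1L) {
        if (worst < tol || worst >= fresh_worst) {
          done <- TRUE      # idempotent, or a fresh design no longer improves
          break
        }
        fresh_worst <- worst
      }
      if (worst >= prev) break     # expanding wiggle within the round
      x <- x - fits
      prev <- worst
      if (worst < tol) break
    }
    if (done) break
  }
  x <- best_x
  if (!all(is.finite(x))) stop("normalization produced non-finite values", call. = FALSE)
  attr(x, "probes") <- probes
  x
}

#' Measure the residual MA trend of a log2 matrix
#'
#' Refits the M-vs-A lowess for every sample against the median
#' pseudo-reference and reports the maximum absolute fitted deviation,
#' restricted to the central `central` fraction of the A range (trend
#' estimates at the extremes rest on few probes).
#'
#' @param x log2 matrix (probes x samples).
#' @param span lowess span.
#' @param central central fraction of the A-range to assess.
#' @return largest absolute fitted M trend (log2 units) across samples.
#' @export
assess_ma_trend <- function(x, span = 0.3, central = 0.9) {
  ref <- apply(x, 1L, median)
  worst <- 0
  for (s in seq_len(ncol(x))) {
    M <- x[, s] - ref
    A <- (x[, s] + ref) / 2
    fv <- ma_fit(A, M, span)
    qs <- stats::quantile(A, c((1 - central) / 2, 1 - (1 - central) / 2))
    keep <- A >= qs[1] & A <= qs[2]
    worst <- max(worst, max(abs(fv[keep])))
  }
  worst
}

#' Paired Student's t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = x - y`,
#' with a two-sided p value on `n - 1` degrees of freedom. When the
#' differences have zero variance the statistic is degenerate: `t` is 0 when
#' the mean difference is also 0 (identical vectors) and signed infinity
#' otherwise, and `p` is `NA` with `degenerate = TRUE`.
#'
#' @param x,y numeric vectors paired by position (replicate).
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @examples
#' paired_t_test(c(2.1, 1.9, 2.0), c(1.0, 1.0, 1.0))
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("input error: x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("input error: at least 2 pairs are required", call. = FALSE)
  d <- x - y
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    return(list(t = t, p = NA_real_, df = n - 1L, mean_diff = m,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1L), df = n - 1L,
       mean_diff = m, degenerate = FALSE)
}

#' Classical one-way ANOVA
#'
#' Between/within decomposition with `(k - 1, N - k)` degrees of freedom.
#' Zero within-group variance is flagged degenerate (`F` is 0 when the
#' between-group sum of squares is also 0, infinite otherwise).
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list with `F`, `p`, `df1`, `df2`, `degenerate`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("input error: at least two groups are required", call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) {
    stop("input error: every group needs at least 2 values", call. = FALSE)
  }
  all_v <- unlist(groups)
  N <- length(all_v); k <- length(groups)
  grand <- mean(all_v)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
    return(list(F = f, p = NA_real_, df1 = df1, df2 = df2, degenerate = TRUE))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE), df1 = df1, df2 = df2,
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adjusted[i] = min over j >= rank(i) of m * p[(j)] / j`, capped at 1.
#' Input p values must lie in (0, 1].
#'
#' @param p numeric vector of raw p values.
#' @return adjusted p values, same order as the input.
#' @examples
#' bh_adjust(c(0.001, 0.008, 0.039, 0.041))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("input error: p values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Specify a two-group comparison
#'
#' Covers both cohort contrasts within a tissue (e.g. R- vs S- in fat body)
#' and tissue contrasts within a cohort (fat body vs cuticle in R+).
#'
#' @param cohort_a,cohort_b cohort labels (`R+`, `R-`, `S+`, `S-`).
#' @param tissue_a,tissue_b tissue labels (`cuticle`, `fat_body`);
#'   `tissue_b` defaults to `tissue_a`.
#' @param alpha significance level on the raw p value.
#' @return object of class `comparison_spec`.
#' @export
comparison_spec <- function(cohort_a, tissue_a, cohort_b,
                            tissue_b = tissue_a, alpha = 0.01) {
  for (co in c(cohort_a, cohort_b)) {
    if (!co %in% COHORTS) stop(sprintf("input error: unknown cohort '%s'", co), call. = FALSE)
  }
  for (ti in c(tissue_a, tissue_b)) {
    if (!ti %in% TISSUES) stop(sprintf("input error: unknown tissue '%s'", ti), call. = FALSE)
  }
  if (identical(c(cohort_a, tissue_a), c(cohort_b, tissue_b))) {
    stop("input error: the two groups of a comparison must differ", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("input error: alpha must lie in (0,1)", call. = FALSE)
  structure(list(cohort_a = cohort_a, tissue_a = tissue_a,
                 cohort_b = cohort_b, tissue_b = tissue_b, alpha = alpha,
                 label = if (tissue_a == tissue_b) {
                   comparison_label(cohort_a, cohort_b, tissue_a)
                 } else {
                   sprintf("%s vs %s / %s", tissue_a, tissue_b, cohort_a)
                 }),
            class = "comparison_spec")
}

comparison_label <- function(cohort_a, cohort_b, tissue) {
  sprintf("%s vs %s / %s", cohort_a, cohort_b, tissue)
}

# collapse probe triplicates to one value per miRNA x sample.
# Triplicates are averaged by the mean: with three probes per miRNA the
# mean keeps the full sqrt(3) noise reduction that the triplicate printing
# buys, which the paired test at n = 3 replicates needs.
collapse_probes <- function(x, probes) {
  g <- factor(probes$mirna, levels = unique(probes$mirna))
  out <- rowsum(x, g, reorder = FALSE) / as.vector(table(g)[levels(g)])
  out
}

#' Differential expression calls for one comparison
#'
#' Probe triplicates are averaged per sample, the log2 fold change is
#' `mean(group A) - mean(group B)`, the p value comes from a paired t test
#' across replicate pairs (pairing by replicate index), and BH-adjusted p
#' values are reported alongside. The significance call is gated on the raw
#' p value (`p_raw < alpha`); the adjusted value is reported, not gated on.
#'
#' @param x normalized log2 matrix from [lowess_normalize()] (probe table
#'   attached), or a bare matrix plus `probes`.
#' @param design design table (`sample_id`, `cohort`, `tissue`, `replicate`).
#' @param comparison a [comparison_spec()].
#' @param probes probe table override.
#' @return data.frame of class `de_result`: `mirna`, `comparison`,
#'   `log2_fc`, `t`, `p_raw`, `p_adj`, `significant`, `degenerate`.
#' @export
call_de <- function(x, design, comparison, probes = attr(x, "probes")) {
  stopifnot(inherits(comparison, "comparison_spec"))
  design <- validate_design(design)
  if (is.null(probes)) stop("input error: probe -> miRNA map is required", call. = FALSE)
  pick <- function(co, ti) {
    d <- design[design$cohort == co & design$tissue == ti, ]
    d <- d[order(d$replicate), ]
    if (nrow(d) == 0L) {
      stop(sprintf("input error: no samples for cohort %s / tissue %s", co, ti),
           call. = FALSE)
    }
    d$sample_id
  }
  sa <- pick(comparison$cohort_a, comparison$tissue_a)
  sb <- pick(comparison$cohort_b, comparison$tissue_b)
  if (length(sa) != length(sb)) {
    stop("input error: paired testing needs equal replicate counts", call. = FALSE)
  }
  v <- collapse_probes(x, probes)
  A <- v[, sa, drop = FALSE]
  B <- v[, sb, drop = FALSE]
  d <- A - B
  n <- ncol(d)
  md <- rowMeans(d)
  sdd <- sqrt(rowSums((d - md)^2) / (n - 1L))
  tstat <- ifelse(sdd > 0, md / (sdd / sqrt(n)),
                  ifelse(md == 0, 0, sign(md) * Inf))
  degenerate <- sdd == 0
  p <- ifelse(degenerate, NA_real_, 2 * pt(-abs(md / (sdd / sqrt(n))), df = n - 1L))
  p_adj <- rep(NA_real_, length(p))
  p_adj[!degenerate] <- bh_adjust(p[!degenerate])
  out <- data.frame(mirna = rownames(v),
                    comparison = comparison$label,
                    log2_fc = rowMeans(A) - rowMeans(B),
                    t = tstat, p_raw = p, p_adj = p_adj,
                    significant = !is.na(p) & p < comparison$alpha,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  attr(out, "comparison") <- comparison
  out
}

#' Relative expression by the delta-delta-Ct (Livak) method
#'
#' `dCt = Ct_target - Ct_reference` per condition; `ddCt` is formed per
#' replicate pair (test minus calibrator) and the fold change is
#' `2^(-mean(ddCt))`. The reference is a housekeeping gene (18S rRNA in the
#' assays this mirrors). Per-replicate dCt values are retained so a paired t
#' test between conditions can be run on them.
#'
#' @param ct_target_test,ct_ref_test Ct values in the test condition.
#' @param ct_target_cal,ct_ref_cal Ct values in the calibrator condition.
#' @return list with `fold_change`, `ddct` (per replicate), `per_replicate`
#'   fold changes, and `t_test` (paired t on the dCt values).
#' @examples
#' qpcr_relative_expression(c(20, 20.1), c(15, 15.1), c(22, 22.1), c(15, 15.1))
#' @export
qpcr_relative_expression <- function(ct_target_test, ct_ref_test,
                                     ct_target_cal, ct_ref_cal) {
  all_ct <- c(ct_target_test, ct_ref_test, ct_target_cal, ct_ref_cal)
  if (anyNA(all_ct)) stop("input error: missing Ct value", call. = FALSE)
  if (any(all_ct <= 0)) stop("input error: Ct values must be positive", call. = FALSE)
  if (length(ct_target_test) != length(ct_ref_test) ||
      length(ct_target_cal) != length(ct_ref_cal) ||
      length(ct_target_test) != length(ct_target_cal)) {
    stop("input error: replicate counts must agree across conditions", call. = FALSE)
  }
  dct_test <- ct_target_test - ct_ref_test
  dct_cal <- ct_target_cal - ct_ref_cal
  ddct <- dct_test - dct_cal
  list(fold_change = 2^(-mean(ddct)),
       ddct = ddct,
       per_replicate = 2^(-ddct),
       t_test = if (length(ddct) >= 2L) paired_t_test(dct_test, dct_cal) else NULL)
}
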