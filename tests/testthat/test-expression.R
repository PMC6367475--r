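make_im <- function(fg, bg = NULL) {
  n <- nrow(fg)
  probes <- data.frame(probe_id = sprintf("p%d", seq_len(n)),
                       mirna = sprintf("mir%d", seq_len(n)),
                       replicate_probe = 1L)
  if (is.null(colnames(fg))) colnames(fg) <- sprintf("s%d", seq_len(ncol(fg)))
  if (!is.null(bg)) dimnames(bg) <- dimnames(fg)
  intensity_matrix(fg, bg, probes)
}

test_that("background subtraction floors and drops the channel", {
  m <- make_im(matrix(c(100, 10, 50), 3, 1),
               matrix(c(30, 50, 0), 3, 1))
  out <- subtract_background(m)
  expect_equal(unname(out$foreground[, 1]), c(70, 1, 50))
  expect_null(out$background)
  # all-zero background: identity (floored)
  m2 <- make_im(matrix(c(5, 0.2), 2, 1), matrix(0, 2, 1))
  expect_equal(unname(subtract_background(m2)$foreground[, 1]), c(5, 1))
  expect_error(intensity_matrix(matrix(1, 2, 2), matrix(1, 3, 2),
                                data.frame(probe_id = c("a", "b"),
                                           mirna = c("x", "y"),
                                           replicate_probe = 1L)),
               "shape mismatch")
})

test_that("normalization leaves a reference-identical sample untouched", {
  set.seed(1)
  base <- 2^runif(200, 6, 12)
  fg <- matrix(rep(base, 3), ncol = 3)
  colnames(fg) <- c("a", "b", "c")
  out <- lowess_normalize(make_im(fg))
  expect_lt(max(abs(out - log2(fg))), 1e-6)
})

test_that("normalization removes a constant shift", {
  set.seed(2)
  base <- runif(500, 6, 12)
  x <- cbind(s1 = base, s2 = base, s3 = base + 1.5)  # constant M on sample 3
  out <- lowess_normalize(2^x)
  ref <- apply(out, 1, median)
  expect_lt(max(abs((out[, "s3"] - ref) - median(out[, "s3"] - ref))), 1e-9)
  expect_lt(max(abs(out[, "s3"] - base)), 1e-3)
})

test_that("normalization refuses undersized or unsubtracted input", {
  expect_error(lowess_normalize(matrix(2, 5, 2)), "fewer than 10")
  expect_error(lowess_normalize(matrix(c(-1, rep(2, 19)), 10, 2)), "positive")
})

test_that("planted smooth bias is flattened and renormalization is idempotent", {
  cfg <- sim_config(rng_seed = 41, n_contigs = 5, n_mirnas = 300,
                    noise_sd = 0, bias_amplitude = 0.8)
  mirnas <- make_mirna_set(cfg)
  design <- make_design(cfg)
  ma <- make_microarray(cfg, mirnas, design, planted_de = empty_planted_de())
  corrected <- subtract_background(ma$intensities)
  pre <- assess_ma_trend(log2(corrected$foreground))
  expect_gte(pre, 0.5)
  norm <- lowess_normalize(corrected)
  expect_lt(assess_ma_trend(norm), 0.05)
  renorm <- lowess_normalize(2^unclass(norm))
  expect_lt(max(abs(renorm - norm)), 1e-3)
})

test_that("paired t matches the hand formula and stats::t.test", {
  r <- paired_t_test(c(2.1, 1.9, 2.0), c(1.0, 1.0, 1.0))
  expect_equal(r$t, sqrt(3) * 1.0 / 0.1, tolerance = 1e-12)
  expect_equal(r$df, 2)

  ident <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_true(ident$degenerate)
  expect_true(is.na(ident$p))

  set.seed(3)
  for (k in 1:25) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- paired_t_test(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(paired_t_test(1, 1), "at least 2")
  expect_error(paired_t_test(c(1, 2), c(1, 2, 3)), "paired")
})

test_that("one-way ANOVA matches hand sums of squares, t^2 and aov", {
  r <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$F, 13.5, tolerance = 1e-12)
  expect_equal(r$df1, 1); expect_equal(r$df2, 4)

  # two groups: F = t^2 of the unpaired equal-variance t
  set.seed(4)
  for (k in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    f <- anova_oneway(list(a, b))
    t2 <- unname(t.test(a, b, var.equal = TRUE)$statistic)^2
    expect_equal(f$F, t2, tolerance = 1e-10)
    # and against aov on a random 3-group layout
    g <- list(rnorm(4), rnorm(5), rnorm(3))
    mine <- anova_oneway(g)
    df <- data.frame(y = unlist(g), grp = factor(rep(1:3, lengths(g))))
    ref <- summary(aov(y ~ grp, df))[[1]]
    expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }

  degen <- anova_oneway(list(c(1, 1), c(1, 1)))
  expect_true(degen$degenerate)
  expect_equal(degen$F, 0)
  expect_error(anova_oneway(list(c(1, 2))), "two groups")
})

test_that("BH adjustment reproduces the hand-worked example and the step-up definition", {
  expect_equal(bh_adjust(c(0.001, 0.008, 0.039, 0.041)),
               c(0.004, 0.016, 0.041, 0.041), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(5)
  for (k in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_false(is.unsorted(adj[order(p)]))  # monotone in raw-p rank
    expect_true(all(adj >= p))
  }
  expect_error(bh_adjust(c(0.5, 0)), "input error")
  expect_error(bh_adjust(c(0.5, 1.2)), "input error")
})

test_that("call_de recovers planted effects and is null on self-comparison", {
  cfg <- small_sim_config(seed = 31)
  mirnas <- make_mirna_set(cfg)
  design <- make_design(cfg)
  plant <- data.frame(mirna = mirnas$name[c(1, 2)], cohort = "R-",
                      tissue = "fat_body", log2_fc = c(2, -2))
  ma <- make_microarray(cfg, mirnas, design, planted_de = plant)
  norm <- lowess_normalize(subtract_background(ma$intensities))
  de <- call_de(norm, design, comparison_spec("R-", "fat_body", "S-"))
  expect_s3_class(de, "de_result")
  expect_equal(nrow(de), nrow(mirnas))
  expect_true(all(de$p_adj >= de$p_raw, na.rm = TRUE))
  top <- de[match(plant$mirna, de$mirna), ]
  expect_equal(sign(top$log2_fc), c(1, -1))
  expect_true(all(abs(top$log2_fc - plant$log2_fc) < 0.6))

  # same group on both sides: all fold changes exactly zero
  self <- call_de(norm, design, comparison_spec("R-", "fat_body", "R-", "cuticle"))
  expect_equal(nrow(self), nrow(mirnas))
  selfsame <- call_de(norm, design,
                      structure(list(cohort_a = "R-", tissue_a = "fat_body",
                                     cohort_b = "R-", tissue_b = "fat_body",
                                     alpha = 0.01, label = "self"),
                                class = "comparison_spec"))
  expect_true(all(selfsame$log2_fc == 0))
  expect_true(all(selfsame$degenerate))

  expect_error(comparison_spec("Q+", "fat_body", "S-"), "unknown cohort")
  expect_error(comparison_spec("R-", "liver", "S-"), "unknown tissue")
  expect_error(comparison_spec("R-", "fat_body", "R-"), "must differ")
})

test_that("call_de agrees with per-miRNA stats::t.test", {
  cfg <- small_sim_config(seed = 37)
  mirnas <- make_mirna_set(cfg)
  design <- make_design(cfg)
  ma <- make_microarray(cfg, mirnas, design)
  norm <- lowess_normalize(subtract_background(ma$intensities))
  de <- call_de(norm, design, comparison_spec("R+", "cuticle", "S-"))
  probes <- attr(norm, "probes")
  a_cols <- design$sample_id[design$cohort == "R+" & design$tissue == "cuticle"]
  b_cols <- design$sample_id[design$cohort == "S-" & design$tissue == "cuticle"]
  for (nm in mirnas$name[c(2, 11, 27)]) {
    va <- colMeans(norm[probes$mirna == nm, a_cols])
    vb <- colMeans(norm[probes$mirna == nm, b_cols])
    ref <- t.test(va, vb, paired = TRUE)
    row <- de[de$mirna == nm, ]
    expect_equal(row$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(row$p_raw, ref$p.value, tolerance = 1e-9)
    expect_equal(row$log2_fc, mean(va) - mean(vb), tolerance = 1e-12)
  }
})

test_that("delta-delta-Ct fold changes follow the Livak model", {
  # ddCt = 0 -> fold 1
  expect_equal(qpcr_relative_expression(20, 15, 22, 17)$fold_change, 1)
  # ddCt = -2 -> fold 4
  expect_equal(qpcr_relative_expression(18, 15, 22, 17)$fold_change, 4)
  # ddCt = 1.5 -> 2^-1.5
  r <- qpcr_relative_expression(21.5, 15, 22, 17)
  expect_equal(r$fold_change, 2^-1.5, tolerance = 1e-12)
  r2 <- qpcr_relative_expression(c(20, 20.2), c(15, 15.1), c(22, 21.9), c(17, 16.8))
  expect_length(r2$per_replicate, 2)
  expect_false(is.null(r2$t_test))
  expect_error(qpcr_relative_expression(c(20, NA), c(15, 15), c(22, 22), c(17, 17)),
               "missing Ct")
  expect_error(qpcr_relative_expression(20, 15, c(22, 22), c(17, 17)),
               "replicate counts")
})
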