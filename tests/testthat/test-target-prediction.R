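test_that("seed derivation matches the hand-computed reverse complement", {
  s <- derive_seed("mir", "UAGCUUAUCAGACUGAUGUUGA")
  expect_identical(s$seed_rna, "AGCUUAU")
  expect_identical(s$match_dna, "ATAAGCT")
  # homopolymer symmetry
  expect_identical(derive_seed("a", strrep("A", 22))$match_dna, "TTTTTTT")
  # purity
  expect_identical(derive_seed("mir", "UAGCUUAUCAGACUGAUGUUGA"), s)
  expect_error(derive_seed("short", "UAGCUUA"), "shorter than 8")
  # literal variant: positions 2-8 of the whole reverse complement
  lit <- derive_seed("mir", "UAGCUUAUCAGACUGAUGUUGA",
                     interpretation = "literal_revcomp")
  expect_identical(lit$match_dna,
                   substr("TCAACATCAGTCTGATAAGCTA", 2, 8))
})

test_that("seed scanning equals naive substring search, overlaps included", {
  pat <- data.frame(name = "m1", seed_rna = "AAAAAAA", match_dna = "TTTTTTT")
  utr <- data.frame(contig = "c", utr_start = 100, sequence = "TTTTTTTTT")
  hits <- scan_seed_matches(utr, pat)
  expect_equal(hits$utr_pos, 0:2)           # overlapping occurrences
  expect_equal(hits$contig_pos, 100:102)

  none <- scan_seed_matches(data.frame(contig = "c", utr_start = 0,
                                       sequence = "GGGGGGGGGG"), pat)
  expect_equal(nrow(none), 0)
  exact <- scan_seed_matches(data.frame(contig = "c", utr_start = 5,
                                        sequence = "TTTTTTT"), pat)
  expect_equal(exact$utr_pos, 0)

  set.seed(23)
  utrs <- data.frame(contig = sprintf("c%03d", 1:80),
                     utr_start = sample(50:500, 80, replace = TRUE),
                     sequence = vapply(1:80, function(i) random_nt(sample(40:160, 1)), ""))
  pats <- data.frame(name = sprintf("m%02d", 1:12),
                     seed_rna = NA,
                     match_dna = vapply(1:12, function(i) random_nt(7), ""))
  mine <- scan_seed_matches(utrs, pats)
  naive <- do.call(rbind, lapply(seq_len(nrow(pats)), function(k) {
    do.call(rbind, lapply(seq_len(nrow(utrs)), function(u) {
      pos <- naive_search(utrs$sequence[u], pats$match_dna[k])
      if (!length(pos)) return(NULL)
      data.frame(mirna = pats$name[k], contig = utrs$contig[u], utr_pos = pos,
                 contig_pos = utrs$utr_start[u] + pos)
    }))
  }))
  naive <- naive[order(naive$mirna, naive$contig, naive$utr_pos), ]
  expect_equal(mine, naive, ignore_attr = TRUE)
  expect_error(scan_seed_matches(utrs, pats[0, ]), "no seed patterns")
})

test_that("duplex energies: single pair, full helix closed form, resummation", {
  em <- default_energy_model()
  # 1-nt site: one admissible pair, no stacking possible
  one <- duplex_mfe("AAAAAAAAAA", "U", em)
  expect_equal(one$mfe, em$initiation)
  expect_equal(nrow(one$pairs), 1)

  # perfectly complementary site: full helix, initiation + 21 stack terms
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  site <- "UCAACAUCAGUCUGAUAAGCUA"  # exact reverse complement
  full <- duplex_mfe(mir, site, em)
  mc <- strsplit(mir, "")[[1]]; sc <- strsplit(site, "")[[1]]
  L <- length(mc)
  closed <- em$initiation + sum(vapply(seq_len(L - 1), function(t) {
    unname(em$stacks[paste0(mc[t], mc[t + 1], "/", sc[L - t + 1], sc[L - t])])
  }, 0))
  expect_equal(full$mfe, closed, tolerance = 1e-12)
  expect_equal(nrow(full$pairs), L)

  # every reported structure re-sums to its mfe exactly
  set.seed(29)
  for (k in 1:40) {
    m <- random_nt(sample(8:22, 1), c("A", "C", "G", "U"))
    s <- random_nt(sample(7:40, 1), c("A", "C", "G", "U"))
    r <- duplex_mfe(m, s, em)
    if (is.na(r$mfe)) next
    expect_equal(duplex_energy(r$pairs, m, s, em), r$mfe, tolerance = 1e-9)
  }
})

test_that("the DP equals the direct-definition oracle and full enumeration", {
  em <- default_energy_model()
  set.seed(31)
  # exhaustive enumeration on small instances (validates the quartic oracle too)
  for (k in 1:25) {
    m <- random_nt(sample(4:7, 1), c("A", "C", "G", "U"))
    s <- random_nt(sample(4:7, 1), c("A", "C", "G", "U"))
    dp <- duplex_mfe(m, s, em)$mfe
    expect_equal(dp, duplex_oracle_enum(m, s, em), tolerance = 1e-9)
    expect_equal(dp, duplex_oracle_dp(m, s, em), tolerance = 1e-9)
  }
  # adversarial fully-complementary instance: maximal structure count
  expect_equal(duplex_mfe("AAAAGGGG", "CCCCUUUU", em)$mfe,
               duplex_oracle_enum("AAAAGGGG", "CCCCUUUU", em), tolerance = 1e-9)

  # quartic oracle at the acceptance scale (lengths <= 10)
  for (k in 1:60) {
    m <- random_nt(sample(2:10, 1), c("A", "C", "G", "U"))
    s <- random_nt(sample(2:10, 1), c("A", "C", "G", "U"))
    expect_equal(duplex_mfe(m, s, em)$mfe, duplex_oracle_dp(m, s, em),
                 tolerance = 1e-9)
  }
})

test_that("the seed constraint admits only contiguous Watson-Crick seed helices", {
  em <- default_energy_model()
  rna_rc <- function(x) paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]),
                              collapse = "")
  set.seed(37)
  checked <- 0
  for (k in 1:12) {
    m <- random_nt(9, c("A", "C", "G", "U"))
    # plant the exact seed complement so an admissible structure exists
    s <- paste0(random_nt(sample(0:1, 1), c("A", "C", "G", "U")),
                rna_rc(substr(m, 2, 8)),
                random_nt(sample(0:1, 1), c("A", "C", "G", "U")))
    want <- duplex_oracle_enum(m, s, em, require_seed = TRUE)
    got <- duplex_mfe(m, s, em, require_seed = TRUE)
    expect_equal(got$mfe, want, tolerance = 1e-9)
    if (!is.na(want)) {
      checked <- checked + 1
      expect_true(all(2:8 %in% got$pairs[, "mirna_pos"]))
    }
  }
  expect_gte(checked, 5)
  # windows with no Watson-Crick seed run admit nothing
  none <- duplex_mfe("AAAAAAAAA", "AAAAAAAAA", em, require_seed = TRUE)
  expect_true(is.na(none$mfe))
  # a window that cannot pair the seed yields NA, and short windows error
  expect_error(duplex_mfe("UAGCUUAUCAGACUGAUGUUGA", "ACUAG", em,
                          require_seed = TRUE), "shorter than 7")
  expect_error(duplex_mfe("UAGCUUA", "ACUAGGG", em, require_seed = TRUE),
               "shorter than 8")
})

test_that("seed helix energy bounds the reported optimum from above", {
  em <- default_energy_model()
  mir <- "UAGCUUAUCAGACUGAUGUUGA"
  site_dna <- paste0("GGATCGATTGAG", "ATAAGCT", "CAGGATTTCAGG")
  r <- duplex_mfe(mir, chartr("T", "U", site_dna), em, require_seed = TRUE)
  expect_false(is.na(r$mfe))
  seed_only <- duplex_energy(
    r$pairs[r$pairs[, 1] >= 2 & r$pairs[, 1] <= 8, , drop = FALSE],
    mir, chartr("T", "U", site_dna), em)
  expect_lte(r$mfe, seed_only)
})

test_that("target prediction recovers planted sites and filters monotonely", {
  cfg <- small_sim_config(seed = 61, site_plant_prob = 1, n_contigs = 20)
  mirnas <- make_mirna_set(cfg)
  tx <- make_transcriptome(cfg, mirnas)
  ann <- annotate_utrs(tx$contigs)
  # threshold off: every seed match retained; planted (miRNA, contig) recovered
  all_t <- predict_targets(mirnas, ann$utrs, mfe_threshold = Inf)
  truth_pairs <- paste(tx$truth$sites$mirna, tx$truth$sites$contig)
  expect_true(all(truth_pairs %in% paste(all_t$mirna, all_t$contig)))
  expect_setequal(paste(all_t$mirna, all_t$contig, all_t$utr_pos),
                  paste(tx$truth$sites$mirna, tx$truth$sites$contig,
                        tx$truth$sites$utr_offset))
  # default sites are full-complement contexts: strong hybrids at -20
  strong <- predict_targets(mirnas, ann$utrs, mfe_threshold = -20)
  expect_true(all(truth_pairs %in% paste(strong$mirna, strong$contig)))
  # monotone filter
  n_prev <- Inf
  for (thr in c(Inf, -10, -20, -30, -60)) {
    n_now <- nrow(predict_targets(mirnas, ann$utrs, mfe_threshold = thr))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("process summary equals a brute-force group-by", {
  targets <- data.frame(
    mirna = c("m1", "m1", "m2", "m3", "m3"),
    contig = c("c1", "c2", "c1", "c3", "c4"),
    utr_pos = 1:5, contig_pos = 1:5, site_window = "x",
    mfe = -25, n_pairs = 10)
  ann <- data.frame(contig = c("c1", "c2", "c3", ""),
                    process = c("proteolysis", "cuticle formation", "", "oxidoreductase"))
  expect_warning(s <- summarize_by_process(targets, ann), "malformed")
  expect_equal(attr(s, "skipped_rows"), 2)
  expect_equal(s$n_contigs[s$process == "proteolysis"], 1)
  expect_equal(s$n_contigs[s$process == "unannotated"], 2)  # c3, c4
  # empty annotation: everything unannotated
  s0 <- summarize_by_process(targets, NULL)
  expect_equal(s0$n_contigs[s0$process == "unannotated"], 4)
  # single target, single process
  s1 <- summarize_by_process(targets[1, ], data.frame(contig = "c1", process = "p"))
  expect_equal(s1$n_contigs, 1)
  # brute-force tabulation on a random fixture
  set.seed(41)
  tg <- data.frame(mirna = sample(sprintf("m%d", 1:6), 40, TRUE),
                   contig = sample(sprintf("c%d", 1:15), 40, TRUE),
                   utr_pos = 1, contig_pos = 1, site_window = "x",
                   mfe = -25, n_pairs = 8)
  an <- data.frame(contig = sprintf("c%d", 1:10),
                   process = sample(c("p1", "p2", "p3"), 10, TRUE))
  s2 <- summarize_by_process(tg, an)
  lookup <- setNames(an$process, an$contig)
  proc <- ifelse(tg$contig %in% names(lookup), lookup[tg$contig], "unannotated")
  brute <- tapply(tg$contig, proc, function(v) length(unique(v)))
  expect_equal(setNames(s2$n_contigs, s2$process)[names(brute)], brute,
               ignore_attr = TRUE)
})
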