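test_that("peak-loss reduction follows its definition", {
  g <- gene_models(c("g1", "g2"), "chr1", c("+", "+"),
                   tss = c(1000L, 10000L), tes = c(3000L, 12000L))
  wt <- peaks_table(rep("chr1", 2), c(1200L, 10200L), c(1800L, 10800L),
                    rep(-40, 2), rep(3, 2))
  mut_keep_g2 <- peaks_table("chr1", 10200L, 10800L, -40, 3)

  r <- reduced_methylation(wt, mut_keep_g2, g)
  expect_equal(r, c(g1 = TRUE, g2 = FALSE))

  # identical WT and mutant peak sets: nothing is reduced
  r2 <- reduced_methylation(wt, wt, g)
  expect_false(any(r2))

  # asking about a gene not marked in WT is undefined
  no_peaks <- peaks_table()
  expect_error(reduced_methylation(wt, wt, g, gene_ids = "g3"),
               "not K27-marked")
  r3 <- reduced_methylation(wt, no_peaks, g)
  expect_true(all(r3))
})

test_that("signal-drop mode compares gene-body means", {
  g <- gene_models("g1", "chr1", "+", tss = 1000L, tes = 3000L)
  wt_pk <- peaks_table("chr1", 1200L, 1800L, -40, 3)
  n <- 100
  pos <- seq(0L, by = 50L, length.out = n)
  body <- pos >= 1000 & pos < 3000
  wt_trk <- probe_track(rep("chr1", n), pos, ifelse(body, 2, 0))
  drop_trk <- probe_track(rep("chr1", n), pos, ifelse(body, 0.5, 0))
  hold_trk <- probe_track(rep("chr1", n), pos, ifelse(body, 1.5, 0))
  expect_true(reduced_methylation(wt_pk, wt_pk, g, mode = "signal_drop",
                                  wt_track = wt_trk,
                                  mutant_track = drop_trk)[["g1"]])
  expect_false(reduced_methylation(wt_pk, wt_pk, g, mode = "signal_drop",
                                   wt_track = wt_trk,
                                   mutant_track = hold_trk)[["g1"]])
})

test_that("planted mutant loss fractions are recovered end to end", {
  fracs <- numeric(0)
  for (seed in 1:10) {
    cfg <- sim_config(genome_length = 1.2e6, n_chromosomes = 1,
                      n_genes = 250, frac_emf1_bound = 0, frac_k27 = 0.5,
                      mutant_loss = c(fie = 0.84),
                      expression_samples = "WT", seed = 600 + seed)
    gn <- simulate_genome(cfg)
    chip <- simulate_chip_tracks(gn, cfg)
    kp <- caller_params("k27")
    wt_pk <- call_peaks(chip$tracks$k27_WT, kp, gn$chrom_sizes)
    mu_pk <- call_peaks(chip$tracks$k27_fie, kp, gn$chrom_sizes)
    r <- reduced_methylation(wt_pk, mu_pk, gn$genes,
                             chrom_sizes = gn$chrom_sizes)
    fracs <- c(fracs, mean(r))
  }
  expect_lt(abs(mean(fracs) - 0.84), 0.03)
})

test_that("classification reproduces the printed set arithmetic", {
  # printed margins: 5,533 bound; 3,230 also K27 (58%); Group I 1,845 (57%)
  universe <- sprintf("At%05d", seq_len(28244))
  emf1 <- universe[1:5533]
  k27 <- universe[c(1:3230, 10000:14520)]       # 3,230 overlap the bound set
  reduced <- universe[1:1845]
  st <- classify_genes(emf1, k27, reduced, universe)
  tab <- table(st$group)
  expect_equal(unname(tab[["EMF1_K27_groupI"]]), 1845L)
  expect_equal(unname(tab[["EMF1_K27_groupII"]]), 1385L)   # 3,230 - 1,845
  expect_equal(unname(tab[["EMF1_no_K27"]]), 2303L)        # 5,533 - 3,230
  # the partition identities
  expect_equal(tab[["EMF1_K27_groupI"]] + tab[["EMF1_K27_groupII"]], 3230L)
  expect_equal(3230L + tab[["EMF1_no_K27"]], length(emf1))
  expect_equal(sum(tab), length(universe))
  # fractions as printed: 58% of bound genes marked, 57%/43% split
  expect_equal(round(100 * 3230 / 5533), 58)
  expect_equal(round(100 * 1845 / 3230), 57)
  expect_equal(round(100 * 1385 / 3230), 43)
})

test_that("classification errors and degenerate cases behave", {
  u <- letters
  expect_error(classify_genes("a", c("a", "b"), "c", u), "subset of k27")
  expect_error(classify_genes("zz", "a", character(0), u), "universe")
  st <- classify_genes(character(0), c("a", "b"), character(0), u)
  expect_equal(sum(st$group == "K27_only"), 2L)
  expect_false(any(st$group %in% c("EMF1_K27_groupI", "EMF1_K27_groupII")))
})

test_that("fisher_overlap matches full hypergeometric enumeration", {
  # total containment on a small universe: p = 1 / C(20,10)
  u <- sprintf("g%02d", 1:20)
  r <- fisher_overlap(u[1:10], u[1:10], u)
  expect_equal(r$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(r$expected_overlap, 5)

  set.seed(51)
  for (i in 1:100) {
    N <- sample(20:2000, 1)
    u <- sprintf("x%04d", seq_len(N))
    a <- sample(u, sample.int(N, 1))
    b <- sample(u, sample.int(N, 1))
    r <- fisher_overlap(a, b, u)
    bf <- bf_hyper_log10(r$overlap, r$size_b, N, r$size_a)
    expect_equal(r$log10_p, bf, tolerance = 1e-9)
  }
})

test_that("overlap p-values point the right way", {
  N <- 1000
  u <- sprintf("x%04d", seq_len(N))
  a <- u[1:100]
  b <- u[c(1:10, 101:190)]   # overlap 10 = expected 100*100/1000
  r <- fisher_overlap(a, b, u)
  expect_gt(r$p_value, 0.2)
  expect_lt(r$p_value, 0.9)
  # overlap below expectation: p >= 0.5
  b2 <- u[c(1:5, 101:195)]
  expect_gte(fisher_overlap(a, b2, u)$p_value, 0.5)
  expect_error(fisher_overlap("a", "a", character(0)), "empty universe")
})

test_that("venn regions match per-element enumeration", {
  s <- sprintf("g%02d", 1:10)
  idt <- venn_counts(list(A = s, B = s, C = s))
  expect_equal(unname(idt$regions["abc"]), 10L)
  expect_equal(sum(idt$regions), 10L)
  expect_equal(unname(idt$conditional_triple), rep(1, 3))

  dis <- venn_counts(list(A = s[1:3], B = s[4:6], C = s[7:9]))
  expect_equal(unname(dis$regions[c("ab", "ac", "bc", "abc")]),
               rep(0L, 4))

  set.seed(61)
  pool <- sprintf("e%03d", 1:200)
  sets <- lapply(1:3, function(i) sample(pool, 80))
  names(sets) <- c("A", "B", "C")
  v <- venn_counts(sets)
  # brute force: classify every element by membership pattern
  pat <- sapply(pool, function(e)
    paste0(as.integer(e %in% sets$A), as.integer(e %in% sets$B),
           as.integer(e %in% sets$C)))
  expect_equal(unname(v$regions["a_only"]), sum(pat == "100"))
  expect_equal(unname(v$regions["ab"]), sum(pat == "110"))
  expect_equal(unname(v$regions["abc"]), sum(pat == "111"))
  expect_equal(unname(v$conditional_triple["B"]),
               sum(pat == "111") / length(sets$B))
})

test_that("independent vs planted co-occupancy drives the overlap test", {
  cfg_ind <- sim_config(seed = 71)
  gn <- simulate_genome(cfg_ind)
  tr_ind <- simulate_chip_tracks(gn, cfg_ind)
  a <- tr_ind$truth$gene_id[tr_ind$truth$planted_emf1]
  b <- tr_ind$truth$gene_id[tr_ind$truth$planted_k27_wt]
  r_ind <- fisher_overlap(a, b, tr_ind$truth$gene_id)
  dev <- abs(r_ind$overlap - r_ind$expected_overlap)
  sd_ov <- sqrt(r_ind$expected_overlap *
                (1 - r_ind$size_b / r_ind$universe_size))
  expect_lt(dev, 3.5 * sd_ov)
  expect_gt(r_ind$p_value, 1e-3)

  cfg_co <- sim_config(co_occupancy = 0.6, seed = 72)
  tr_co <- simulate_chip_tracks(gn, cfg_co)
  a2 <- tr_co$truth$gene_id[tr_co$truth$planted_emf1]
  b2 <- tr_co$truth$gene_id[tr_co$truth$planted_k27_wt]
  r_co <- fisher_overlap(a2, b2, tr_co$truth$gene_id)
  expect_lt(r_co$log10_p, -20)
})
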