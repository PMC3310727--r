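test_that("presets carry the published cutoff pairs", {
  p_emf1 <- caller_params("emf1")
  expect_equal(p_emf1$p_cutoff, 1e-6)
  expect_equal(p_emf1$min_peak_length, 100L)
  p_k27 <- caller_params("k27")
  expect_equal(p_k27$p_cutoff, 1e-35)
  expect_equal(p_k27$min_peak_length, 300L)
  expect_equal(p_emf1$window_size, 300L)
  expect_equal(p_emf1$step_size, 50L)
  expect_error(caller_params("custom"), "p_cutoff")
  expect_error(caller_params("emf1", window_size = 40, step_size = 50),
               "window_size")
})

test_that("mirrored-negative sigma follows its defining formula", {
  trk <- probe_track(rep("chr1", 4), c(0, 50, 100, 150), c(-1, -1, 1, 5))
  expect_equal(estimate_noise_sigma(trk), 1.0)

  all_pos <- probe_track(rep("chr1", 3), c(0, 50, 100), c(1, 2, 3))
  expect_error(estimate_noise_sigma(all_pos, center = FALSE),
               "non-positive")

  # Monte-Carlo: a pure Normal(0, 0.5) null is recovered
  big <- noise_track(n = 1e5, sd = 0.5, seed = 99)
  expect_lt(abs(estimate_noise_sigma(big) - 0.5), 0.01)
  expect_lt(abs(estimate_noise_sigma(big, mode = "global_sd") - 0.5), 0.01)
})

test_that("window p-values follow the one-sided Gaussian null", {
  trk <- probe_track(rep("chr1", 6), seq(0, 250, 50), rep(0, 6))
  p <- caller_params("emf1")
  ws <- window_scan(trk, p, sigma = 0.5)
  expect_equal(ws$log10_p[1], log10(0.5))    # mean 0 -> p = 0.5

  # mean = sigma with 4 probes: z = 2, p = upper-tail Phi(2)
  trk2 <- probe_track(rep("chr1", 4), seq(0, 150, 50), rep(0.5, 4))
  ws2 <- window_scan(trk2, caller_params("emf1"), sigma = 0.5)
  expect_equal(10^ws2$log10_p[1], 0.02275013, tolerance = 1e-6)

  # a 10 kb chromosome at step 50 has 200 window positions
  trk3 <- noise_track(n = 200, spacing = 50, seed = 2)   # spans [0, 9951)
  ws3 <- window_scan(trk3, caller_params("emf1"), sigma = 0.5,
                     chrom_sizes = c(chr1 = 10000))
  expect_equal(nrow(ws3), 200L)
  expect_equal(ws3$start, seq(0L, 9950L, 50L))
})

test_that("window means and p-values match brute-force enumeration", {
  set.seed(41)
  # irregular probe spacing over ~20 kb, two chromosomes
  pos1 <- sort(sample.int(20000, 350))
  pos2 <- sort(sample.int(15000, 200))
  trk <- probe_track(c(rep("chr1", 350), rep("chr2", 200)),
                     c(pos1, pos2) - 1L, rnorm(550, 0.1, 0.6))
  p <- caller_params("emf1")
  sigma <- estimate_noise_sigma(trk)
  ws <- window_scan(trk, p, sigma)
  bf <- bf_window_scan(trk, p$window_size, p$step_size, sigma)
  expect_equal(nrow(ws), nrow(bf))
  expect_equal(ws$n_probes, bf$n_probes)
  expect_equal(ws$mean_value, bf$mean_value, tolerance = 1e-12)
  expect_equal(ws$log10_p, bf$log10_p, tolerance = 1e-12)
})

test_that("null tracks yield (almost) no peaks at the binding preset", {
  # 2 Mb of pure noise per seed; expected false windows = 4e4 * 1e-6
  total <- 0L
  for (seed in 1:20) {
    trk <- noise_track(n = 40000, sd = 0.5, seed = 100 + seed)
    pk <- call_peaks(trk, caller_params("emf1"))
    total <- total + nrow(pk)
  }
  expect_lte(total, 4L)   # Poisson(0.8) over the 20 seeds
})

test_that("a planted domain is recovered as a single covering peak", {
  set.seed(7)
  n <- 4000                               # 200 kb at 50 bp spacing
  v <- rnorm(n, 0, 0.5)
  dom <- c(100000L, 100600L)              # 600 bp at +3 sigma
  pos <- seq(0L, by = 50L, length.out = n)
  in_dom <- pos >= dom[1] & pos < dom[2]
  v[in_dom] <- v[in_dom] + 1.5
  trk <- probe_track(rep("chr1", n), pos, v)
  pk <- call_peaks(trk, caller_params("emf1"))
  expect_equal(nrow(pk), 1L)
  ov <- min(pk$end, dom[2]) - max(pk$start, dom[1])
  expect_gte(ov / 600, 0.8)

  # the same domain fails a 1000 bp minimum-length filter
  pk2 <- call_peaks(trk, caller_params("emf1", min_peak_length = 1000))
  expect_equal(nrow(pk2), 0L)
})

test_that("significant-window counts are calibrated on the null", {
  # relaxed alpha = 1e-3; window count is fixed per seed, expectation is
  # exact by linearity even though neighboring windows are correlated
  alpha <- 1e-3
  n_sig <- 0; n_win <- 0
  for (seed in 1:20) {
    trk <- noise_track(n = 4000, sd = 0.5, seed = 300 + seed)
    params <- caller_params("custom", p_cutoff = alpha, min_peak_length = 1)
    sigma <- estimate_noise_sigma(trk)
    ws <- window_scan(trk, params, sigma)
    n_sig <- n_sig + sum(ws$log10_p < log10(alpha), na.rm = TRUE)
    n_win <- n_win + sum(ws$n_probes > 0)
  }
  expected <- n_win * alpha
  expect_gt(n_sig, expected / 2)
  expect_lt(n_sig, expected * 2)
})

test_that("planted +3 sigma domains >= 600 bp are found with high sensitivity", {
  found <- 0L; planted <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(genome_length = 5e5, n_chromosomes = 1, n_genes = 40,
                      frac_emf1_bound = 0.5, frac_k27 = 0,
                      emf1_length_range = c(600, 1000), mutant_loss = c(),
                      expression_samples = "WT", seed = 400 + seed)
    gn <- simulate_genome(cfg)
    chip <- simulate_chip_tracks(gn, cfg)
    pk <- call_peaks(chip$tracks$emf1, caller_params("emf1"),
                     gn$chrom_sizes)
    bound <- assign_peaks_to_genes(pk, gn$genes,
                                   chrom_sizes = gn$chrom_sizes)$bound_genes
    truth <- gn$genes$gene_id[chip$truth$planted_emf1]
    planted <- planted + length(truth)
    found <- found + sum(truth %in% bound)
  }
  expect_gte(found / planted, 0.95)
})

test_that("peak counts respond monotonically to the cutoffs", {
  set.seed(55)
  n <- 8000
  pos <- seq(0L, by = 50L, length.out = n)
  v <- rnorm(n, 0, 0.5)
  for (s in seq(0, by = 40000, length.out = 8)) {
    sel <- pos >= s + 1000 & pos < s + 1000 + sample(300:900, 1)
    v[sel] <- v[sel] + runif(1, 0.5, 2)
  }
  trk <- probe_track(rep("chr1", n), pos, v)
  n_at <- function(p_cut, min_len = 100) {
    nrow(call_peaks(trk, caller_params("custom", p_cutoff = p_cut,
                                       min_peak_length = min_len)))
  }
  cuts <- c(1e-12, 1e-9, 1e-6, 1e-3)
  expect_true(all(diff(vapply(cuts, n_at, numeric(1))) >= 0))
  lens <- c(100, 300, 600, 1200)
  expect_true(all(diff(vapply(lens, function(l) n_at(1e-4, l),
                              numeric(1))) <= 0))
})

test_that("merged peaks are disjoint and each contains a significant window", {
  set.seed(66)
  n <- 6000
  pos <- seq(0L, by = 50L, length.out = n)
  v <- rnorm(n, 0, 0.5)
  for (s in c(20000, 21000, 100000, 200000)) {
    sel <- pos >= s & pos < s + 700
    v[sel] <- v[sel] + 1.6
  }
  trk <- probe_track(rep("chr1", n), pos, v)
  params <- caller_params("emf1")
  pk <- call_peaks(trk, params)
  expect_gt(nrow(pk), 0L)
  expect_true(all(pk$end - pk$start >= params$min_peak_length))
  expect_true(all(pk$log10_p < log10(params$p_cutoff)))
  by_c <- split(pk, pk$chrom)
  for (sub in by_c) {
    if (nrow(sub) > 1) expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  # cross-check: every peak holds >= 1 window below the cutoff
  sigma <- estimate_noise_sigma(trk)
  ws <- window_scan(center_track(trk), params, sigma)
  sig <- ws[!is.na(ws$log10_p) & ws$log10_p < log10(params$p_cutoff), ]
  for (i in seq_len(nrow(pk))) {
    expect_true(any(sig$start < pk$end[i] & sig$end > pk$start[i]))
  }
})
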