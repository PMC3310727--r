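# span of the planted binding domain, recomputed from first principles
planted_emf1_span <- function(gene, len) {
  if (gene$strand == "+") c(gene$tss, gene$tss + len)
  else c(gene$tss - len, gene$tss)
}

test_that("the probe grid tiles every chromosome at the set spacing", {
  cfg <- sim_config(genome_length = 200000, n_chromosomes = 2, n_genes = 10,
                    probe_spacing = 50, seed = 3)
  gn <- simulate_genome(cfg)
  for (cc in names(gn$chrom_sizes)) {
    p <- gn$probes$pos[gn$probes$chrom == cc]
    expect_length(p, 2000)  # 100 kb / 50 bp
    expect_equal(p, seq(0L, 99950L, 50L))
  }
})

test_that("gene placement respects the intergenic-gap invariant", {
  cfg <- sim_config(genome_length = 1e6, n_chromosomes = 1, n_genes = 100,
                    seed = 11)
  gn <- simulate_genome(cfg)
  span <- data.frame(start = pmin(gn$genes$tss, gn$genes$tes),
                     end = pmax(gn$genes$tss, gn$genes$tes))
  span <- span[order(span$start), ]
  gaps <- span$start[-1] - span$end[-nrow(span)]
  expect_true(all(gaps >= 2000))
  expect_true(all(span$start >= 0) && all(span$end <= 1e6))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 2e5, n_chromosomes = 1, n_genes = 20,
                    seed = 5)
  a <- simulate_genome(cfg); b <- simulate_genome(cfg)
  expect_identical(a, b)
  ca <- simulate_chip_tracks(a, cfg); cb <- simulate_chip_tracks(b, cfg)
  expect_identical(ca, cb)
  ea <- simulate_expression(a, cfg); eb <- simulate_expression(b, cfg)
  expect_identical(ea, eb)
  # a different seed changes the draw
  cfg2 <- sim_config(genome_length = 2e5, n_chromosomes = 1, n_genes = 20,
                     seed = 6)
  expect_false(identical(simulate_chip_tracks(a, cfg2)$tracks$emf1$value,
                         ca$tracks$emf1$value))
})

test_that("infeasible gene packing raises a configuration error", {
  cfg <- sim_config(genome_length = 1e5, n_chromosomes = 1, n_genes = 200,
                    seed = 1)
  expect_error(simulate_genome(cfg), "infeasible packing")
})

test_that("planted binding domains carry the configured effect", {
  cfg <- sim_config(genome_length = 2e5, n_chromosomes = 1, n_genes = 5,
                    frac_emf1_bound = 1, frac_k27 = 0, noise_sd = 0.5,
                    emf1_length_range = c(600, 600), mutant_loss = c(),
                    expression_samples = "WT", seed = 21)
  gn <- simulate_genome(cfg)
  chip <- simulate_chip_tracks(gn, cfg)
  trk <- chip$tracks$emf1
  for (i in seq_len(nrow(gn$genes))) {
    sp <- planted_emf1_span(gn$genes[i, ], 600)
    inside <- trk$value[trk$pos >= sp[1] & trk$pos < sp[2]]
    expect_length(inside, 12)           # 600 bp / 50 bp spacing
    # mean of 12 probes at +3 sigma: sampling error ~ sigma/sqrt(12)
    expect_lt(abs(mean(inside) - 3 * 0.5), 4 * 0.5 / sqrt(12))
  }
})

test_that("zero planted fraction gives a pure-noise track", {
  cfg <- sim_config(genome_length = 4e5, n_chromosomes = 1, n_genes = 20,
                    frac_emf1_bound = 0, frac_k27 = 0, noise_sd = 0.5,
                    mutant_loss = c(), expression_samples = "WT", seed = 8)
  gn <- simulate_genome(cfg)
  chip <- simulate_chip_tracks(gn, cfg)
  v <- chip$tracks$emf1$value
  expect_false(any(chip$truth$planted_emf1))
  expect_lt(abs(mean(v)), 4 * 0.5 / sqrt(length(v)))
  expect_lt(abs(sd(v) - 0.5), 0.02)
})

test_that("complete mutant loss removes every planted domain", {
  cfg <- sim_config(genome_length = 4e5, n_chromosomes = 1, n_genes = 20,
                    frac_emf1_bound = 0, frac_k27 = 1, noise_sd = 0.5,
                    mutant_loss = c(emf1 = 1.0),
                    expression_samples = "WT", seed = 13)
  gn <- simulate_genome(cfg)
  chip <- simulate_chip_tracks(gn, cfg)
  expect_false(any(chip$truth$planted_k27_emf1))
  v <- chip$tracks$k27_emf1$value
  expect_lt(abs(mean(v)), 4 * 0.5 / sqrt(length(v)))   # noise only
  # while the WT track does carry the domains
  expect_gt(mean(chip$tracks$k27_WT$value), 0.2)
})

test_that("planted fractions are recovered within binomial noise", {
  cfg <- sim_config(genome_length = 2e6, n_chromosomes = 2, n_genes = 500,
                    frac_emf1_bound = 0.5, frac_k27 = 0.4,
                    mutant_loss = c(emf1 = 0.44), seed = 77)
  gn <- simulate_genome(cfg)
  chip <- simulate_chip_tracks(gn, cfg)
  n <- nrow(chip$truth)
  for (col_frac in list(c("planted_emf1", 0.5), c("planted_k27_wt", 0.4))) {
    f_hat <- mean(chip$truth[[col_frac[1]]])
    f <- as.numeric(col_frac[2])
    expect_lt(abs(f_hat - f), 3 * sqrt(f * (1 - f) / n) + 1 / n)
  }
  # per-mutant loss fraction among WT-marked genes
  k27 <- chip$truth$planted_k27_wt
  lost <- k27 & !chip$truth$planted_k27_emf1
  expect_lt(abs(sum(lost) / sum(k27) - 0.44),
            3 * sqrt(0.44 * 0.56 / sum(k27)) + 1 / sum(k27))
})

test_that("expression shifts land on the configured genes only", {
  shifts <- list(mut = c(G1_0001 = 2.0, G1_0002 = 2.0))
  cfg <- sim_config(genome_length = 4e5, n_chromosomes = 1, n_genes = 20,
                    mutant_loss = c(), expression_samples = c("WT", "mut"),
                    expression_shifts = shifts, noise_sd = 0.5, seed = 31)
  gn <- simulate_genome(cfg)
  ex <- simulate_expression(gn, cfg)
  expect_equal(ex$truth$mean_mut[ex$truth$gene_id == "G1_0001"], 2.0)
  expect_equal(sum(ex$truth$mean_mut != 0), 2L)
  expect_true(all(ex$truth$mean_WT == 0))
  # recovered per-gene mean close to the planted one
  sc <- transcription_score(ex$tracks$mut, gn$genes)
  g1 <- sc$score[sc$gene_id == "G1_0001"]
  n1 <- sc$n_probes[sc$gene_id == "G1_0001"]
  expect_lt(abs(g1 - 2.0), 4 * 0.5 / sqrt(n1))
  # unshifted genes center on zero
  rest <- sc$score[!sc$gene_id %in% names(shifts$mut)]
  expect_lt(abs(mean(rest)), 0.2)
})

test_that("configuration fractions are validated", {
  expect_error(sim_config(frac_k27 = 1.2), "fractions")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(probe_spacing = 0), "probe_spacing")
})
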