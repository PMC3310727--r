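#' Configuration for the synthetic tiling-array generator
#'
#' The generator emulates a NimbleGen-HD2-like experiment on a mini-genome:
#' probes every `probe_spacing` bp tile each chromosome end to end without
#' gaps, log2 ratios carry symmetric Gaussian noise, and ground-truth
#' domains are planted per gene — narrow TSS-anchored binding domains for
#' the repressor (EMF1-like) and broad gene-body domains for H3K27me3-like
#' marks that extend past the 3' end. Mutant tracks lose a configured
#' fraction of the wild-type K27 domains; expression tracks add per-gene
#' mean shifts inside gene bodies.
#'
#' Default effect sizes are set so each data type is detectable at its own
#' caller preset: the narrow binding domains at +3 sigma (a full 300-bp
#' window of 6 probes gives z around 7.3, well past p < 1e-6) and the broad
#' K27 domains at +6 sigma (z around 14.7, past the much stricter p < 1e-35
#' used for the strongly enriched broad mark).
#'
#' @param genome_length total genome size in bp, split evenly across
#'   chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param n_genes number of genes, placed non-overlapping with at least
#'   `min_gap` bp of intergenic space.
#' @param probe_spacing bp between probe centers.
#' @param noise_sd standard deviation sigma of the probe noise.
#' @param gene_length_range min/max gene length (bp), drawn uniformly.
#' @param min_gap minimum intergenic gap (bp).
#' @param frac_emf1_bound fraction of genes with a planted binding domain.
#' @param frac_k27 fraction of genes with a planted K27 domain in wild type.
#' @param co_occupancy if not `NULL`, the fraction of binding-domain genes
#'   that also get a K27 domain (planted co-occurrence); `NULL` means the
#'   two sets are drawn independently.
#' @param emf1_effect added log2 ratio inside binding domains.
#' @param emf1_length_range min/max binding-domain length (bp), anchored at
#'   the TSS and extending downstream.
#' @param k27_effect added log2 ratio inside K27 domains.
#' @param k27_upstream upstream extent of K27 domains before the TSS (bp).
#' @param k27_ext_max maximum 3' extension of K27 domains past the TES (bp).
#' @param mutant_loss named vector: per mutant, the fraction of wild-type
#'   K27-marked genes whose domain is removed in that mutant.
#' @param expression_samples sample names for expression tracks.
#' @param expression_shifts named list (one element per sample) of named
#'   numeric vectors mapping gene_id to the per-gene expression mean shift;
#'   genes not listed have mean 0.
#' @param noise_df if not `NULL`, use scaled Student-t noise with this many
#'   degrees of freedom (variance still `noise_sd^2`) to stress-test
#'   robustness to heavier tails.
#' @param seed integer random seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 4e6, n_chromosomes = 2,
                       n_genes = 1000, probe_spacing = 50, noise_sd = 0.5,
                       gene_length_range = c(800, 2000), min_gap = 2000,
                       frac_emf1_bound = 0.5, frac_k27 = 0.4,
                       co_occupancy = NULL,
                       emf1_effect = 3 * noise_sd,
                       emf1_length_range = c(300, 1000),
                       k27_effect = 6 * noise_sd,
                       k27_upstream = 200, k27_ext_max = 500,
                       mutant_loss = c(emf1 = 0.44, emf2 = 0.54, fie = 0.84),
                       expression_samples = c("WT", names(mutant_loss)),
                       expression_shifts = list(),
                       noise_df = NULL, seed = 1) {
  cfg <- list(
    genome_length = as.numeric(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    n_genes = as.integer(n_genes),
    probe_spacing = as.integer(probe_spacing),
    noise_sd = as.numeric(noise_sd),
    gene_length_range = as.numeric(gene_length_range),
    min_gap = as.numeric(min_gap),
    frac_emf1_bound = as.numeric(frac_emf1_bound),
    frac_k27 = as.numeric(frac_k27),
    co_occupancy = co_occupancy,
    emf1_effect = as.numeric(emf1_effect),
    emf1_length_range = as.numeric(emf1_length_range),
    k27_effect = as.numeric(k27_effect),
    k27_upstream = as.numeric(k27_upstream),
    k27_ext_max = as.numeric(k27_ext_max),
    mutant_loss = mutant_loss,
    expression_samples = expression_samples,
    expression_shifts = expression_shifts,
    noise_df = noise_df,
    seed = as.integer(seed)
  )
  fr <- c(cfg$frac_emf1_bound, cfg$frac_k27, cfg$mutant_loss,
          cfg$co_occupancy %||% 0)
  if (any(fr < 0 | fr > 1)) stop("all fractions must be in [0, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$probe_spacing < 1) stop("probe_spacing must be >= 1")
  if (is.null(names(cfg$mutant_loss)) && length(cfg$mutant_loss)) {
    stop("mutant_loss must be a named vector")
  }
  class(cfg) <- "sim_config"
  cfg
}

# derive a per-stage seed below 2^31 from the master seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Simulate a mini-genome annotation and probe grid
#'
#' Places `n_genes` non-overlapping genes (random strands, lengths uniform
#' in `gene_length_range`) across the chromosomes with at least `min_gap`
#' bp between them, and lays a gapless probe grid at `probe_spacing`.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with `genes` (a [gene_models()] table), `probes`
#'   (data frame of `chrom`, `pos`), and `chrom_sizes` (named vector).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genome"))
  chrom_len <- floor(config$genome_length / config$n_chromosomes)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  n_per <- diff(floor(seq(0, config$n_genes,
                          length.out = config$n_chromosomes + 1)))
  genes <- list()
  for (ci in seq_along(chroms)) {
    n <- n_per[ci]
    if (n == 0L) next
    len <- round(stats::runif(n, config$gene_length_range[1],
                              config$gene_length_range[2]))
    needed <- sum(len) + (n + 1) * config$min_gap
    if (needed > chrom_len) {
      stop("infeasible packing: ", n, " genes need ", needed,
           " bp on a ", chrom_len, " bp chromosome ",
           "(reduce n_genes or gene lengths, or grow the genome)")
    }
    w <- stats::runif(n + 1)
    extra <- floor((chrom_len - needed) * w / sum(w))
    gaps <- config$min_gap + extra
    starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, len[-n]))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    genes[[ci]] <- data.frame(
      gene_id = sprintf("G%s_%04d", sub("^chr", "", chroms[ci]), seq_len(n)),
      chrom = chroms[ci], strand = strand,
      start = as.integer(starts), end = as.integer(starts + len),
      stringsAsFactors = FALSE
    )
  }
  g <- do.call(rbind, genes)
  gm <- gene_models(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    tss = ifelse(g$strand == "+", g$start, g$end),
    tes = ifelse(g$strand == "+", g$end, g$start)
  )
  probes <- do.call(rbind, lapply(chroms, function(cc) {
    data.frame(chrom = cc,
               pos = as.integer(seq(0, chrom_len - 1, config$probe_spacing)),
               stringsAsFactors = FALSE)
  }))
  chrom_sizes <- stats::setNames(rep(chrom_len, length(chroms)), chroms)
  list(genes = gm, probes = probes, chrom_sizes = chrom_sizes)
}

# noise vector under the configured model
sim_noise <- function(n, config) {
  if (is.null(config$noise_df)) {
    stats::rnorm(n, 0, config$noise_sd)
  } else {
    df <- config$noise_df
    stats::rt(n, df) * config$noise_sd / sqrt(df / (df - 2))
  }
}

# add `effect` to probes falling in [s, e) on `chrom`; the probe grid is
# regular so membership is index arithmetic, not a scan
add_domain_effect <- function(values, probes_by_chrom, spacing, chrom,
                              s, e, effect) {
  info <- probes_by_chrom[[chrom]]
  s <- max(s, 0); e <- min(e, info$size)
  if (e <= s) return(values)
  i0 <- ceiling(s / spacing)
  i1 <- ceiling(e / spacing) - 1
  i1 <- min(i1, info$n - 1L)
  if (i1 < i0) return(values)
  idx <- info$offset + (i0:i1) + 1L
  values[idx] <- values[idx] + effect
  values
}

# strand-aware planted domain spans
emf1_domain_span <- function(gene, len) {
  if (gene$strand == "+") c(gene$tss, gene$tss + len)
  else c(gene$tss - len, gene$tss)
}

k27_domain_span <- function(gene, upstream, ext) {
  if (gene$strand == "+") c(gene$tss - upstream, gene$tes + ext)
  else c(gene$tes - ext, gene$tss + upstream)
}

probe_grid_index <- function(genome) {
  chroms <- names(genome$chrom_sizes)
  n_per <- vapply(chroms, function(cc) sum(genome$probes$chrom == cc),
                  integer(1))
  offs <- cumsum(c(0L, utils::head(n_per, -1)))
  stats::setNames(lapply(seq_along(chroms), function(i) {
    list(offset = offs[i], n = n_per[i],
         size = unname(genome$chrom_sizes[chroms[i]]))
  }), chroms)
}

#' Simulate ChIP tracks with planted domains and full ground truth
#'
#' Produces one binding (EMF1-like IP) track, one wild-type K27 track and
#' one K27 track per mutant in `config$mutant_loss`. Baseline probe values
#' are Normal(0, `noise_sd`); probes inside a planted domain get the
#' domain's effect added. Each track draws its own noise, reproducibly
#' derived from `seed`.
#'
#' @param genome output of [simulate_genome()].
#' @param config a [sim_config()].
#' @param seed seed for this stage; defaults to `config$seed`.
#' @return A list with `tracks` (named list of [probe_track()]s: `emf1`,
#'   `k27_WT`, `k27_<mutant>`...) and `truth` (data frame with per-gene
#'   `planted_emf1`, `planted_k27_wt` and `planted_k27_<mutant>` flags,
#'   where the mutant flag records whether the domain is still present).
#' @export
simulate_chip_tracks <- function(genome, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(seed, "chip"))
  g <- genome$genes
  n <- nrow(g)
  mutants <- names(config$mutant_loss)

  emf1_idx <- sort(sample.int(n, round(config$frac_emf1_bound * n)))
  n_k27 <- round(config$frac_k27 * n)
  if (is.null(config$co_occupancy)) {
    k27_idx <- sort(sample.int(n, n_k27))
  } else {
    n_in <- min(round(config$co_occupancy * length(emf1_idx)), n_k27)
    rest <- setdiff(seq_len(n), emf1_idx)
    n_out <- min(n_k27 - n_in, length(rest))
    k27_idx <- sort(c(sample(emf1_idx, n_in), sample(rest, n_out)))
  }
  emf1_len <- round(stats::runif(length(emf1_idx),
                                 config$emf1_length_range[1],
                                 config$emf1_length_range[2]))
  k27_ext <- round(stats::runif(length(k27_idx), 0, config$k27_ext_max))
  lost <- lapply(mutants, function(m) {
    k <- round(config$mutant_loss[[m]] * length(k27_idx))
    sort(sample(k27_idx, k))
  })
  names(lost) <- mutants

  grid <- probe_grid_index(genome)
  np <- nrow(genome$probes)
  spacing <- config$probe_spacing

  plant <- function(idx, spans, effect) {
    v <- sim_noise(np, config)
    for (j in seq_along(idx)) {
      gene <- g[idx[j], ]
      v <- add_domain_effect(v, grid, spacing, gene$chrom,
                             spans[[j]][1], spans[[j]][2], effect)
    }
    v
  }

  emf1_spans <- lapply(seq_along(emf1_idx), function(j)
    emf1_domain_span(g[emf1_idx[j], ], emf1_len[j]))
  k27_spans <- lapply(seq_along(k27_idx), function(j)
    k27_domain_span(g[k27_idx[j], ], config$k27_upstream, k27_ext[j]))

  tracks <- list()
  tracks$emf1 <- probe_track(genome$probes$chrom, genome$probes$pos,
                             plant(emf1_idx, emf1_spans, config$emf1_effect),
                             label = "EMF1_IP", sort = FALSE)
  tracks$k27_WT <- probe_track(genome$probes$chrom, genome$probes$pos,
                               plant(k27_idx, k27_spans, config$k27_effect),
                               label = "K27_WT", sort = FALSE)
  for (m in mutants) {
    keep <- !(k27_idx %in% lost[[m]])
    tracks[[paste0("k27_", m)]] <- probe_track(
      genome$probes$chrom, genome$probes$pos,
      plant(k27_idx[keep], k27_spans[keep], config$k27_effect),
      label = paste0("K27_", m), sort = FALSE)
  }

  truth <- data.frame(gene_id = g$gene_id,
                      planted_emf1 = seq_len(n) %in% emf1_idx,
                      planted_k27_wt = seq_len(n) %in% k27_idx,
                      stringsAsFactors = FALSE)
  for (m in mutants) {
    truth[[paste0("planted_k27_", m)]] <-
      truth$planted_k27_wt & !(seq_len(n) %in% lost[[m]])
  }
  list(tracks = tracks, truth = truth)
}

#' Simulate expression tracks (log2 cDNA/genomic DNA)
#'
#' Probe values inside a gene body equal that gene's per-sample mean plus
#' noise; intergenic probes are pure noise. Per-gene means come from
#' `config$expression_shifts` (absent genes have mean 0).
#'
#' @param genome output of [simulate_genome()].
#' @param config a [sim_config()].
#' @param seed seed for this stage; defaults to `config$seed`.
#' @return A list with `tracks` (named list of [probe_track()]s, one per
#'   sample in `config$expression_samples`) and `truth` (data frame of
#'   per-gene planted means, one `mean_<sample>` column per sample).
#' @export
simulate_expression <- function(genome, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(seed, "expression"))
  g <- genome$genes
  span <- gene_body_span(g)
  grid <- probe_grid_index(genome)
  np <- nrow(genome$probes)
  spacing <- config$probe_spacing

  truth <- data.frame(gene_id = g$gene_id, stringsAsFactors = FALSE)
  tracks <- list()
  for (s in config$expression_samples) {
    shifts <- config$expression_shifts[[s]]
    mu <- stats::setNames(rep(0, nrow(g)), g$gene_id)
    if (!is.null(shifts)) mu[names(shifts)] <- mu[names(shifts)] + shifts
    v <- sim_noise(np, config)
    for (i in seq_len(nrow(g))) {
      if (mu[i] != 0) {
        v <- add_domain_effect(v, grid, spacing, span$chrom[i],
                               span$start[i], span$end[i], mu[i])
      }
    }
    tracks[[s]] <- probe_track(genome$probes$chrom, genome$probes$pos, v,
                               label = paste0("expr_", s), sort = FALSE)
    truth[[paste0("mean_", s)]] <- unname(mu)
  }
  list(tracks = tracks, truth = truth)
}
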