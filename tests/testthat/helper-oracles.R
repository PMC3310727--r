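# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the code paths (and, where possible, the
# library calls) they are checking.

# direct per-window probe averaging: loop over windows, subset, mean
bf_window_scan <- function(trk, window_size, step_size, sigma,
                           chrom_sizes = NULL) {
  out <- list()
  for (cc in unique(trk$chrom)) {
    tc <- trk[trk$chrom == cc, ]
    size <- if (!is.null(chrom_sizes)) chrom_sizes[[cc]] else max(tc$pos) + 1
    starts <- seq(0, size - 1, by = step_size)
    for (s in starts) {
      in_w <- tc$pos >= s & tc$pos < s + window_size
      n <- sum(in_w)
      mv <- if (n > 0) mean(tc$value[in_w]) else NA_real_
      lp <- if (n > 0) {
        stats::pnorm(mv * sqrt(n) / sigma, lower.tail = FALSE,
                     log.p = TRUE) / log(10)
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(chrom = cc, start = s,
                                           n_probes = n, mean_value = mv,
                                           log10_p = lp)
    }
  }
  do.call(rbind, out)
}

# quadratic peak-to-gene overlap check
bf_assign <- function(peaks, genes, upstream = 200) {
  pairs <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      if (genes$strand[j] == "+") {
        gs <- max(genes$tss[j] - upstream, 0); ge <- genes$tes[j]
      } else {
        gs <- genes$tes[j]; ge <- genes$tss[j] + upstream
      }
      if (peaks$start[i] < ge && gs < peaks$end[i]) {
        pairs[[length(pairs) + 1]] <- c(genes$gene_id[j], i)
      }
    }
  }
  if (!length(pairs)) {
    return(data.frame(gene_id = character(), peak = integer()))
  }
  m <- do.call(rbind, pairs)
  data.frame(gene_id = m[, 1], peak = as.integer(m[, 2]),
             stringsAsFactors = FALSE)
}

# per-gene metagene binning by explicit loop over probes
bf_metagene_row <- function(trk, gene, anchor, flank, bin) {
  nb <- 2 * flank / bin
  row <- rep(NA_real_, nb)
  tc <- trk[trk$chrom == gene$chrom, ]
  a <- if (anchor == "TSS") gene$tss else gene$tes
  off <- if (gene$strand == "+") tc$pos - a else a - tc$pos
  keep <- off >= -flank & off < flank
  if (!any(keep)) return(row)
  bi <- floor((off[keep] + flank) / bin) + 1
  v <- tc$value[keep]
  for (b in unique(bi)) row[b] <- mean(v[bi == b])
  row
}

# upper-tail log10 p from enumerated log masses: when the lower tail is the
# small side, 1 - lower via log1p keeps near-1 p accurate too
tail_log10_from_masses <- function(lt_all, from) {
  upper <- lt_all[from:length(lt_all)]
  lower <- if (from > 1) lt_all[1:(from - 1)] else numeric(0)
  lower_sum <- sum(exp(lower))
  if (length(lower) && lower_sum < 0.5) {
    log1p(-lower_sum) / log(10)
  } else {
    m <- max(upper)
    (m + log(sum(exp(upper - m)))) / log(10)
  }
}

# hypergeometric upper tail by explicit enumeration (no phyper)
bf_hyper_log10 <- function(k, K, N, n) {
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  if (k > hi) return(-Inf)
  kk <- lo:hi
  lt <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  tail_log10_from_masses(lt, which(kk == max(k, lo)))
}

# Poisson upper tail by direct mass summation (no ppois)
bf_pois_log10 <- function(k, lambda) {
  if (k <= 0) return(0)
  kmax <- max(k, ceiling(lambda)) + 2000
  kk <- 0:kmax
  lt <- -lambda + kk * log(lambda) - lgamma(kk + 1)
  tail_log10_from_masses(lt, k + 1L)
}

# small synthetic fixtures ------------------------------------------------

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                         seed = 1) {
  set.seed(seed)
  cc <- sample(chroms, n, replace = TRUE)
  # keep per-chromosome peaks disjoint, as the Peak invariant requires
  out <- do.call(rbind, lapply(split(seq_len(n), cc), function(idx) {
    m <- length(idx)
    starts <- sort(sample.int(max_pos - 2000, m))
    width <- sample(100:900, m, replace = TRUE)
    ends <- pmin(starts + width, c(starts[-1], max_pos))
    data.frame(chrom = cc[idx[1]], start = starts, end = ends)
  }))
  out <- out[out$end > out$start, ]
  peaks_table(out$chrom, out$start, out$end,
              log10_p = -stats::runif(nrow(out), 1, 250),
              summit_score = stats::rnorm(nrow(out), 2, 0.5))
}

random_genes <- function(n, chrom_len = 1e6, chrom = "chr1", seed = 1,
                         min_len = 500, max_len = 3000) {
  set.seed(seed)
  starts <- sort(sample.int(chrom_len - max_len - 1000, n))
  len <- sample(min_len:max_len, n, replace = TRUE)
  ends <- pmin(starts + len, c(starts[-1] - 1, chrom_len))
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  strand <- sample(c("+", "-"), length(starts), replace = TRUE)
  gene_models(
    gene_id = sprintf("g%03d", seq_along(starts)),
    chrom = chrom, strand = strand,
    tss = ifelse(strand == "+", starts, ends),
    tes = ifelse(strand == "+", ends, starts)
  )
}

noise_track <- function(n = 1000, sd = 0.5, chrom = "chr1", spacing = 50,
                        seed = 1, label = "noise") {
  set.seed(seed)
  probe_track(rep(chrom, n), seq(0, by = spacing, length.out = n),
              stats::rnorm(n, 0, sd), label = label, sort = FALSE)
}

# metagene matrix object built directly from a values matrix
make_metagene <- function(values, anchor = "TSS", flank = 3000, bin = 100) {
  nb <- 2 * flank / bin
  stopifnot(ncol(values) == nb)
  colnames(values) <- seq(-flank + bin / 2, flank - bin / 2, by = bin)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%04d", seq_len(nrow(values)))
  }
  structure(list(values = values, anchor = anchor, flank = flank,
                 bin = bin, cluster_labels = NULL, sort_order = NULL),
            class = "metagene_matrix")
}
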