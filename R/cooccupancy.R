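#' Score per-gene reduced methylation in a mutant
#'
#' For genes K27-marked in wild type, decides whether the mark is reduced
#' in a mutant. Default `peak_loss` mode: a gene is reduced iff no mutant
#' K27 peak (called at the same preset) overlaps its search interval —
#' peak presence/absence being the construct the pipeline makes available
#' genome-wide. The `signal_drop` alternative instead requires the mean
#' gene-body signal to fall by more than a fraction `delta` of the
#' wild-type gene-body mean (only defined where that mean is positive).
#'
#' @param wt_peaks wild-type K27 [peaks_table()].
#' @param mutant_peaks mutant K27 [peaks_table()].
#' @param genes a [gene_models()] data frame.
#' @param mode `"peak_loss"` (default) or `"signal_drop"`.
#' @param gene_ids genes to score; must be K27-marked in wild type
#'   (default: all wild-type-marked genes). Asking about an unmarked gene
#'   is an error — the question is undefined for it.
#' @param upstream flank for the search interval (bp).
#' @param chrom_sizes optional chromosome lengths.
#' @param wt_track,mutant_track probe tracks, required for `signal_drop`.
#' @param delta fractional signal drop required in `signal_drop` mode.
#' @return Named logical vector over `gene_ids`: `TRUE` = reduced.
#' @export
reduced_methylation <- function(wt_peaks, mutant_peaks, genes,
                                mode = c("peak_loss", "signal_drop"),
                                gene_ids = NULL, upstream = 200,
                                chrom_sizes = NULL,
                                wt_track = NULL, mutant_track = NULL,
                                delta = 0.5) {
  mode <- match.arg(mode)
  wt_marked <- assign_peaks_to_genes(wt_peaks, genes, upstream,
                                     chrom_sizes)$bound_genes
  if (is.null(gene_ids)) {
    gene_ids <- wt_marked
  } else {
    bad <- setdiff(gene_ids, wt_marked)
    if (length(bad)) {
      stop("not K27-marked in WT (reduced methylation undefined): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (mode == "peak_loss") {
    mut_marked <- assign_peaks_to_genes(mutant_peaks, genes, upstream,
                                        chrom_sizes)$bound_genes
    out <- !(gene_ids %in% mut_marked)
  } else {
    if (is.null(wt_track) || is.null(mutant_track)) {
      stop("signal_drop mode needs wt_track and mutant_track")
    }
    sub <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]
    wt_mean <- transcription_score(wt_track, sub)$score
    mut_mean <- transcription_score(mutant_track, sub)$score
    out <- !is.na(wt_mean) & wt_mean > 0 & !is.na(mut_mean) &
      (mut_mean < (1 - delta) * wt_mean)
  }
  stats::setNames(out, gene_ids)
}

#' Classify genes by repressor binding and K27 status
#'
#' The headline partition: `EMF1_K27` genes (bound and marked) split into
#' Group I (mark reduced in the repressor mutant — the repressor-dependent
#' K27 genes) and Group II (mark retained); bound-but-unmarked genes are
#' `EMF1_no_K27`; marked-but-unbound genes are `K27_only`; everything else
#' `none`. Group I and II partition the EMF1_K27 set, and EMF1_K27 plus
#' EMF1_no_K27 partition the bound set.
#'
#' @param emf1_bound,k27_wt character vectors of gene ids.
#' @param reduced_in_emf1 gene ids with reduced K27 in the repressor
#'   mutant; must be a subset of `k27_wt`.
#' @param universe all gene ids under consideration.
#' @return A data frame (one row per universe gene): `gene_id`,
#'   `emf1_bound`, `k27_wt`, `group` with levels `EMF1_K27_groupI`,
#'   `EMF1_K27_groupII`, `EMF1_no_K27`, `K27_only`, `none`.
#' @export
classify_genes <- function(emf1_bound, k27_wt, reduced_in_emf1, universe) {
  if (anyDuplicated(universe)) stop("universe contains duplicates")
  for (nm in c("emf1_bound", "k27_wt", "reduced_in_emf1")) {
    s <- get(nm)
    out <- setdiff(s, universe)
    if (length(out)) {
      stop(nm, " not a subset of the universe: ",
           paste(utils::head(out, 5), collapse = ", "))
    }
  }
  bad <- setdiff(reduced_in_emf1, k27_wt)
  if (length(bad)) {
    stop("reduced_in_emf1 must be a subset of k27_wt; offending: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  b <- universe %in% emf1_bound
  k <- universe %in% k27_wt
  r <- universe %in% reduced_in_emf1
  group <- rep("none", length(universe))
  group[b & k & r] <- "EMF1_K27_groupI"
  group[b & k & !r] <- "EMF1_K27_groupII"
  group[b & !k] <- "EMF1_no_K27"
  group[!b & k] <- "K27_only"
  data.frame(gene_id = universe, emf1_bound = b, k27_wt = k,
             group = factor(group, levels = c("EMF1_K27_groupI",
                                              "EMF1_K27_groupII",
                                              "EMF1_no_K27", "K27_only",
                                              "none")),
             stringsAsFactors = FALSE)
}

#' One-sided Fisher overlap test between two gene sets
#'
#' Enrichment p-value for the observed overlap: the hypergeometric upper
#' tail P(X >= overlap) with population `|universe|`, `|set_b|` successes
#' and `|set_a|` draws, computed in log space so overlaps far below double
#' underflow remain representable as `log10_p`.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe the background gene set (recorded in the result; the
#'   choice of background matters and is deliberately explicit).
#' @return A list: `universe_size`, `size_a`, `size_b`, `overlap`,
#'   `expected_overlap`, `p_value`, `log10_p`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  for (s in list(a = set_a, b = set_b)) {
    if (length(setdiff(s, universe))) stop("sets must be within the universe")
  }
  N <- length(universe); n <- length(set_a); K <- length(set_b)
  k <- length(intersect(set_a, set_b))
  log_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                         log.p = TRUE)
  list(universe_size = N, size_a = n, size_b = K, overlap = k,
       expected_overlap = n * K / N,
       p_value = exp(log_p), log10_p = log_p / log(10))
}

#' Three-set Venn region counts
#'
#' Counts the 7 regions of a three-set Venn diagram plus, for each set A,
#' the conditional triple-overlap fraction `|A & B & C| / |A|` (the
#' "fraction of A's genes also reduced in both other mutants" statistic).
#'
#' @param sets named list of exactly three character vectors.
#' @return A list: `sizes`, `regions` (named counts: `a_only`, `b_only`,
#'   `c_only`, `ab`, `ac`, `bc`, `abc`), `conditional_triple` (named
#'   fractions, `NA` for an empty set).
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3L)
  if (is.null(names(sets))) names(sets) <- c("A", "B", "C")
  a <- unique(sets[[1]]); b <- unique(sets[[2]]); c <- unique(sets[[3]])
  all_g <- unique(c(a, b, c))
  ina <- all_g %in% a; inb <- all_g %in% b; inc <- all_g %in% c
  regions <- c(
    a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc),
    bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc)
  )
  triple <- regions[["abc"]]
  sizes <- vapply(list(a, b, c), length, integer(1))
  cond <- ifelse(sizes > 0, triple / sizes, NA_real_)
  names(cond) <- names(sets)
  names(sizes) <- names(sets)
  list(sizes = sizes, regions = regions, conditional_triple = cond)
}
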