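#' Poisson tail p-value for category over-representation
#'
#' Models the category count in a gene group as Poisson with
#' `lambda = group_size * genome_fraction` and returns the upper tail
#' P(X >= group_count), computed in log space.
#'
#' @param group_count observed genes of the category in the group.
#' @param group_size number of genes in the group (> 0).
#' @param genome_fraction genome-wide fraction of the category, in (0, 1).
#'   A zero fraction with a positive count is degenerate: p = 0 with a
#'   warning.
#' @return A list: `p_value`, `log10_p`, `lambda`.
#' @export
poisson_enrichment <- function(group_count, group_size, genome_fraction) {
  if (group_size <= 0) stop("group_size must be > 0")
  if (genome_fraction < 0 || genome_fraction >= 1) {
    stop("genome_fraction must be in [0, 1)")
  }
  lambda <- group_size * genome_fraction
  if (genome_fraction == 0) {
    if (group_count > 0) {
      warning("genome_fraction = 0 with a positive count: degenerate p = 0")
      return(list(p_value = 0, log10_p = -Inf, lambda = 0))
    }
    return(list(p_value = 1, log10_p = 0, lambda = 0))
  }
  log_p <- stats::ppois(group_count - 1, lambda, lower.tail = FALSE,
                        log.p = TRUE)
  list(p_value = exp(log_p), log10_p = log_p / log(10), lambda = lambda)
}

#' Fisher (hypergeometric) p-value for category over-representation
#'
#' One-sided upper tail P(X >= group_count) drawing `group_size` genes
#' from a genome of `genome_size` containing `genome_count` category
#' members — the same engine as [fisher_overlap()], on count margins.
#'
#' @param group_count category members observed in the group.
#' @param group_size group size.
#' @param genome_count category members in the genome.
#' @param genome_size genome (universe) size.
#' @return A list: `p_value`, `log10_p`, `expected`.
#' @export
fisher_enrichment <- function(group_count, group_size, genome_count,
                              genome_size) {
  if (genome_size <= 0) stop("genome_size must be > 0")
  if (group_size > genome_size || genome_count > genome_size ||
      group_count > min(group_size, genome_count)) {
    stop("inconsistent counts (group must be within the genome)")
  }
  log_p <- stats::phyper(group_count - 1, genome_count,
                         genome_size - genome_count, group_size,
                         lower.tail = FALSE, log.p = TRUE)
  list(p_value = exp(log_p), log10_p = log_p / log(10),
       expected = group_size * genome_count / genome_size)
}

#' Category over-representation table for a gene group
#'
#' One row per category in the annotation map: genome and group counts and
#' fractions, the expected count under no association, and an enrichment
#' p-value — Poisson tail for ordinary categories, Fisher's exact test
#' when the expected count is small (below `small_category_threshold`),
#' where the Poisson approximation is least trustworthy. Raw p-values are
#' reported (single-table usage); a Benjamini-Hochberg column is added for
#' convenience.
#'
#' @param group character vector of gene ids, a subset of `universe`.
#' @param annotation data frame `gene_id`, `category` (a multimap; see
#'   [read_annotation_map()]). Genes outside the universe are ignored.
#' @param universe background gene ids.
#' @param small_category_threshold expected-count switch-over to Fisher.
#' @return Data frame sorted by p: `category`, `genome_count`,
#'   `genome_fraction`, `group_count`, `group_fraction`, `expected`,
#'   `p_value`, `log10_p`, `test_used`, `p_adjust_bh`.
#' @export
enrichment_table <- function(group, annotation, universe,
                             small_category_threshold = 5) {
  if (is.null(annotation) || nrow(annotation) == 0L) {
    stop("empty annotation map")
  }
  stopifnot(all(c("gene_id", "category") %in% names(annotation)))
  universe <- unique(universe)
  group <- unique(group)
  out <- setdiff(group, universe)
  if (length(out)) {
    stop("group genes outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  }
  ann <- unique(annotation[annotation$gene_id %in% universe, ,
                           drop = FALSE])
  if (nrow(ann) == 0L) stop("annotation covers no universe gene")
  N <- length(universe)
  n <- length(group)
  cats <- sort(unique(ann$category))
  genome_count <- vapply(split(ann$gene_id, ann$category)[cats],
                         function(g) length(unique(g)), integer(1))
  in_group <- ann[ann$gene_id %in% group, , drop = FALSE]
  group_count <- vapply(cats, function(cc) {
    length(unique(in_group$gene_id[in_group$category == cc]))
  }, integer(1))
  genome_fraction <- genome_count / N
  expected <- n * genome_fraction
  test_used <- ifelse(expected < small_category_threshold,
                      "fisher", "poisson")
  log10_p <- numeric(length(cats))
  for (i in seq_along(cats)) {
    log10_p[i] <- if (test_used[i] == "fisher") {
      fisher_enrichment(group_count[i], n, genome_count[i], N)$log10_p
    } else {
      poisson_enrichment(group_count[i], n, genome_fraction[i])$log10_p
    }
  }
  p <- 10^log10_p
  tab <- data.frame(
    category = cats,
    genome_count = unname(genome_count),
    genome_fraction = unname(genome_fraction),
    group_count = unname(group_count),
    group_fraction = unname(group_count) / n,
    expected = unname(expected),
    p_value = p,
    log10_p = log10_p,
    test_used = test_used,
    p_adjust_bh = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$log10_p), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
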