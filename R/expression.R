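#' Median-normalize an expression track
#'
#' Subtracts the array-wide median from every probe value so the track
#' median is zero (to machine precision). Idempotent.
#'
#' @param trk a non-empty [probe_track()] of log2(cDNA/gDNA) values.
#' @return The normalized track.
#' @export
normalize_expression <- function(trk) {
  validate_probe_track(trk)
  if (nrow(trk) == 0L) stop("cannot normalize an empty track")
  trk$value <- trk$value - stats::median(trk$value)
  trk
}

#' Per-gene transcription scores
#'
#' The transcription score of a gene is the mean of the median-normalized
#' probe values whose centers fall in the gene body (the strand-resolved
#' genomic span `[TSS, TES)`). Genes with no in-body probes get `NA`.
#'
#' @param trk a normalized [probe_track()].
#' @param genes a [gene_models()] data frame.
#' @param aggregate `"mean"` (default) or `"median"` probe aggregation.
#' @return Data frame `gene_id`, `score`, `n_probes`.
#' @export
transcription_score <- function(trk, genes, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  validate_probe_track(trk)
  validate_gene_models(genes)
  span <- gene_body_span(genes)
  by_chrom <- split(seq_len(nrow(trk)), trk$chrom)
  score <- rep(NA_real_, nrow(genes))
  np <- integer(nrow(genes))
  agg <- if (aggregate == "mean") mean else stats::median
  for (i in seq_len(nrow(genes))) {
    idx <- by_chrom[[span$chrom[i]]]
    if (is.null(idx)) next
    pos <- trk$pos[idx]
    lo <- findInterval(span$start[i] - 1, pos) + 1
    hi <- findInterval(span$end[i] - 1, pos)
    if (hi < lo) next
    score[i] <- agg(trk$value[idx][lo:hi])
    np[i] <- hi - lo + 1L
  }
  data.frame(gene_id = genes$gene_id, score = score, n_probes = np,
             stringsAsFactors = FALSE)
}

#' Average transcription score of a gene set
#'
#' @param scores output of [transcription_score()] (or any data frame with
#'   `gene_id` and `score`).
#' @param gene_set character vector of gene ids (duplicates ignored).
#' @return Mean over the non-missing scores of the set.
#' @export
category_average_score <- function(scores, gene_set) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0L) stop("empty gene set")
  s <- scores$score[match(gene_set, scores$gene_id)]
  if (all(is.na(s))) stop("no scored genes in the set")
  mean(s, na.rm = TRUE)
}

#' Differential-expression calls from mutant vs wild-type scores
#'
#' Per gene, `delta = score_mutant - score_wt`; the reference spread
#' `sd_ref` is the standard deviation of delta over all genes scored in
#' both samples, and a gene is called `up` when
#' `delta > sd_multiple * sd_ref`, `down` when below the negative
#' threshold, `unchanged` otherwise (the +/-1.5 sd rule by default).
#'
#' @param scores_wt,scores_mutant outputs of [transcription_score()] over
#'   the same genes.
#' @param sd_multiple cutoff in units of `sd_ref` (default 1.5).
#' @param sd_ref optional override of the reference spread (e.g. a
#'   per-probe-derived value); computed from the per-gene deltas when
#'   `NULL`.
#' @return A list: `calls` (data frame `gene_id`, `score_wt`,
#'   `score_mutant`, `delta`, `call`), `sd_ref`, and the `up`, `down`,
#'   `unchanged` gene-id vectors (a partition of the genes scored in both
#'   samples).
#' @export
differential_genes <- function(scores_wt, scores_mutant, sd_multiple = 1.5,
                               sd_ref = NULL) {
  m <- merge(scores_wt[, c("gene_id", "score")],
             scores_mutant[, c("gene_id", "score")],
             by = "gene_id", suffixes = c("_wt", "_mutant"))
  m <- m[match(scores_wt$gene_id[scores_wt$gene_id %in% m$gene_id],
               m$gene_id), , drop = FALSE]
  names(m) <- c("gene_id", "score_wt", "score_mutant")
  m$delta <- m$score_mutant - m$score_wt
  ok <- !is.na(m$delta)
  if (sum(ok) < 2L) stop("need >= 2 genes scored in both samples")
  if (is.null(sd_ref)) sd_ref <- stats::sd(m$delta[ok])
  m$call <- NA_character_
  if (sd_ref == 0) {
    warning("sd_ref is 0 (identical scores): all genes called unchanged")
    m$call[ok] <- "unchanged"
  } else {
    m$call[ok] <- ifelse(m$delta[ok] > sd_multiple * sd_ref, "up",
                         ifelse(m$delta[ok] < -sd_multiple * sd_ref,
                                "down", "unchanged"))
  }
  rownames(m) <- NULL
  list(calls = m, sd_ref = sd_ref,
       up = m$gene_id[ok & m$call == "up"],
       down = m$gene_id[ok & m$call == "down"],
       unchanged = m$gene_id[ok & m$call == "unchanged"])
}
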