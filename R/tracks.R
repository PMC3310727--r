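#' Construct a probe-level signal track
#'
#' A probe track is the universal signal carrier of the pipeline: an ordered
#' set of (chromosome, probe position, log2 ratio) triples, as produced by a
#' tiling array. Positions are 0-based probe centers. Within each chromosome
#' positions are strictly increasing; all values are finite.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based probe center positions.
#' @param value numeric vector of log2 ratios, one per probe.
#' @param label free-text sample/antibody label.
#' @param sort sort probes by (chrom, pos) before validation. Input files are
#'   not required to be position-sorted, so this defaults to `TRUE`.
#' @return A `probe_track`: a data frame with columns `chrom`, `pos`, `value`
#'   and a `label` attribute.
#' @export
probe_track <- function(chrom, pos, value, label = "", sort = TRUE) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(value))
  trk <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  if (sort) trk <- trk[order(trk$chrom, trk$pos), , drop = FALSE]
  rownames(trk) <- NULL
  attr(trk, "label") <- label
  class(trk) <- c("probe_track", "data.frame")
  validate_probe_track(trk)
  trk
}

#' Validate probe-track invariants
#'
#' Checks strictly increasing positions per chromosome, finite values and
#' non-negative positions. Called by the constructor and the readers.
#'
#' @param trk a `probe_track`.
#' @return `trk`, invisibly, or an error.
#' @export
validate_probe_track <- function(trk) {
  stopifnot(all(c("chrom", "pos", "value") %in% names(trk)))
  if (nrow(trk) == 0L) return(invisible(trk))
  if (any(trk$pos < 0L)) stop("probe positions must be non-negative")
  if (any(!is.finite(trk$value))) stop("probe values must be finite")
  d <- unlist(lapply(split(trk$pos, trk$chrom), diff), use.names = FALSE)
  if (length(d) && any(d <= 0L)) {
    stop("probe positions must be strictly increasing within a chromosome ",
         "(overlapping duplicate positions?)")
  }
  invisible(trk)
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("probe_track '%s': %d probes on %d chromosome(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom))))
  NextMethod()
}

track_label <- function(trk) attr(trk, "label") %||% ""

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median-center a track
#'
#' Subtracts the array-wide median so the log2 ratios are centered on zero,
#' the precondition of the Gaussian background model and of median
#' normalization of expression arrays. Idempotent.
#'
#' @param trk a `probe_track`.
#' @return The centered `probe_track`.
#' @export
center_track <- function(trk) {
  validate_probe_track(trk)
  if (nrow(trk) == 0L) stop("cannot center an empty track")
  trk$value <- trk$value - stats::median(trk$value)
  trk
}

#' Combine replicate tracks by per-probe mean
#'
#' Utility for pre-combining biological replicate hybridizations into one
#' track before peak calling. All tracks must share an identical probe grid.
#'
#' @param ... two or more `probe_track`s on the same probes.
#' @param label label for the combined track.
#' @return A `probe_track` whose values are per-probe means.
#' @export
combine_tracks <- function(..., label = "combined") {
  trks <- list(...)
  if (length(trks) == 1L && is.list(trks[[1]]) &&
      !inherits(trks[[1]], "data.frame")) {
    trks <- trks[[1]]
  }
  if (length(trks) < 2L) stop("need at least two tracks to combine")
  ref <- trks[[1]]
  for (t in trks[-1]) {
    if (!identical(ref$chrom, t$chrom) || !identical(ref$pos, t$pos)) {
      stop("tracks must share an identical probe grid")
    }
  }
  vals <- rowMeans(do.call(cbind, lapply(trks, `[[`, "value")))
  probe_track(ref$chrom, ref$pos, vals, label = label, sort = FALSE)
}

#' Construct a gene model table
#'
#' One row per gene: chromosome, strand, transcription start (TSS) and end
#' (TES) in 0-based genomic coordinates. The TSS is always the biological
#' start, so `tss < tes` on the plus strand and `tss > tes` on the minus
#' strand.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss,tes integer transcription start/end positions (bp, 0-based).
#' @return A `gene_models` data frame with an added `length` column.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, tes) {
  g <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    tss = as.integer(tss),
    tes = as.integer(tes),
    stringsAsFactors = FALSE
  )
  g$length <- abs(g$tes - g$tss)
  class(g) <- c("gene_models", "data.frame")
  validate_gene_models(g)
  g
}

#' Validate gene-model invariants
#' @param g a `gene_models` data frame.
#' @return `g`, invisibly, or an error.
#' @export
validate_gene_models <- function(g) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "tes") %in% names(g)))
  if (anyDuplicated(g$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(g$gene_id[duplicated(g$gene_id)]), collapse = ", "))
  }
  if (!all(g$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for every gene")
  }
  bad <- (g$strand == "+" & g$tss >= g$tes) |
         (g$strand == "-" & g$tss <= g$tes)
  if (any(bad)) {
    stop("TSS/TES order inconsistent with strand for: ",
         paste(utils::head(g$gene_id[bad], 5), collapse = ", "))
  }
  invisible(g)
}

# genomic span [start, end) of the gene body, strand-resolved
gene_body_span <- function(g) {
  data.frame(
    gene_id = g$gene_id, chrom = g$chrom,
    start = pmin(g$tss, g$tes), end = pmax(g$tss, g$tes),
    stringsAsFactors = FALSE
  )
}

#' Construct a peak table
#'
#' A peak is a merged run of significant sliding windows: 0-based half-open
#' span, the minimum window p-value (kept in log10 space so values far below
#' double underflow stay representable) and the summit score (maximum window
#' mean inside the peak).
#'
#' @param chrom,start,end peak coordinates (0-based half-open).
#' @param log10_p log10 of the peak p-value (canonical representation).
#' @param summit_score maximum window mean inside the peak.
#' @return A `peaks` data frame with columns `chrom`, `start`, `end`,
#'   `log10_p`, `p_value`, `summit_score`, sorted by position.
#' @export
peaks_table <- function(chrom = character(), start = integer(),
                        end = integer(), log10_p = numeric(),
                        summit_score = numeric()) {
  p <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    log10_p = as.numeric(log10_p),
    p_value = 10^as.numeric(log10_p),
    summit_score = as.numeric(summit_score),
    stringsAsFactors = FALSE
  )
  p <- p[order(p$chrom, p$start), , drop = FALSE]
  rownames(p) <- NULL
  if (any(p$end <= p$start)) stop("peaks must have positive width")
  if (any(p$log10_p > 0)) stop("p-values must be <= 1")
  class(p) <- c("peaks", "data.frame")
  p
}

peaks_to_granges <- function(p) {
  GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end)
  )
}
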