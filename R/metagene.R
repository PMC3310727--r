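#' Build an anchor-aligned metagene matrix
#'
#' For every gene, probe offsets are computed strand-relatively around the
#' anchor (TSS or TES): upstream offsets are negative, downstream positive,
#' and minus-strand offsets are negated so transcription always runs left
#' to right. Offsets in `[-flank, flank)` are averaged into fixed-width
#' bins; bins with no probes are missing. Bins beyond a short gene's 3'
#' end are still filled from the genomic track unless `mask_short_genes`
#' is set.
#'
#' @param trk a [probe_track()].
#' @param genes a [gene_models()] data frame.
#' @param anchor `"TSS"` or `"TES"` (the 3'-end-aligned variant).
#' @param flank half-width of the window in bp (default 3000, giving the
#'   6 kb view).
#' @param bin bin width in bp (default 100, so 60 bins).
#' @param mask_short_genes if `TRUE`, bins whose whole span lies beyond the
#'   gene's far end are masked to missing.
#' @return A `metagene_matrix`: list with `values` (genes x bins matrix,
#'   column names = strand-relative bin midpoints), `anchor`, `flank`,
#'   `bin`, and empty `cluster_labels` / `sort_order` slots.
#' @export
build_metagene_matrix <- function(trk, genes, anchor = c("TSS", "TES"),
                                  flank = 3000, bin = 100,
                                  mask_short_genes = FALSE) {
  anchor <- match.arg(anchor)
  validate_probe_track(trk)
  validate_gene_models(genes)
  if ((2 * flank) %% bin != 0) stop("2*flank must be a multiple of bin")
  nb <- as.integer(2 * flank / bin)
  mids <- seq(-flank + bin / 2, flank - bin / 2, by = bin)
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = nb,
                dimnames = list(genes$gene_id, mids))
  by_chrom <- split(seq_len(nrow(trk)), trk$chrom)
  missing_chrom <- setdiff(unique(genes$chrom), names(by_chrom))
  if (length(missing_chrom)) {
    warning("no probes for chromosome(s): ",
            paste(missing_chrom, collapse = ", "),
            "; affected gene rows are all-missing")
  }
  for (i in seq_len(nrow(genes))) {
    cc <- genes$chrom[i]
    idx <- by_chrom[[cc]]
    if (is.null(idx)) next
    pos <- trk$pos[idx]
    a <- if (anchor == "TSS") genes$tss[i] else genes$tes[i]
    if (genes$strand[i] == "+") {
      sel <- (findInterval(a - flank - 1, pos) + 1):findInterval(a + flank - 1, pos)
    } else {
      sel <- (findInterval(a - flank, pos) + 1):findInterval(a + flank, pos)
    }
    if (length(sel) == 0L || sel[1] > sel[length(sel)]) next
    sel <- sel[sel >= 1]
    if (!length(sel)) next
    off <- if (genes$strand[i] == "+") pos[sel] - a else a - pos[sel]
    bi <- floor((off + flank) / bin) + 1
    keep <- bi >= 1 & bi <= nb
    if (!any(keep)) next
    m <- tapply(trk$value[idx][sel][keep], bi[keep], mean)
    mat[i, as.integer(names(m))] <- as.numeric(m)
  }
  if (mask_short_genes) {
    far <- abs(genes$tes - genes$tss)   # distance from TSS to the far end
    for (i in seq_len(nrow(genes))) {
      lim <- if (anchor == "TSS") far[i] else Inf
      mat[i, mids - bin / 2 >= lim] <- NA_real_
    }
  }
  structure(list(values = mat, anchor = anchor, flank = flank, bin = bin,
                 cluster_labels = NULL, sort_order = NULL),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("metagene_matrix: %d genes x %d bins (%s-anchored, +/-%d bp, %d bp bins)%s\n",
              nrow(x$values), ncol(x$values), x$anchor, x$flank, x$bin,
              if (is.null(x$cluster_labels)) "" else ", clustered"))
  invisible(x)
}

# bins whose midpoint lies downstream of the anchor (the gene-body side)
body_bin_cols <- function(m) which(as.numeric(colnames(m$values)) > 0)

metagene_body_means <- function(m) {
  rowMeans(m$values[, body_bin_cols(m), drop = FALSE], na.rm = TRUE)
}

#' Average metagene profile of a gene subset
#'
#' Per-bin mean over the non-missing entries of the selected rows.
#'
#' @param m a `metagene_matrix`.
#' @param genes character vector of gene ids; `NULL` means all genes.
#' @return Numeric vector, one value per bin (NA where no gene has data).
#' @export
average_profile <- function(m, genes = NULL) {
  stopifnot(inherits(m, "metagene_matrix"))
  rows <- if (is.null(genes)) rownames(m$values) else genes
  if (length(rows) == 0L) stop("empty gene subset")
  miss <- setdiff(rows, rownames(m$values))
  if (length(miss)) {
    stop("genes not in matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  v <- colMeans(m$values[rows, , drop = FALSE], na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  v
}

#' Partition genes into High/Low clusters by k-means (k = 2)
#'
#' Clusters the bin vectors with Euclidean k-means; missing entries are
#' imputed with the gene's own non-missing mean for clustering only. The
#' cluster with the larger mean gene-body signal (bins downstream of the
#' anchor) is labeled `"High"`, which makes labels reproducible across
#' seeds and input orderings. The stored sort order puts the High cluster
#' first, each cluster ordered by descending gene-body mean, so other
#' datasets can be displayed in the same order via [align_by_order()].
#'
#' @param m a `metagene_matrix` with at least 2 genes carrying data.
#' @param seed integer seed (k-means initialization).
#' @param nstart random restarts for k-means.
#' @return `m` with `cluster_labels` (named `"High"`/`"Low"` vector
#'   covering all genes) and `sort_order` filled in.
#' @export
kmeans_high_low <- function(m, seed = 1, nstart = 10) {
  stopifnot(inherits(m, "metagene_matrix"))
  x <- m$values
  has_data <- rowSums(!is.na(x)) > 0
  if (sum(has_data) < 2L) stop("need >= 2 genes with non-missing data")
  xi <- x[has_data, , drop = FALSE]
  rm_ <- rowMeans(xi, na.rm = TRUE)
  for (j in seq_len(ncol(xi))) {
    nas <- is.na(xi[, j])
    if (any(nas)) xi[nas, j] <- rm_[nas]
  }
  body <- metagene_body_means(m)
  labels <- stats::setNames(rep("Low", nrow(x)), rownames(x))
  degenerate <- all(apply(xi, 2, function(col) length(unique(col)) == 1L))
  if (degenerate) {
    warning("all rows identical: single effective cluster")
    lab <- if (mean(body[has_data], na.rm = TRUE) > 0) "High" else "Low"
    labels[has_data] <- lab
  } else {
    set.seed(seed)
    if (nrow(xi) == 2L) {           # k-means needs > k rows; split directly
      km <- list(cluster = c(1L, 2L))
    } else {
      km <- stats::kmeans(xi, centers = 2, nstart = nstart, iter.max = 100)
    }
    cl_body <- tapply(body[has_data], km$cluster, mean, na.rm = TRUE)
    high_cl <- as.integer(names(cl_body)[which.max(cl_body)])
    labels[has_data] <- ifelse(km$cluster == high_cl, "High", "Low")
  }
  ord <- order(labels != "High", -body, na.last = TRUE)
  m$cluster_labels <- labels
  m$sort_order <- rownames(x)[ord]
  m
}

#' Reorder a metagene matrix by a stored sort order
#'
#' Permutes the rows of `other` to the supplied order (typically the
#' wild-type K27 sort order), leaving values untouched, so heat maps of
#' different datasets line up gene by gene.
#'
#' @param other a `metagene_matrix` over the same gene universe.
#' @param order character vector of gene ids (a permutation of the rows).
#' @return `other` with rows permuted and `sort_order` set.
#' @export
align_by_order <- function(other, order) {
  stopifnot(inherits(other, "metagene_matrix"))
  missing <- setdiff(order, rownames(other$values))
  extra <- setdiff(rownames(other$values), order)
  if (length(missing) || length(extra)) {
    stop("gene set mismatch; missing from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "),
         "; absent from order: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  other$values <- other$values[order, , drop = FALSE]
  if (!is.null(other$cluster_labels)) {
    other$cluster_labels <- other$cluster_labels[order]
  }
  other$sort_order <- order
  other
}

#' Write a metagene matrix (and labels) as TSV
#' @param m a `metagene_matrix`.
#' @param path output path for the matrix (genes x bins, header = bin
#'   midpoints).
#' @param labels_path optional path for a `gene_id`, `cluster` table.
#' @return `path`, invisibly.
#' @export
write_metagene_matrix <- function(m, path, labels_path = NULL) {
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path) && !is.null(m$cluster_labels)) {
    lab <- data.frame(gene_id = names(m$cluster_labels),
                      cluster = unname(m$cluster_labels),
                      stringsAsFactors = FALSE)
    lab <- lab[match(m$sort_order, lab$gene_id), , drop = FALSE]
    utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
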