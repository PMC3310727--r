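#' Strand-aware gene search intervals
#'
#' The interval a peak must overlap to be assigned to a gene: from 200 bp
#' (configurable) upstream of the TSS to the 3' end of the transcribed
#' region. In genomic coordinates that is `[tss - upstream, tes)` on the
#' plus strand and `[tes, tss + upstream)` on the minus strand, clipped at
#' chromosome boundaries.
#'
#' @param genes a [gene_models()] data frame (vectorized over genes).
#' @param upstream upstream flank in bp.
#' @param chrom_sizes optional named vector for right-boundary clipping.
#' @return Data frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
gene_search_interval <- function(genes, upstream = 200, chrom_sizes = NULL) {
  validate_gene_models(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tes)
  end <- ifelse(plus, genes$tes, genes$tss + upstream)
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[genes$chrom]
    end <- pmin(end, ifelse(is.na(lim), end, lim))
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Assign peaks to genes by search-interval overlap
#'
#' A peak is genic iff it overlaps at least `min_overlap` bp of any gene's
#' search interval; it may map to several genes, and a gene is bound iff
#' at least one peak maps to it. Genic and intergenic peaks partition the
#' peak set.
#'
#' @param peaks a [peaks_table()].
#' @param genes a [gene_models()] data frame.
#' @param upstream upstream flank passed to [gene_search_interval()].
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return A list: `assignments` (data frame `gene_id`, `peak` row index
#'   into `peaks`), `bound_genes` (character vector), `genic` and
#'   `intergenic` (disjoint [peaks_table()]s).
#' @export
assign_peaks_to_genes <- function(peaks, genes, upstream = 200,
                                  chrom_sizes = NULL, min_overlap = 1L) {
  validate_gene_models(genes)
  unmatched <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(unmatched)) {
    stop("peak chromosomes absent from the annotation: ",
         paste(unmatched, collapse = ", "))
  }
  if (nrow(peaks) == 0L) {
    return(list(assignments = data.frame(gene_id = character(),
                                         peak = integer()),
                bound_genes = character(),
                genic = peaks, intergenic = peaks))
  }
  si <- gene_search_interval(genes, upstream, chrom_sizes)
  gr_g <- GenomicRanges::GRanges(si$chrom,
                                 IRanges::IRanges(si$start + 1L, si$end))
  gr_p <- peaks_to_granges(peaks)
  hits <- GenomicRanges::findOverlaps(gr_p, gr_g,
                                      minoverlap = as.integer(min_overlap))
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  genic_idx <- sort(unique(pi))
  list(
    assignments = data.frame(gene_id = si$gene_id[gi], peak = pi,
                             stringsAsFactors = FALSE),
    bound_genes = unique(si$gene_id[gi]),
    genic = peaks[genic_idx, , drop = FALSE],
    intergenic = peaks[setdiff(seq_len(nrow(peaks)), genic_idx), ,
                       drop = FALSE]
  )
}

#' Peak density per fixed-size chromosomal bin
#'
#' Counts peaks by midpoint in bins tiling each chromosome (the
#' "binding regions per 100 kb" view). A midpoint exactly on a bin
#' boundary belongs to the right-hand bin (half-open bins).
#'
#' @param peaks a [peaks_table()].
#' @param bin bin width in bp.
#' @param chrom_sizes optional named vector of chromosome lengths; defaults
#'   to the last peak end per chromosome.
#' @return Data frame `chrom`, `start`, `end`, `count`; counts sum to the
#'   number of peaks.
#' @export
chromosomal_density <- function(peaks, bin = 100000, chrom_sizes = NULL) {
  if (nrow(peaks) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), count = integer()))
  }
  mid <- floor((peaks$start + peaks$end) / 2)
  out <- lapply(split(seq_len(nrow(peaks)), peaks$chrom), function(idx) {
    cc <- peaks$chrom[idx[1]]
    size <- if (!is.null(chrom_sizes) && cc %in% names(chrom_sizes)) {
      as.numeric(chrom_sizes[[cc]])
    } else {
      max(peaks$end[idx])
    }
    nb <- ceiling(size / bin)
    cnt <- tabulate(floor(mid[idx] / bin) + 1L, nbins = nb)
    data.frame(chrom = cc,
               start = as.integer((seq_len(nb) - 1L) * bin),
               end = as.integer(pmin(seq_len(nb) * bin, size)),
               count = cnt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a density table as bedGraph
#' @param density output of [chromosomal_density()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density <- function(density, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('track type=bedGraph name="peak_density"', con)
  if (nrow(density)) {
    writeLines(paste(density$chrom, density$start, density$end,
                     density$count, sep = "\t"), con)
  }
  invisible(path)
}
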