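#' Read a probe-level signal track from bedGraph or WIG
#'
#' bedGraph intervals are collapsed to their midpoints (tiling-array data are
#' probe-centric, so each interval represents one probe); WIG records use
#' their own position. Coordinates are converted to the internal 0-based
#' convention. Probes need not be sorted in the file; they are sorted on
#' read.
#'
#' @param path file in bedGraph or fixed-step WIG format.
#' @param format `"auto"` (by extension: `.wig` is WIG, anything else
#'   bedGraph), `"bedGraph"` or `"wig"`.
#' @param label sample label attached to the track; defaults to the file
#'   base name.
#' @return A [probe_track()] covering all chromosomes in the file. An empty
#'   file yields an empty track with a warning.
#' @export
read_track <- function(path, format = c("auto", "bedGraph", "wig"),
                       label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig"
              else "bedGraph"
  }
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "bedGraph") prescan_bedgraph(path)
  gr <- rtracklayer::import(path, format = format)
  if (length(gr) == 0L) {
    warning("no probe records in ", path)
    return(probe_track(character(), integer(), numeric(), label = label))
  }
  # midpoint of the 0-based half-open interval [start-1, end)
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  mid <- as.integer(floor((start0 + end0) / 2))
  trk <- probe_track(as.character(GenomicRanges::seqnames(gr)), mid,
                     gr$score, label = label, sort = TRUE)
  trk
}

# light structural check so malformed bedGraph lines are reported with their
# line number (the importer's own errors do not carry one)
prescan_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible())
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[!skip]), "[ \t]+")
  ln <- seq_along(lines)[!skip]
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ok <- length(f) == 4L &&
      !anyNA(suppressWarnings(as.numeric(f[2:4]))) &&
      f[2] == as.character(as.integer(f[2]))
    if (!ok) {
      stop("malformed bedGraph line ", ln[i], " in ", path, ": ",
           paste(f, collapse = " "))
    }
  }
  invisible()
}

#' Write a probe track as bedGraph
#'
#' Each probe becomes a 1-bp interval `[pos, pos+1)`, so reading the file
#' back reproduces the track exactly.
#'
#' @param trk a [probe_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(trk, path) {
  validate_probe_track(trk)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', track_label(trk)), con)
  if (nrow(trk)) {
    writeLines(paste(trk$chrom, trk$pos, trk$pos + 1L,
                     formatC(trk$value, digits = 17, format = "g"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 files contribute their `gene`-type features (1-based closed
#' coordinates converted to the internal 0-based half-open convention);
#' BED12 files contribute every record. The strand decides which end is the
#' TSS: on the minus strand the TSS is the larger coordinate.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return A [gene_models()] data frame.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (length(gr) == 0L) stop("no 'gene' features in ", path)
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) ids <- gr$Name
    if (is.null(ids) || anyNA(ids)) stop("gene features need ID or Name")
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) stop("no records in ", path)
    ids <- gr$name
    if (is.null(ids) || anyNA(ids)) stop("BED records need a name column")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("missing strand for: ",
         paste(utils::head(ids[strand == "*"], 5), collapse = ", "))
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  gene_models(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = ifelse(strand == "+", start0, end0),
    tes = ifelse(strand == "+", end0, start0)
  )
}

#' Write gene models as BED12
#'
#' Single-block BED12 records; [read_gene_models()] on the output reproduces
#' the input.
#'
#' @param genes a [gene_models()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  validate_gene_models(genes)
  span <- gene_body_span(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = span$chrom,
    ranges = IRanges::IRanges(start = span$start + 1L, end = span$end),
    strand = genes$strand
  )
  gr$name <- genes$gene_id
  gr$score <- 0
  gr$thick <- IRanges::ranges(gr)
  gr$blocks <- IRanges::IRangesList(lapply(span$end - span$start,
                                           function(w) IRanges::IRanges(1L, w)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes a [gene_models()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  validate_gene_models(genes)
  span <- gene_body_span(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = span$chrom,
    ranges = IRanges::IRanges(start = span$start + 1L, end = span$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write peaks as BED6+1
#'
#' Column 5 carries `-log10(p)` capped at 1000; the extra seventh column is
#' the summit score. Scores are written at full double precision so
#' [read_peaks()] reproduces the set.
#'
#' @param peaks a [peaks_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('track name="peaks" type=bed', con)
  if (nrow(peaks)) {
    score <- pmin(-peaks$log10_p, 1000)
    writeLines(paste(peaks$chrom, peaks$start, peaks$end,
                     sprintf("peak_%d", seq_len(nrow(peaks))),
                     formatC(score, digits = 17, format = "g"), ".",
                     formatC(peaks$summit_score, digits = 17, format = "g"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read peaks from a BED6+1 file written by [write_peaks()]
#'
#' @param path input path.
#' @return A [peaks_table()].
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed",
                            extraCols = c(summit_score = "numeric"))
  if (length(gr) == 0L) {
    return(peaks_table())
  }
  peaks_table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    log10_p = -gr$score,
    summit_score = gr$summit_score
  )
}

#' Write a per-gene status table as TSV
#'
#' One row per gene, stable column order; logical flags are stored as 0/1.
#' [read_gene_table()] restores the types from the column names (`emf1_bound`,
#' `k27_*` are flags; `tx_*` numeric scores; `group` and `de_*` character).
#'
#' @param table data frame with a `gene_id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(table, path) {
  stopifnot("gene_id" %in% names(table))
  out <- as.data.frame(table)
  for (nm in names(out)) {
    if (is.logical(out[[nm]])) out[[nm]] <- as.integer(out[[nm]])
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-gene status table written by [write_gene_table()]
#' @param path input path.
#' @return A data frame with flag columns restored to logical.
#' @export
read_gene_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  flag <- grepl("^(emf1_bound|k27_)", names(out)) &
    vapply(out, is.numeric, logical(1))
  for (nm in names(out)[flag]) out[[nm]] <- as.logical(out[[nm]])
  out
}

#' Read a gene-to-category annotation map
#'
#' Two-column tab-separated file: gene identifier, category label. A gene
#' may appear on several lines (multimap). Lines starting with `#` are
#' skipped; a `gene_id<TAB>category` header row is recognized and dropped.
#'
#' @param path input path.
#' @return A data frame with columns `gene_id` and `category`.
#' @export
read_annotation_map <- function(path) {
  m <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE,
                         col.names = c("gene_id", "category"))
  if (nrow(m) && m$gene_id[1] == "gene_id") m <- m[-1, , drop = FALSE]
  if (nrow(m) == 0L) stop("empty annotation map: ", path)
  rownames(m) <- NULL
  m
}
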