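#' Read gene models from GFF3 or BED
#'
#' Parses gene intervals into the package's internal 1-based inclusive
#' convention. From GFF3 only rows with feature type `gene` are used; BED
#' intervals (0-based half-open) are shifted on import. Overlapping genes
#' are retained and tested independently downstream.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return A data.frame of class `gene_model_set` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand` and `length`, sorted by
#'   `(chrom, start, end)`.
#' @export
read_genes <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID)
           else if (!is.null(gr$Name)) as.character(gr$Name)
           else stop("GFF3 gene rows carry neither ID nor Name attributes")
  } else {
    ids <- as.character(gr$name)
    if (length(gr) && (is.null(gr$name) || anyNA(ids)))
      stop("BED input must carry a name column (BED6)")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    bad <- ids[which(!strand %in% c("+", "-"))[1L]]
    stop("unknown strand symbol for record ", bad, " (expected + or -)")
  }
  gene_model_set(gene_id = ids,
                 chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr),
                 strand = strand)
}

#' Assemble a set of gene models
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A sorted `gene_model_set` data.frame.
#' @export
gene_model_set <- function(gene_id, chrom, start, end, strand) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start > end)) {
    bad <- gene_id[which(start > end)[1L]]
    stop("start > end for record ", bad)
  }
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand symbol for record ",
         gene_id[which(!strand %in% c("+", "-"))[1L]])
  if (anyDuplicated(gene_id))
    stop("duplicated gene_id: ", gene_id[anyDuplicated(gene_id)])
  g <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  start = start, end = end, strand = as.character(strand),
                  length = end - start + 1, stringsAsFactors = FALSE)
  g <- g[order(g$chrom, g$start, g$end), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("gene_model_set", "data.frame")
  g
}

#' Write gene models as BED6
#'
#' @param genes a `gene_model_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  utils::write.table(
    data.frame(genes$chrom, format(genes$start - 1, scientific = FALSE,
                                   trim = TRUE),
               format(genes$end, scientific = FALSE, trim = TRUE),
               genes$gene_id, 0L, genes$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand-aware transcription start/end sites
#'
#' The TSS is the leftmost coordinate of a `+` gene and the rightmost of a
#' `-` gene; the TES is the opposite border.
#'
#' @param genes a `gene_model_set`.
#' @return Numeric vector of positions, one per gene.
#' @export
gene_tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)

#' @rdname gene_tss
#' @export
gene_tes <- function(genes) ifelse(genes$strand == "+", genes$end, genes$start)

#' Map gene borders to matrix bins
#'
#' @param genes a `gene_model_set` (or any data.frame with `start`/`end`).
#' @param resolution bin width in bp.
#' @return Integer matrix with columns `first_bin` and `last_bin` (0-based),
#'   one row per gene.
#' @export
gene_bins <- function(genes, resolution) {
  cbind(first_bin = as.integer(floor((genes$start - 1) / resolution)),
        last_bin = as.integer(floor((genes$end - 1) / resolution)))
}
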