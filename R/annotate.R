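#' Read gene models from a GFF3 file
#'
#' Imports a GFF3 annotation and keeps features of type `gene`, with
#' coordinates taken verbatim (GFF3 is 1-based inclusive). The gene id is
#' the `ID` attribute.
#'
#' @param path GFF3 path.
#' @return Data frame: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (!length(gr))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#' @param genes Data frame as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$source <- "edscan"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Genes overlapping candidate regions
#'
#' Assigns each gene model to every candidate region it overlaps by at
#' least 1 bp (both in the 1-based inclusive convention). With
#' `within = TRUE` only genes entirely contained in a region are assigned.
#'
#' @param genes Data frame from [read_gff3()].
#' @param regions Data frame with `chrom`, `start`, `end`.
#' @param within Require full containment instead of any overlap.
#' @return Data frame with one row per (region, gene) pair: `chrom`,
#'   `region_start`, `region_end`, `gene_id`, `gene_start`, `gene_end`,
#'   `strand`.
#' @export
genes_in_regions <- function(genes, regions, within = FALSE) {
  empty <- data.frame(chrom = character(), region_start = numeric(),
                      region_end = numeric(), gene_id = character(),
                      gene_start = integer(), gene_end = integer(),
                      strand = character())
  if (!nrow(genes) || !nrow(regions)) return(empty)
  lev <- union(unique(genes$chrom), unique(regions$chrom))
  gg <- GenomicRanges::GRanges(factor(genes$chrom, levels = lev),
                               IRanges::IRanges(genes$start, genes$end))
  rg <- GenomicRanges::GRanges(factor(regions$chrom, levels = lev),
                               IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(
    gg, rg, type = if (within) "within" else "any", minoverlap = 1L)
  if (!length(hits)) return(empty)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  out <- data.frame(chrom = regions$chrom[j],
                    region_start = regions$start[j],
                    region_end = regions$end[j],
                    gene_id = genes$gene_id[i],
                    gene_start = genes$start[i],
                    gene_end = genes$end[i],
                    strand = genes$strand[i],
                    stringsAsFactors = FALSE)
  out <- out[order(j, genes$start[i]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
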