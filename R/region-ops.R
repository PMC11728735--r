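#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Round half-away-from-zero to `digits` decimals (matches printed Mb sizes;
# base round() is round-half-even). Small eps guards binary representation
# of exact halves.
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Candidate-region sizes in bp and Mb
#'
#' Adds `size_bp = end - start` and `size_mb = size_bp / 1e6` rounded
#' half-away-from-zero to 4 decimals. Region bounds are 1-based SNP
#' positions; the `end - start` span convention reproduces published
#' interval sizes such as 14333783..14628947 -> 0.2952 Mb.
#'
#' @param regions Data frame with `start` and `end` columns (`start <= end`).
#' @return `regions` with `size_bp` and `size_mb` columns added/updated.
#' @export
region_size <- function(regions) {
  if (any(regions$start > regions$end)) stop("region with start > end")
  regions$size_bp <- regions$end - regions$start
  regions$size_mb <- round_half_up(regions$size_bp / 1e6, 4)
  regions
}

check_region_frame <- function(regions, what = "regions") {
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    stop(what, " must have columns chrom, start, end")
  if (any(regions$start > regions$end)) stop(what, ": start > end")
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)]))
      stop(what, ": overlapping regions on ", ch)
  }
  invisible(regions)
}

as_granges <- function(regions, seqlevels = unique(regions$chrom)) {
  GenomicRanges::GRanges(
    factor(regions$chrom, levels = seqlevels),
    IRanges::IRanges(regions$start, regions$end))
}

#' Intersect candidate regions across two runs
#'
#' Per-chromosome pairwise interval intersection, the "consistent across
#' years" rule of a replicated bulk-segregant design: the overlap of regions
#' a and b is `[max(starts), min(ends)]` when non-empty.
#'
#' @param regions_a,regions_b Data frames with `chrom`, `start`, `end`;
#'   each sorted and non-overlapping within itself. Optional `label`
#'   columns are combined with "&".
#' @param strict Error when the two sets share no chromosome names (the
#'   signature of regions called on different genomes). Set `FALSE` where
#'   both sets are known to come from the same genome, in which case an
#'   empty chromosome intersection simply yields no overlap.
#' @return Data frame of overlap regions with sizes ([region_size()]),
#'   sorted by chromosome and start; zero rows when nothing overlaps.
#' @examples
#' a <- data.frame(chrom = "Chr1", start = 100, end = 500)
#' b <- data.frame(chrom = "Chr1", start = 300, end = 900)
#' intersect_regions(a, b)
#' @export
intersect_regions <- function(regions_a, regions_b, strict = TRUE) {
  check_region_frame(regions_a, "regions_a")
  check_region_frame(regions_b, "regions_b")
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), label = character())
  if (!nrow(regions_a) || !nrow(regions_b))
    return(region_size(empty))
  if (!length(intersect(unique(regions_a$chrom), unique(regions_b$chrom)))) {
    if (strict)
      stop("region sets share no chromosome names: mismatched genomes?")
    return(region_size(empty))
  }
  lev <- union(unique(regions_a$chrom), unique(regions_b$chrom))
  ga <- as_granges(regions_a, lev)
  gb <- as_granges(regions_b, lev)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (!length(hits)) return(region_size(empty))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ga))[i],
    start = pmax(regions_a$start[i], regions_b$start[j]),
    end = pmin(regions_a$end[i], regions_b$end[j]),
    label = paste(
      if (is.null(regions_a$label)) "a" else regions_a$label[i],
      if (is.null(regions_b$label)) "b" else regions_b$label[j],
      sep = "&"),
    stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, unique(regions_a$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  region_size(out)
}

#' Total size of a set of non-overlapping regions, in Mb
#'
#' @param regions Data frame with `chrom`, `start`, `end`; must be
#'   non-overlapping (intersect or merge first).
#' @return Total `end - start` span in Mb, rounded half-away-from-zero to
#'   4 decimals.
#' @examples
#' r <- data.frame(chrom = c("Chr2", "Chr3"),
#'                 start = c(14333783, 41117720),
#'                 end = c(14628947, 41517255))
#' total_size(r)
#' @export
total_size <- function(regions) {
  if (!nrow(regions)) return(0)
  check_region_frame(regions)
  round_half_up(sum(regions$end - regions$start) / 1e6, 4)
}

#' Write regions as BED (0-based half-open)
#' @param regions Data frame with `chrom`, `start`, `end` (1-based).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom,
                   format(regions$start - 1, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions back to the 1-based convention
#' @param path BED path (chrom, start, end in the first three columns).
#' @return Data frame `chrom`, `start`, `end` (1-based).
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = df[[1L]], start = df[[2L]] + 1, end = df[[3L]])
}
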