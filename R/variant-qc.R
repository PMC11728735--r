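#' Variant quality-control parameters
#'
#' Bundles the filtering thresholds applied to a pooled variant table before
#' scanning: genotype-validity depth, site missingness, minor allele
#' frequency, and the marker-density window. Defaults follow common BSA-seq
#' practice: observations below 5x depth are treated as missing, sites
#' missing in more than half the pools are excluded, and only biallelic SNPs
#' with MAF >= 0.2 are retained.
#'
#' @param min_depth Minimum per-pool read depth for a valid observation.
#' @param max_site_missing Maximum tolerated fraction of missing pools per
#'   site; sites above it are dropped.
#' @param max_sample_missing Maximum missing rate per sample (used only in
#'   per-variety genotype mode; inert for a two-pool table).
#' @param min_maf Minimum pooled minor allele frequency.
#' @param het_min_reads Minimum reads supporting each allele for a
#'   heterozygous per-sample genotype call (per-variety mode only).
#' @param density_window Window size in bp for marker-density summaries.
#' @return An object of class `"qc_params"`.
#' @export
qc_params <- function(min_depth = 5, max_site_missing = 0.5,
                      max_sample_missing = 0.3, min_maf = 0.2,
                      het_min_reads = 4, density_window = 5e5) {
  if (min_depth < 1) stop("'min_depth' must be >= 1")
  for (f in c(max_site_missing, max_sample_missing, min_maf))
    if (!(f >= 0 && f <= 1)) stop("fractions must lie in [0, 1]")
  if (density_window <= 0) stop("'density_window' must be positive")
  structure(list(min_depth = min_depth, max_site_missing = max_site_missing,
                 max_sample_missing = max_sample_missing, min_maf = min_maf,
                 het_min_reads = het_min_reads,
                 density_window = density_window),
            class = "qc_params")
}

#' @export
#' @method print qc_params
print.qc_params <- function(x, ...) {
  cat("QC parameters: min depth", x$min_depth,
      "| site missing <=", x$max_site_missing,
      "| MAF >=", x$min_maf,
      "| density window", format(x$density_window, scientific = FALSE),
      "bp\n")
  invisible(x)
}

#' Read a two-pool variant table from VCF
#'
#' Loads a VCF with samples `HIGH` and `LOW` carrying per-sample `AD`
#' allele depths and returns one row per biallelic SNP. Records that are not
#' simple biallelic SNPs (indels, multiallelic sites, symbolic alleles) are
#' dropped, with a message reporting the count.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return Variant-site data frame: `chrom`, `pos`, `ref`, `alt`,
#'   `high_ref`, `high_alt`, `low_ref`, `low_alt`.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1L]
  for (s in c("HIGH", "LOW"))
    if (!s %in% samples) stop("VCF is missing required sample '", s, "'")
  if (nrow(v@fix) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      high_ref = integer(), high_alt = integer(),
                      low_ref = integer(), low_alt = integer()))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)AD(:|$)", fmt)))
    stop("AD FORMAT field missing for samples HIGH/LOW")
  snp <- !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message(n_drop, " non-SNP or multiallelic record(s) dropped")
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(dim(ad)))                       # single-record VCF drops dims
    ad <- matrix(ad, nrow = 1L, dimnames = list(NULL, names(ad)))
  parse_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE)
    n1 <- as.integer(vapply(parts, `[`, "", 1L))
    n2 <- as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else "0", FUN.VALUE = ""))
    cbind(n1, n2)
  }
  hi <- parse_ad(ad[, "HIGH"])
  lo <- parse_ad(ad[, "LOW"])
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    high_ref = hi[, 1L], high_alt = hi[, 2L],
                    low_ref = lo[, 1L], low_alt = lo[, 2L],
                    stringsAsFactors = FALSE)
  out <- out[snp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the depth-validity and site-missingness filters
#'
#' A pool's observation at a site is valid when its total read depth reaches
#' `min_depth`; lower-depth observations are treated as missing. Sites whose
#' missing fraction across pools exceeds `max_site_missing` are dropped
#' (with two pools and the 0.5 default, a site is dropped exactly when both
#' pools are missing).
#'
#' @param sites Variant-site data frame (see [read_variant_vcf()]).
#' @param params A [qc_params()] object.
#' @return The retained sites with logical columns `valid_high`,
#'   `valid_low` added.
#' @export
apply_validity <- function(sites, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  sites$valid_high <- (sites$high_ref + sites$high_alt) >= params$min_depth
  sites$valid_low <- (sites$low_ref + sites$low_alt) >= params$min_depth
  miss_frac <- (2 - sites$valid_high - sites$valid_low) / 2
  keep <- miss_frac <= params$max_site_missing
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_missing") <- sum(!keep)
  out
}

#' Apply the pooled minor-allele-frequency filter
#'
#' The pooled MAF is computed from the combined ref/alt depths of the valid
#' pools; sites with MAF below `min_maf` are dropped (boundary inclusive:
#' MAF equal to the threshold is retained).
#'
#' @inheritParams apply_validity
#' @return The retained sites, with a `maf` column added.
#' @export
apply_maf <- function(sites, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  if (is.null(sites$valid_high))
    stop("run apply_validity() before apply_maf()")
  ref_tot <- sites$high_ref * sites$valid_high + sites$low_ref * sites$valid_low
  alt_tot <- sites$high_alt * sites$valid_high + sites$low_alt * sites$valid_low
  tot <- ref_tot + alt_tot
  if (any(tot == 0))
    stop("retained site with zero combined depth: validity filter missed it")
  sites$maf <- pmin(ref_tot, alt_tot) / tot
  keep <- sites$maf >= params$min_maf
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_maf") <- sum(!keep)
  out
}

#' Run the full variant QC pass
#'
#' Depth validity and site missingness, then pooled MAF; records the number
#' of sites dropped by each rule in the `"qc_log"` attribute.
#'
#' @inheritParams apply_validity
#' @return Retained sites with `valid_high`, `valid_low`, `maf` columns.
#' @export
qc_filter <- function(sites, params = qc_params()) {
  n0 <- nrow(sites)
  v <- apply_validity(sites, params)
  m <- apply_maf(v, params)
  attr(m, "qc_log") <- c(input = n0,
                         dropped_missing = attr(v, "n_dropped_missing"),
                         dropped_maf = attr(m, "n_dropped_maf"),
                         retained = nrow(m))
  m
}

#' Marker density in fixed windows and adjacent-marker gap sizes
#'
#' Counts SNPs per non-overlapping window of `window` bp along each
#' chromosome (half-open windows `[k*w, (k+1)*w)` in 0-based coordinates;
#' positions are 1-based) and lists the gaps between successive markers.
#'
#' @param sites Variant-site data frame sorted by chromosome and position.
#' @param window Window size in bp.
#' @return List with `density` (data frame: chrom, window_start, window_end,
#'   n_snps; 1-based inclusive window bounds) and `gaps` (data frame: chrom,
#'   gap in bp between successive markers).
#' @export
marker_density <- function(sites, window = 5e5) {
  if (window <= 0) stop("'window' must be positive")
  dens <- list(); gaps <- list()
  for (chrom in unique(sites$chrom)) {
    pos <- sites$pos[sites$chrom == chrom]
    if (is.unsorted(pos)) stop("positions not sorted on ", chrom)
    idx <- floor((pos - 1) / window)       # 0-based window index
    counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
    k <- seq_along(counts) - 1L
    dens[[chrom]] <- data.frame(chrom = chrom,
                                window_start = k * window + 1,
                                window_end = (k + 1) * window,
                                n_snps = counts)
    if (length(pos) > 1L)
      gaps[[chrom]] <- data.frame(chrom = chrom, gap = diff(pos))
  }
  list(density = if (length(dens))
         do.call(rbind, c(dens, list(make.row.names = FALSE)))
       else data.frame(chrom = character(), window_start = numeric(),
                       window_end = numeric(), n_snps = integer()),
       gaps = if (length(gaps))
         do.call(rbind, c(gaps, list(make.row.names = FALSE)))
       else data.frame(chrom = character(), gap = numeric()))
}
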