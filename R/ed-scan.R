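#' Euclidean distance between two allele-frequency vectors
#'
#' The per-SNP association statistic of a bulked-segregant scan: the
#' Euclidean distance `sqrt(sum((H - L)^2))` between the allele-frequency
#' vector of the high-trait pool (H) and that of the low-trait pool (L).
#' For a biallelic site it ranges from 0 (identical pools) to `sqrt(2)`
#' (fixed for opposite alleles), and it is symmetric under pool swap.
#'
#' @param h,l Numeric allele-frequency vectors of equal length, each summing
#'   to 1 (e.g. `c(ref_freq, alt_freq)`).
#' @return The ED value, a non-negative scalar.
#' @examples
#' ed_statistic(c(0.8, 0.2), c(0.3, 0.7))  # sqrt(0.25 + 0.25)
#' @export
ed_statistic <- function(h, l) {
  if (length(h) != length(l))
    stop("'h' and 'l' must have the same length")
  if (abs(sum(h) - 1) > 1e-6 || abs(sum(l) - 1) > 1e-6)
    stop("allele-frequency vectors must each sum to 1")
  sqrt(sum((h - l)^2))
}

#' Per-pool allele frequencies at each variant site
#'
#' Converts the read depths of a variant table into the H and L frequency
#' vectors of the ED statistic. Every site must be observable in both pools:
#' sites where either pool has zero depth (or a failed validity flag, if
#' present) must be removed upstream.
#'
#' @param sites Variant-site data frame with `high_ref`, `high_alt`,
#'   `low_ref`, `low_alt` depth columns.
#' @return List of two n x 2 matrices `H` and `L` with columns
#'   `ref`, `alt`; each row sums to 1.
#' @export
pool_frequencies <- function(sites) {
  hi_tot <- sites$high_ref + sites$high_alt
  lo_tot <- sites$low_ref + sites$low_alt
  if (any(hi_tot == 0) || any(lo_tot == 0))
    stop("site with zero depth in a pool: filter before computing frequencies")
  if (!is.null(sites$valid_high) &&
      (any(!sites$valid_high) || any(!sites$valid_low)))
    stop("site with an invalid pool observation: filter before computing frequencies")
  H <- cbind(ref = sites$high_ref / hi_tot, alt = sites$high_alt / hi_tot)
  L <- cbind(ref = sites$low_ref / lo_tot, alt = sites$low_alt / lo_tot)
  list(H = H, L = L)
}

# Tricube weight on |d| <= bw (zero at the boundary).
tricube <- function(d, bw) (1 - pmin(abs(d) / bw, 1)^3)^3

#' Smooth a scan profile with a tricube distance kernel
#'
#' Local weighted mean of the profile values over physical distance: the
#' fitted value at position `p` averages all values within `bandwidth` bp,
#' weighted by the tricube kernel `(1 - (|d|/bw)^3)^3`. The smoother
#' reproduces constants exactly and every fitted value lies within the range
#' of the raw values inside its window.
#'
#' @param pos Sorted numeric vector of positions (bp) on one chromosome.
#' @param y Profile values (e.g. ED^x), same length as `pos`.
#' @param bandwidth Half-window width in bp (> 0).
#' @return Numeric vector of fitted values.
#' @export
fit_profile <- function(pos, y, bandwidth = 2e6) {
  n <- length(pos)
  if (length(y) != n) stop("'pos' and 'y' must have the same length")
  if (bandwidth <= 0) stop("'bandwidth' must be positive")
  if (n == 0L) return(numeric())
  if (is.unsorted(pos)) stop("'pos' must be sorted")
  if (n > 1L && bandwidth < stats::median(diff(pos)))
    warning("bandwidth smaller than the median marker gap: ",
            "fitted values will mostly reproduce the raw profile")
  fitted <- numeric(n)
  lo <- findInterval(pos - bandwidth, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + bandwidth, pos)
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    w <- tricube(pos[j] - pos[i], bandwidth)
    fitted[i] <- sum(w * y[j]) / sum(w)
  }
  fitted
}

#' Per-chromosome scan threshold: median plus three standard deviations
#'
#' The background-interference threshold of the genome scan, computed on the
#' fitted profile of one chromosome.
#'
#' @param fitted Numeric vector of fitted profile values (length >= 2).
#' @return List with elements `median`, `sd`, `value` where
#'   `value = median + 3 * sd`.
#' @export
ed_threshold <- function(fitted) {
  if (length(fitted) < 2L)
    stop("at least 2 sites are needed to compute a threshold (SD undefined)")
  m <- stats::median(fitted)
  s <- stats::sd(fitted)
  list(median = m, sd = s, value = m + 3 * s)
}

#' Call above-threshold candidate regions on one chromosome
#'
#' Maximal runs of consecutive sites whose fitted value strictly exceeds the
#' threshold; runs separated by less than `merge_gap` bp are merged. Region
#' bounds are the first and last SNP positions of the run.
#'
#' @param pos Sorted positions on one chromosome.
#' @param fitted Fitted profile values, same length.
#' @param threshold Threshold value (scalar, or the list from
#'   [ed_threshold()]).
#' @param merge_gap Runs closer than this many bp are merged.
#' @return Data frame with `start`, `end`, `n_sites` (possibly 0 rows).
#' @export
call_regions <- function(pos, fitted, threshold, merge_gap = 1e5) {
  if (is.list(threshold)) threshold <- threshold$value
  if (length(pos) != length(fitted))
    stop("'pos' and 'fitted' must have the same length")
  above <- fitted > threshold
  if (!any(above))
    return(data.frame(start = numeric(), end = numeric(),
                      n_sites = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  # merge runs separated by < merge_gap bp
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (k in 2:nrow(runs)) {
      gap <- pos[runs$i0[k]] - pos[merged$i1[nrow(merged)]]
      if (gap < merge_gap) {
        merged$i1[nrow(merged)] <- runs$i1[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  data.frame(start = pos[merged$i0], end = pos[merged$i1],
             n_sites = merged$i1 - merged$i0 + 1L)
}

#' Euclidean-distance genome scan between two extreme bulks
#'
#' The central estimator of the package. For each biallelic SNP it computes
#' the Euclidean distance (ED) between the allele-frequency vectors of the
#' HIGH and LOW pools, raises it to the power `power` (ED^2 by default, to
#' suppress background noise relative to signal), smooths the ED^x profile
#' along each chromosome with a tricube distance kernel, derives a
#' per-chromosome threshold (median + 3 SD of the fitted profile), and calls
#' candidate regions as maximal above-threshold runs.
#'
#' @param sites Variant-site data frame (typically the output of
#'   [qc_filter()] or [read_variant_vcf()]), sorted by chromosome and
#'   position. Sites observable in only one pool (retained by the
#'   missingness rule but useless to ED) are excluded with a message.
#' @param power Exponent `x` of the ED^x transform (>= 1).
#' @param bandwidth Tricube smoothing half-window in bp.
#' @param merge_gap Above-threshold runs closer than this are merged (bp).
#' @return An object of class `"ed_scan"`: a list with
#'   \describe{
#'     \item{sites}{data frame `chrom`, `pos`, `ed`, `ed_x`, `fitted`}
#'     \item{thresholds}{data frame `chrom`, `median`, `sd`, `value`}
#'     \item{regions}{data frame `chrom`, `start`, `end`, `size_bp`,
#'       `size_mb`, `n_sites`}
#'     \item{params}{the call parameters}
#'   }
#' @examples
#' truth <- sim_bsa_panel(60, c(Chr1 = 20e6), snp_per_mb = 10,
#'                        qtls = list(qtl_spec("Chr1", 10e6, 1)),
#'                        h2 = 0.9, seed = 2)
#' bulks <- select_bulks(truth$pheno[, 1], 0.2, 0.2)
#' sites <- sim_pool_reads(truth, bulks, depth = 60, seed = 3)
#' scan <- ed_scan(qc_filter(sites))
#' summary(scan)
#' @export
ed_scan <- function(sites, power = 2, bandwidth = 2e6, merge_gap = 1e5) {
  if (power < 1) stop("'power' must be >= 1")
  # the ED statistic needs both pools observed: sites retained by QC on one
  # valid pool alone are excluded here, with a count
  both <- if (!is.null(sites$valid_high)) {
    sites$valid_high & sites$valid_low
  } else {
    (sites$high_ref + sites$high_alt) > 0 & (sites$low_ref + sites$low_alt) > 0
  }
  if (any(!both)) {
    message(sum(!both), " site(s) without both pools observed excluded ",
            "from the scan")
    sites <- sites[both, , drop = FALSE]
  }
  if (!nrow(sites)) stop("no variant sites to scan")
  chroms <- unique(sites$chrom)
  fr <- pool_frequencies(sites)
  ed <- sqrt(rowSums((fr$H - fr$L)^2))
  ed_x <- ed^power

  site_out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                         ed = ed, ed_x = ed_x, fitted = NA_real_,
                         stringsAsFactors = FALSE)
  thr_rows <- list(); reg_rows <- list()
  for (chrom in chroms) {
    sel <- which(site_out$chrom == chrom)
    pos <- site_out$pos[sel]
    if (is.unsorted(pos)) stop("positions not sorted on ", chrom)
    f <- fit_profile(pos, ed_x[sel], bandwidth)
    site_out$fitted[sel] <- f
    th <- ed_threshold(f)
    thr_rows[[chrom]] <- data.frame(chrom = chrom, median = th$median,
                                    sd = th$sd, value = th$value)
    reg <- call_regions(pos, f, th$value, merge_gap)
    if (nrow(reg))
      reg_rows[[chrom]] <- data.frame(chrom = chrom, reg)
  }
  thresholds <- do.call(rbind, c(thr_rows, list(make.row.names = FALSE)))
  regions <- if (length(reg_rows))
    do.call(rbind, c(reg_rows, list(make.row.names = FALSE)))
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  n_sites = integer())
  regions <- region_size(regions)

  structure(list(sites = site_out, thresholds = thresholds,
                 regions = regions,
                 params = list(power = power, bandwidth = bandwidth,
                               merge_gap = merge_gap)),
            class = "ed_scan")
}

#' @export
#' @method print ed_scan
print.ed_scan <- function(x, ...) {
  cat("Euclidean-distance bulked-segregant scan\n")
  cat("  ", nrow(x$sites), " SNPs on ", length(unique(x$sites$chrom)),
      " chromosome(s); ED^", x$params$power,
      ", bandwidth ", format(x$params$bandwidth, scientific = FALSE),
      " bp\n", sep = "")
  cat("  ", nrow(x$regions), " candidate region(s) above median + 3 SD\n",
      sep = "")
  invisible(x)
}

#' @export
#' @method summary ed_scan
summary.ed_scan <- function(object, ...) {
  structure(list(scan = object), class = "summary.ed_scan")
}

#' @export
#' @method print summary.ed_scan
print.summary.ed_scan <- function(x, ...) {
  print(x$scan)
  cat("\nPer-chromosome thresholds (median + 3 SD of fitted ED^x):\n")
  print(x$scan$thresholds, row.names = FALSE, digits = 4)
  cat("\nCandidate regions:\n")
  if (nrow(x$scan$regions))
    print(x$scan$regions, row.names = FALSE, digits = 6)
  else cat("  none\n")
  invisible(x)
}

#' @export
#' @method fitted ed_scan
fitted.ed_scan <- function(object, ...) object$sites$fitted

#' @export
#' @method as.data.frame ed_scan
as.data.frame.ed_scan <- function(x, ...) x$sites

#' Plot an ED genome scan
#'
#' Raw ED^x values (points), the fitted profile (line) and the
#' per-chromosome threshold (dashed), one panel per chromosome on a
#' concatenated genome axis.
#'
#' @param x An `"ed_scan"` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
#' @method plot ed_scan
plot.ed_scan <- function(x, ...) {
  s <- x$sites
  chroms <- unique(s$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(s$pos[s$chrom == ch]), 0)))
  names(offs) <- c(chroms, "end")
  gx <- s$pos + offs[s$chrom]
  graphics::plot(gx, s$ed_x, pch = 16, cex = 0.3,
                 col = c("grey50", "grey70")[1L + (match(s$chrom, chroms) %% 2L)],
                 xlab = "genome position (bp)",
                 ylab = sprintf("ED^%g", x$params$power), ...)
  for (ch in chroms) {
    sel <- s$chrom == ch
    graphics::lines(gx[sel], s$fitted[sel], col = "firebrick", lwd = 1.5)
    th <- x$thresholds$value[x$thresholds$chrom == ch]
    graphics::segments(min(gx[sel]), th, max(gx[sel]), th,
                       lty = 2, col = "grey30")
  }
  graphics::abline(v = offs[-c(1L, length(offs))], col = "grey85")
  invisible(x)
}
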