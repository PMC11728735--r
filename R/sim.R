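#' Specify a quantitative trait locus for the simulator
#'
#' A QTL is a single SNP with an additive effect on the trait: each copy of
#' the alternate allele adds `effect` trait units to an individual's genetic
#' value.
#'
#' @param chrom Chromosome identifier (character scalar).
#' @param pos 1-based position in bp (integer >= 1).
#' @param effect Additive effect, trait units per alternate-allele copy.
#' @param freq Alternate-allele frequency in the founding panel, in (0, 1).
#' @return An object of class `"qtl_spec"`.
#' @examples
#' qtl_spec("Chr3", 25e6, effect = 1, freq = 0.4)
#' @export
qtl_spec <- function(chrom, pos, effect, freq = 0.5) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  pos <- as.numeric(pos)
  if (length(pos) != 1L || is.na(pos) || pos < 1 || pos != floor(pos))
    stop("'pos' must be a single integer >= 1")
  if (!is.finite(effect)) stop("'effect' must be finite")
  if (!(freq > 0 && freq < 1)) stop("'freq' must lie strictly in (0, 1)")
  structure(list(chrom = chrom, pos = pos, effect = effect, freq = freq),
            class = "qtl_spec")
}

# Derive independent substream seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a natural soybean-like panel with known QTLs
#'
#' Forward-simulates a diversity panel segregating for a quantitative trait:
#' a multi-chromosome SNP map, individual genotypes with linkage around each
#' locus, and replicate-year phenotypes with a controlled heritability. The
#' returned truth set is the ground-truth oracle against which downstream
#' bulk-segregant scans can be validated.
#'
#' Haplotypes are generated by a Markov renewal ("copying") process along
#' each chromosome: walking from SNP to SNP, the current ancestral allele is
#' kept with probability `1 - r` and redrawn from the local panel frequency
#' with probability `r = min(0.5, gap_bp * 1e-8 * recomb_scale)`. Correlation
#' with a causal locus therefore decays approximately exponentially with
#' physical distance, producing association peaks of controllable width
#' without a coalescent model.
#'
#' Phenotypes are `genetic value + Gaussian noise`; the noise variance is set
#' from the realized genetic variance so that the genetic fraction of the
#' phenotypic variance equals `h2`. Replicate years share genotypes and
#' genetic values but redraw the environmental noise. `h2 = 0` yields pure
#' unit-variance noise (a null trait with no genetic signal).
#'
#' @param n_individuals Number of panel individuals (>= 4).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param snp_per_mb Average SNP density per Mb.
#' @param qtls List of [qtl_spec()] objects (may be empty).
#' @param h2 Narrow-sense heritability in `[0, 1]`.
#' @param n_years Number of replicate phenotype years.
#' @param maf_range Range from which non-QTL panel allele frequencies are
#'   drawn uniformly.
#' @param recomb_scale Scale factor of the per-bp recombination rate; larger
#'   values give faster linkage decay (narrower peaks).
#' @param seed Integer master seed; all substreams derive from it.
#' @return An object of class `"bsa_truth"`: a list with elements
#'   `chrom_lengths`, `snps` (data frame: chrom, pos, ref, alt, freq, qtl
#'   flag), `geno` (individuals x SNPs dosage matrix, values 0/1/2), `pheno`
#'   (individuals x years matrix), `genetic_value`, `qtls`, `h2`, `seed`.
#' @examples
#' truth <- sim_bsa_panel(50, c(Chr1 = 10e6), snp_per_mb = 5,
#'                        qtls = list(qtl_spec("Chr1", 5e6, 1)),
#'                        h2 = 0.8, seed = 1)
#' dim(truth$geno)
#' @export
sim_bsa_panel <- function(n_individuals, chrom_lengths, snp_per_mb = 20,
                          qtls = list(), h2 = 0.5, n_years = 1,
                          maf_range = c(0.1, 0.9), recomb_scale = 50,
                          seed = 1) {
  if (n_individuals < 4) stop("'n_individuals' must be at least 4")
  if (!(h2 >= 0 && h2 <= 1)) stop("'h2' must lie in [0, 1]")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("'chrom_lengths' must be a named vector")
  if (any(chrom_lengths <= 0)) stop("zero or negative chromosome length")
  if (inherits(qtls, "qtl_spec")) qtls <- list(qtls)
  for (q in qtls) {
    if (!q$chrom %in% names(chrom_lengths))
      stop("QTL chromosome '", q$chrom, "' not in 'chrom_lengths'")
    if (q$pos > chrom_lengths[[q$chrom]])
      stop("QTL at ", q$chrom, ":", q$pos, " lies outside its chromosome (",
           chrom_lengths[[q$chrom]], " bp)")
  }

  seeds <- derive_seeds(seed, 2L + n_years)
  set.seed(seeds[1L])

  bases <- c("A", "C", "G", "T")
  n_hap <- 2L * n_individuals
  snp_list <- list()
  geno_list <- list()

  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    n_snp <- max(1L, round(len / 1e6 * snp_per_mb))
    pos <- sort(sample.int(len, min(n_snp, len)))
    freq <- stats::runif(length(pos), maf_range[1L], maf_range[2L])
    is_qtl <- rep(FALSE, length(pos))
    for (q in qtls) {
      if (q$chrom != chrom) next
      j <- match(q$pos, pos)
      if (is.na(j)) {            # insert the causal SNP at its exact position
        j <- findInterval(q$pos, pos) + 1L
        pos <- append(pos, q$pos, after = j - 1L)
        freq <- append(freq, q$freq, after = j - 1L)
        is_qtl <- append(is_qtl, TRUE, after = j - 1L)
      } else {
        freq[j] <- q$freq
        is_qtl[j] <- TRUE
      }
    }
    m <- length(pos)
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

    # Markov copying process over haplotypes (rows: haplotypes, cols: SNPs)
    hap <- matrix(0L, nrow = n_hap, ncol = m)
    a <- stats::rbinom(n_hap, 1L, freq[1L])
    hap[, 1L] <- a
    if (m > 1L) {
      r <- pmin(0.5, diff(pos) * 1e-8 * recomb_scale)
      for (j in 2:m) {
        refresh <- stats::runif(n_hap) < r[j - 1L]
        if (any(refresh))
          a[refresh] <- stats::rbinom(sum(refresh), 1L, freq[j])
        hap[, j] <- a
      }
    }
    geno_list[[chrom]] <- hap[seq(1L, n_hap, by = 2L), , drop = FALSE] +
      hap[seq(2L, n_hap, by = 2L), , drop = FALSE]
    snp_list[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                                    alt = alt, freq = freq, qtl = is_qtl,
                                    stringsAsFactors = FALSE)
  }

  snps <- do.call(rbind, snp_list)
  rownames(snps) <- NULL
  geno <- do.call(cbind, geno_list)
  ids <- sprintf("ind_%03d", seq_len(n_individuals))
  rownames(geno) <- ids

  # genetic values and year-replicate phenotypes
  effects <- numeric(nrow(snps))
  for (q in qtls) {
    j <- which(snps$chrom == q$chrom & snps$pos == q$pos)
    effects[j] <- effects[j] + q$effect
  }
  g <- as.vector(geno %*% effects)
  var_g <- stats::var(g)
  if (h2 == 0 || var_g == 0) {
    g <- rep(0, n_individuals)
    sd_e <- 1
  } else if (h2 == 1) {
    sd_e <- 0
  } else {
    sd_e <- sqrt(var_g * (1 - h2) / h2)
  }
  pheno <- matrix(NA_real_, n_individuals, n_years,
                  dimnames = list(ids, paste0("year", seq_len(n_years))))
  for (y in seq_len(n_years)) {
    set.seed(seeds[2L + y])
    pheno[, y] <- g + stats::rnorm(n_individuals, 0, sd_e)
  }

  structure(list(chrom_lengths = chrom_lengths, snps = snps, geno = geno,
                 pheno = pheno, genetic_value = g, qtls = qtls, h2 = h2,
                 seed = seed),
            class = "bsa_truth")
}

#' @export
#' @method print bsa_truth
print.bsa_truth <- function(x, ...) {
  cat("Simulated BSA panel:", nrow(x$geno), "individuals,",
      nrow(x$snps), "SNPs on", length(x$chrom_lengths), "chromosome(s),",
      ncol(x$pheno), "year(s)\n")
  cat("  h2 =", x$h2, "| QTLs:", length(x$qtls), "| seed =", x$seed, "\n")
  for (q in x$qtls)
    cat("   ", q$chrom, format(q$pos, big.mark = ","),
        "effect", q$effect, "freq", q$freq, "\n")
  invisible(x)
}

#' Select the extreme phenotype bulks
#'
#' Partitions the phenotypic tails into a high-trait and a low-trait bulk,
#' the H and L pools of a bulked-segregant design. Bulk sizes are
#' round-half-up of `q * n` per tail; ties in trait value are broken by
#' individual id so the selection is deterministic and permutation-invariant.
#'
#' @param phenotypes Named numeric vector of per-individual trait values
#'   (names are individual ids; defaults to ind_001... if unnamed).
#' @param low_q,high_q Tail fractions in (0, 0.5].
#' @return An object of class `"bulk_pair"`: list with `high` and `low`
#'   (character vectors of ids, disjoint) and `fractions`.
#' @examples
#' ph <- setNames(1:10, sprintf("ind_%03d", 1:10))
#' select_bulks(ph, 0.2, 0.2)
#' @export
select_bulks <- function(phenotypes, low_q = 0.15, high_q = 0.15) {
  if (!(low_q > 0 && low_q <= 0.5) || !(high_q > 0 && high_q <= 0.5))
    stop("tail fractions must lie in (0, 0.5]")
  n <- length(phenotypes)
  if (is.null(names(phenotypes)))
    names(phenotypes) <- sprintf("ind_%03d", seq_len(n))
  if (anyDuplicated(names(phenotypes))) stop("duplicated individual ids")
  if (max(phenotypes) == min(phenotypes))
    stop("all phenotypes identical: no extremes definable")
  k_low <- max(1L, floor(low_q * n + 0.5))
  k_high <- max(1L, floor(high_q * n + 0.5))
  ids <- names(phenotypes)
  low <- ids[order(phenotypes, ids)][seq_len(k_low)]
  high <- ids[order(-phenotypes, ids)][seq_len(k_high)]
  if (length(intersect(high, low)))
    stop("tail fractions overlap: an individual falls in both bulks")
  structure(list(high = sort(high), low = sort(low),
                 fractions = c(low_q = low_q, high_q = high_q)),
            class = "bulk_pair")
}

#' @export
#' @method print bulk_pair
print.bulk_pair <- function(x, ...) {
  cat("Bulk pair: |high| = ", length(x$high), ", |low| = ", length(x$low),
      " (tails ", x$fractions[["low_q"]], "/", x$fractions[["high_q"]],
      ")\n", sep = "")
  invisible(x)
}

#' Simulate pooled sequencing reads over the two bulks
#'
#' For each SNP and each pool, the true pooled alternate-allele frequency is
#' the mean dosage of the bulk members divided by 2. Site read depth is drawn
#' Poisson(`depth`), and the alternate read count Binomial with the true
#' frequency folded through a symmetric per-base error:
#' `p' = p(1 - e) + (1 - p)e`.
#'
#' @param truth A `"bsa_truth"` object from [sim_bsa_panel()].
#' @param bulks A `"bulk_pair"` from [select_bulks()].
#' @param depth Mean read depth per site per pool (> 0).
#' @param error_rate Per-base sequencing error probability, in `[0, 0.25)`.
#' @param seed Integer seed for the read-sampling stream.
#' @return A data frame of variant sites: columns `chrom`, `pos`, `ref`,
#'   `alt`, `high_ref`, `high_alt`, `low_ref`, `low_alt` (read depths).
#' @export
sim_pool_reads <- function(truth, bulks, depth = 50, error_rate = 0.001,
                           seed = 1) {
  stopifnot(inherits(truth, "bsa_truth"), inherits(bulks, "bulk_pair"))
  if (depth <= 0) stop("'depth' must be positive")
  if (!(error_rate >= 0 && error_rate < 0.25))
    stop("'error_rate' must lie in [0, 0.25)")
  if (!length(bulks$high) || !length(bulks$low)) stop("empty bulk")
  missing_ids <- setdiff(c(bulks$high, bulks$low), rownames(truth$geno))
  if (length(missing_ids))
    stop("bulk ids not in panel: ", paste(missing_ids, collapse = ", "))

  set.seed(seed)
  m <- nrow(truth$snps)
  out <- truth$snps[, c("chrom", "pos", "ref", "alt")]
  for (pool in c("high", "low")) {
    p <- colMeans(truth$geno[bulks[[pool]], , drop = FALSE]) / 2
    p_obs <- p * (1 - error_rate) + (1 - p) * error_rate
    dp <- stats::rpois(m, depth)
    alt <- stats::rbinom(m, dp, p_obs)
    out[[paste0(pool, "_ref")]] <- dp - alt
    out[[paste0(pool, "_alt")]] <- alt
  }
  rownames(out) <- NULL
  out
}

#' Write pooled variant sites as a two-sample VCF
#'
#' Emits plain-text VCF 4.2 with samples `HIGH` and `LOW`, each carrying the
#' `AD` (ref,alt allele depths) and `DP` FORMAT fields, suitable for reading
#' back with [read_variant_vcf()].
#'
#' @param sites Variant-site data frame as produced by [sim_pool_reads()],
#'   sorted by chromosome (order of first appearance) and position.
#' @param path Output file path.
#' @param chrom_lengths Optional named vector adding `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(sites, path, chrom_lengths = NULL) {
  req <- c("chrom", "pos", "ref", "alt",
           "high_ref", "high_alt", "low_ref", "low_alt")
  if (!all(req %in% names(sites)))
    stop("'sites' must have columns: ", paste(req, collapse = ", "))
  if (nrow(sites)) {
    chrom_f <- factor(sites$chrom, levels = unique(sites$chrom))
    o <- order(chrom_f, sites$pos)
    if (!identical(o, seq_len(nrow(sites))))
      stop("'sites' must be sorted by (chromosome, position)")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=edscan")
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  hdr <- c(hdr,
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "HIGH", "LOW", sep = "\t"))
  body <- if (nrow(sites)) {
    paste(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
          ".", sites$ref, sites$alt, ".", "PASS", ".", "AD:DP",
          sprintf("%d,%d:%d", sites$high_ref, sites$high_alt,
                  sites$high_ref + sites$high_alt),
          sprintf("%d,%d:%d", sites$low_ref, sites$low_alt,
                  sites$low_ref + sites$low_alt),
          sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a phenotype table
#'
#' Tab-separated columns `id`, `year`, `trait`, one row per individual-year.
#'
#' @param truth A `"bsa_truth"` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(truth, path) {
  stopifnot(inherits(truth, "bsa_truth"))
  df <- data.frame(
    id = rep(rownames(truth$pheno), ncol(truth$pheno)),
    year = rep(colnames(truth$pheno), each = nrow(truth$pheno)),
    trait = as.vector(truth$pheno))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table written by [write_phenotypes()]
#' @param path TSV path with columns id, year, trait.
#' @return Data frame with those columns.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("id", "year", "trait") %in% names(df)))
    stop("phenotype table must have columns id, year, trait")
  df
}

#' Write simulator ground truth as JSON
#'
#' Records the QTL positions/effects, chromosome lengths, heritability and
#' seed so a scan result can be checked against the truth without the full
#' genotype matrix.
#'
#' @param truth A `"bsa_truth"` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "bsa_truth"))
  obj <- list(
    chrom_lengths = as.list(truth$chrom_lengths),
    h2 = truth$h2, seed = truth$seed,
    n_individuals = nrow(truth$geno), n_years = ncol(truth$pheno),
    qtls = lapply(truth$qtls, function(q)
      list(chrom = q$chrom, pos = q$pos, effect = q$effect, freq = q$freq)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
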