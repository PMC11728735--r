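#' Default pipeline configuration
#'
#' The full parameter set of a simulated replicated BSA experiment:
#' panel simulation, bulk selection, pooled sequencing, variant QC, the ED
#' scan, and cross-year region intersection. Any subset can be overridden
#' via [run_pipeline()]'s `config` (a list or a YAML file of the same
#' shape).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_individuals = 200L,
    chrom_lengths = c(Chr1 = 50e6, Chr2 = 50e6, Chr3 = 50e6,
                      Chr4 = 50e6, Chr5 = 50e6),
    snp_per_mb = 20,
    qtls = list(list(chrom = "Chr3", pos = 25e6, effect = 1, freq = 0.5)),
    h2 = 0.8,
    n_years = 2L,
    low_q = 0.15, high_q = 0.15,
    depth = 50, error_rate = 0.001,
    qc = list(),                 # overrides for qc_params()
    power = 2, bandwidth = 2e6, merge_gap = 1e5,
    gff = NULL)
}

normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config          # shallow merge: fields replace whole
  if (is.list(cfg$chrom_lengths)) cfg$chrom_lengths <- unlist(cfg$chrom_lengths)
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full simulate -> QC -> scan -> overlap -> annotate pipeline
#'
#' Simulates a panel with known QTLs, selects extreme bulks per replicate
#' year, simulates pooled reads, writes and QC-filters the variant tables,
#' runs the ED genome scan per year, intersects the per-year candidate
#' regions, optionally annotates the overlap with gene models, and writes
#' all tables plus a reproducibility manifest to `out_dir`. Reruns with the
#' same configuration produce bit-identical outputs.
#'
#' @param config A list overriding [default_config()], or a path to a YAML
#'   file of the same shape.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `truth`, `scans` (one `"ed_scan"` per year),
#'   `regions` (per-year), `overlap` (cross-year region table), `genes`
#'   (or NULL), `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- normalize_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qtls <- lapply(cfg$qtls, function(q)
    qtl_spec(q$chrom, q$pos, q$effect, if (is.null(q$freq)) 0.5 else q$freq))
  seeds <- derive_seeds(cfg$seed, 1L + cfg$n_years)
  params <- do.call(qc_params, cfg$qc)

  truth <- sim_bsa_panel(cfg$n_individuals, cfg$chrom_lengths,
                         snp_per_mb = cfg$snp_per_mb, qtls = qtls,
                         h2 = cfg$h2, n_years = cfg$n_years,
                         seed = seeds[1L])
  write_truth_json(truth, file.path(out_dir, "truth.json"))
  write_phenotypes(truth, file.path(out_dir, "phenotypes.tsv"))
  write_tsv(pheno_table(read_phenotypes(file.path(out_dir, "phenotypes.tsv"))),
            file.path(out_dir, "phenotype_summary.tsv"))

  scans <- list(); regions <- list(); counts <- list()
  for (y in seq_len(cfg$n_years)) {
    yl <- colnames(truth$pheno)[y]
    bulks <- select_bulks(truth$pheno[, y], cfg$low_q, cfg$high_q)
    sites <- sim_pool_reads(truth, bulks, depth = cfg$depth,
                            error_rate = cfg$error_rate,
                            seed = seeds[1L + y])
    write_variant_vcf(sites, file.path(out_dir, paste0(yl, ".vcf")),
                      chrom_lengths = cfg$chrom_lengths)
    qc <- qc_filter(sites, params)
    counts[[yl]] <- as.list(attr(qc, "qc_log"))
    scan <- ed_scan(qc, power = cfg$power, bandwidth = cfg$bandwidth,
                    merge_gap = cfg$merge_gap)
    scans[[yl]] <- scan
    reg <- scan$regions
    if (nrow(reg)) reg$label <- yl
    regions[[yl]] <- reg

    write_tsv(scan$sites, file.path(out_dir, paste0(yl, "_scan.tsv")))
    write_tsv(scan$thresholds,
              file.path(out_dir, paste0(yl, "_thresholds.tsv")))
    write_tsv(reg, file.path(out_dir, paste0(yl, "_regions.tsv")))
    write_regions_bed(reg, file.path(out_dir, paste0(yl, "_regions.bed")))
    plotdata <- merge(scan$sites,
                      scan$thresholds[, c("chrom", "value")], by = "chrom",
                      sort = FALSE)
    names(plotdata)[names(plotdata) == "value"] <- "threshold"
    write_tsv(plotdata, file.path(out_dir, paste0(yl, "_plotdata.tsv")))
  }

  overlap <- Reduce(function(a, b) intersect_regions(a, b, strict = FALSE),
                    regions)
  tbl <- data.frame(Chromosome = overlap$chrom,
                    `Start Location` = overlap$start,
                    `End Location` = overlap$end,
                    `Size/Mb` = overlap$size_mb,
                    check.names = FALSE)
  write_tsv(tbl, file.path(out_dir, "overlap_regions.tsv"))
  write_regions_bed(overlap, file.path(out_dir, "overlap_regions.bed"))

  genes <- NULL
  if (!is.null(cfg$gff)) {
    genes <- genes_in_regions(read_gff3(cfg$gff), overlap)
    write_tsv(genes, file.path(out_dir, "candidate_genes.tsv"))
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "edscan",
    version = as.character(utils::packageVersion("edscan")),
    seed = cfg$seed,
    stage_seeds = as.list(seeds),
    config = cfg[setdiff(names(cfg), "chrom_lengths")],
    chrom_lengths = as.list(cfg$chrom_lengths),
    qc_counts = counts,
    n_overlap_regions = nrow(overlap),
    total_overlap_mb = total_size(overlap),
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(truth = truth, scans = scans, regions = regions,
                 overlap = overlap, genes = genes, manifest = manifest,
                 out_dir = out_dir))
}
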