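# Shared fixtures: all built in code at test time.

# A hand-sized variant table with explicit depths.
make_sites <- function(chrom, pos, high_ref, high_alt, low_ref, low_alt) {
  n <- length(pos)
  data.frame(chrom = chrom, pos = pos,
             ref = rep("A", n), alt = rep("T", n),
             high_ref = high_ref, high_alt = high_alt,
             low_ref = low_ref, low_alt = low_alt,
             stringsAsFactors = FALSE)
}

# Small two-year panel with one QTL, used across scan/pipeline tests.
small_truth <- function(seed = 1, h2 = 0.9, n_years = 2, qtl_pos = 10e6,
                        n_individuals = 120, chrom_lengths = c(Chr1 = 20e6),
                        qtl_chrom = "Chr1", snp_per_mb = 15) {
  qtls <- if (is.null(qtl_pos)) list() else
    list(qtl_spec(qtl_chrom, qtl_pos, effect = 1, freq = 0.5))
  sim_bsa_panel(n_individuals, chrom_lengths, snp_per_mb = snp_per_mb,
                qtls = qtls, h2 = h2, n_years = n_years, seed = seed)
}

# One simulated year: bulks + pooled reads + QC, in memory.
simulate_year <- function(truth, year = 1, low_q = 0.15, high_q = 0.15,
                          depth = 50, seed = 1) {
  bulks <- select_bulks(truth$pheno[, year], low_q, high_q)
  qc_filter(sim_pool_reads(truth, bulks, depth = depth, seed = seed))
}

# Brute-force tricube smoother: the O(n^2) oracle for fit_profile().
brute_fit <- function(pos, y, bw) {
  vapply(seq_along(pos), function(i) {
    d <- abs(pos - pos[i])
    w <- ifelse(d < bw, (1 - (d / bw)^3)^3, 0)
    sum(w * y) / sum(w)
  }, 0)
}

# Does any region row cover chrom:pos?
covers <- function(regions, chrom, pos) {
  any(regions$chrom == chrom & regions$start <= pos & regions$end >= pos)
}
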