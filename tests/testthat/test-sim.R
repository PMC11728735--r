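test_that("noise-free phenotypes follow QTL dosage and replicates share genotypes", {
  truth <- small_truth(seed = 3, h2 = 1, n_years = 2)
  q <- which(truth$snps$qtl)
  expect_length(q, 1L)
  dos <- truth$geno[, q]
  # h2 = 1: phenotype is the genetic value, so dosage groups are ordered
  expect_true(all(diff(tapply(truth$pheno[, 1], dos, mean)) > 0))
  expect_equal(truth$pheno[, 1], truth$genetic_value,
               ignore_attr = TRUE)
  # same seed reruns are identical; years share genotypes, not noise
  truth2 <- small_truth(seed = 3, h2 = 1, n_years = 2)
  expect_identical(truth, truth2)
  noisy <- small_truth(seed = 3, h2 = 0.5, n_years = 2)
  expect_identical(noisy$geno, truth$geno)
  expect_false(identical(noisy$pheno[, 1], noisy$pheno[, 2]))
})

test_that("realized genetic-variance fraction tracks the target heritability", {
  fracs <- vapply(1:50, function(s) {
    truth <- sim_bsa_panel(200, c(Chr1 = 10e6), snp_per_mb = 10,
                           qtls = list(qtl_spec("Chr1", 5e6, 1)),
                           h2 = 0.5, seed = s)
    g <- truth$genetic_value
    e <- truth$pheno[, 1] - g
    var(g) / (var(g) + var(e))
  }, 0)
  expect_true(all(fracs > 0.35 & fracs < 0.65))
})

test_that("simulator rejects invalid genomes and heritabilities", {
  expect_error(sim_bsa_panel(100, c(Chr1 = 0)), "length")
  expect_error(sim_bsa_panel(100, c(Chr1 = 1e6),
                             qtls = list(qtl_spec("Chr1", 2e6, 1))),
               "outside")
  expect_error(sim_bsa_panel(100, c(Chr1 = 1e6), h2 = 1.2), "h2")
  expect_error(sim_bsa_panel(2, c(Chr1 = 1e6)), "at least 4")
})

test_that("bulk selection takes the stated tails with round-half-up sizes", {
  ph <- setNames(1:10, sprintf("i%02d", 1:10))
  b <- select_bulks(ph, 0.2, 0.2)
  expect_setequal(b$high, c("i09", "i10"))
  expect_setequal(b$low, c("i01", "i02"))
  # q = 0.5 on even n partitions everyone
  b2 <- select_bulks(ph, 0.5, 0.5)
  expect_setequal(c(b2$high, b2$low), names(ph))
  # 85 values at 15% tails: round-half-up of 12.75 gives 13 per tail
  set.seed(9)
  ph85 <- setNames(rnorm(85, 8, 2), sprintf("v%03d", 1:85))
  b3 <- select_bulks(ph85, 0.15, 0.15)
  expect_length(b3$high, 13L)
  expect_length(b3$low, 13L)
  expect_length(intersect(b3$high, b3$low), 0L)
  expect_error(select_bulks(rep(1, 10)), "identical")
})

test_that("bulk selection is idempotent and permutation invariant", {
  set.seed(11)
  ph <- setNames(sample(rep(1:20, 2)), sprintf("i%02d", 1:40))
  b <- select_bulks(ph, 0.25, 0.25)
  perm <- sample(seq_along(ph))
  expect_identical(select_bulks(ph[perm], 0.25, 0.25), b)
  expect_identical(select_bulks(ph, 0.25, 0.25), b)
})

test_that("pooled reads reflect bulk allele frequencies", {
  truth <- small_truth(seed = 5, h2 = 1)
  bulks <- select_bulks(truth$pheno[, 1], 0.2, 0.2)
  # all-reference bulk members with zero error can yield no alt reads
  mono <- truth
  mono$geno[] <- 0L
  reads0 <- sim_pool_reads(mono, bulks, depth = 30, error_rate = 0,
                           seed = 2)
  expect_true(all(reads0$high_alt == 0))
  expect_true(all(reads0$low_alt == 0))
  # at great depth the observed alt fraction converges to the pooled truth:
  # mean absolute error within 0.01 and per-site errors within the
  # 3-SD binomial bound at the usual rate
  reads <- sim_pool_reads(truth, bulks, depth = 10000, error_rate = 0,
                          seed = 3)
  p_true <- colMeans(truth$geno[bulks$high, ]) / 2
  dp <- reads$high_ref + reads$high_alt
  p_obs <- reads$high_alt / dp
  expect_lt(mean(abs(p_obs - p_true)), 0.01)
  within3sd <- abs(p_obs - p_true) <= 3 * sqrt(p_true * (1 - p_true) / dp)
  expect_gte(mean(within3sd), 0.99)
  # determinism
  expect_identical(sim_pool_reads(truth, bulks, depth = 50, seed = 7),
                   sim_pool_reads(truth, bulks, depth = 50, seed = 7))
})

test_that("high bulk exceeds low bulk at the QTL across seeds", {
  ok <- vapply(1:20, function(s) {
    truth <- sim_bsa_panel(100, c(Chr1 = 5e6), snp_per_mb = 10,
                           qtls = list(qtl_spec("Chr1", 2.5e6, 1)),
                           h2 = 1, seed = s)
    b <- select_bulks(truth$pheno[, 1], 0.2, 0.2)
    q <- which(truth$snps$qtl)
    mean(truth$geno[b$high, q]) > mean(truth$geno[b$low, q])
  }, NA)
  expect_true(all(ok))
})

test_that("the VCF writer round-trips through the reader", {
  # header-only VCF
  empty <- make_sites(character(), integer(), integer(), integer(),
                      integer(), integer())
  f0 <- tempfile(fileext = ".vcf")
  write_variant_vcf(empty, f0)
  expect_identical(nrow(read_variant_vcf(f0)), 0L)
  # single site, exact depths
  s1 <- make_sites("Chr1", 100L, 10L, 5L, 8L, 7L)
  f1 <- tempfile(fileext = ".vcf")
  write_variant_vcf(s1, f1)
  back <- read_variant_vcf(f1)
  expect_equal(back, s1, ignore_attr = TRUE)
  # a simulated table is recovered field for field
  truth <- small_truth(seed = 6)
  bulks <- select_bulks(truth$pheno[, 1], 0.2, 0.2)
  sites <- sim_pool_reads(truth, bulks, depth = 40, seed = 8)
  f2 <- tempfile(fileext = ".vcf")
  write_variant_vcf(sites, f2, chrom_lengths = truth$chrom_lengths)
  expect_equal(read_variant_vcf(f2), sites, ignore_attr = TRUE)
  # unsorted input is refused
  expect_error(write_variant_vcf(sites[rev(seq_len(nrow(sites))), ],
                                 tempfile()), "sorted")
})
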