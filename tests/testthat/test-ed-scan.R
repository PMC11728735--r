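test_that("pool frequencies normalize depths and reject unusable sites", {
  s <- make_sites("Chr1", c(1L, 2L),
                  high_ref = c(10L, 8L), high_alt = c(10L, 2L),
                  low_ref = c(10L, 3L), low_alt = c(10L, 7L))
  fr <- pool_frequencies(s)
  expect_equal(fr$H[1, ], c(ref = 0.5, alt = 0.5))
  expect_equal(fr$H[2, ], c(ref = 0.8, alt = 0.2))
  expect_equal(fr$L[2, ], c(ref = 0.3, alt = 0.7))
  expect_equal(rowSums(fr$H), rep(1, 2), tolerance = 1e-12)
  expect_equal(rowSums(fr$L), rep(1, 2), tolerance = 1e-12)
  bad <- make_sites("Chr1", 1L, 0L, 0L, 5L, 5L)
  expect_error(pool_frequencies(bad), "zero depth")
})

test_that("the ED statistic matches its closed forms and direct evaluation", {
  expect_identical(ed_statistic(c(0.4, 0.6), c(0.4, 0.6)), 0)
  expect_equal(ed_statistic(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(ed_statistic(c(0.8, 0.2), c(0.3, 0.7)), sqrt(0.5))
  expect_error(ed_statistic(c(1, 0), c(0.5, 0.25, 0.25)), "length")
  set.seed(42)
  for (i in 1:200) {
    a <- runif(1); b <- runif(1)
    h <- c(1 - a, a); l <- c(1 - b, b)
    expect_equal(ed_statistic(h, l),
                 sqrt((h[1] - l[1])^2 + (h[2] - l[2])^2),
                 tolerance = 1e-12)
  }
})

test_that("ED is a metric and invariant under pool swap", {
  set.seed(7)
  for (i in 1:50) {
    x <- runif(3)
    h <- c(1 - x[1], x[1]); l <- c(1 - x[2], x[2]); m <- c(1 - x[3], x[3])
    expect_gte(ed_statistic(h, l), 0)
    expect_equal(ed_statistic(h, l), ed_statistic(l, h))
    expect_lte(ed_statistic(h, l),
               ed_statistic(h, m) + ed_statistic(m, l) + 1e-12)
  }
})

test_that("the power transform preserves rank order", {
  truth <- small_truth(seed = 41)
  qc <- simulate_year(truth, seed = 5)
  scan <- ed_scan(qc, power = 2)
  expect_equal(scan$sites$ed_x, scan$sites$ed^2)
  expect_identical(order(scan$sites$ed_x), order(scan$sites$ed))
  expect_equal(ed_scan(qc, power = 3)$sites$ed_x, scan$sites$ed^3)
})

test_that("the tricube smoother preserves constants and matches the O(n^2) oracle", {
  # constants are reproduced exactly
  pos <- sort(sample.int(1e6, 50))
  expect_equal(fit_profile(pos, rep(3.3, 50), 1e5), rep(3.3, 50))
  # a single site is its own fit
  expect_equal(fit_profile(5e5, 1.7, 1e5), 1.7)
  # full-window fit equals the brute-force weighted mean site by site
  set.seed(13)
  pos <- sort(sample.int(2e6, 101))
  y <- runif(101)
  expect_equal(fit_profile(pos, y, 3e6), brute_fit(pos, y, 3e6),
               tolerance = 1e-12)
  # fitted values stay inside the window's data range
  f <- fit_profile(pos, y, 2e5)
  expect_true(all(f >= min(y) - 1e-12 & f <= max(y) + 1e-12))
  expect_warning(fit_profile(pos, y, 2), "bandwidth")
})

test_that("the threshold is median + 3 SD with location equivariance", {
  f <- c(0, 0, 0, 0, 10)
  th <- ed_threshold(f)
  # hand recomputation: median 0, sample SD sqrt(sum((x - 2)^2) / 4)
  expect_equal(th$median, 0)
  expect_equal(th$sd, sqrt((4 * 4 + 64) / 4))
  expect_equal(th$value, 3 * sqrt(20))
  # constant profile: SD 0, threshold equals the constant
  expect_equal(ed_threshold(rep(2.5, 10))$value, 2.5)
  # adding k shifts the threshold by exactly k
  th2 <- ed_threshold(f + 1.25)
  expect_equal(th2$value, th$value + 1.25)
  expect_error(ed_threshold(1), "2 sites")
})

test_that("region calling finds maximal runs and merges nearby runs", {
  pos <- c(1e6, 2e6, 3e6, 4e6, 5e6)
  expect_identical(nrow(call_regions(pos, rep(0, 5), 1)), 0L)
  all_above <- call_regions(pos, rep(2, 5), 1)
  expect_equal(all_above$start, 1e6)
  expect_equal(all_above$end, 5e6)
  expect_identical(all_above$n_sites, 5L)
  # two runs split by one low site: merged when the gap is small enough
  f <- c(2, 2, 0, 2, 2)
  split <- call_regions(pos, f, 1, merge_gap = 1e6)
  expect_identical(nrow(split), 2L)
  merged <- call_regions(pos, f, 1, merge_gap = 3e6)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$end, 5e6)
  # strict inequality: sites exactly at the threshold stay below
  expect_identical(nrow(call_regions(pos, rep(1, 5), 1)), 0L)
})

test_that("swapping the pools leaves the scan unchanged", {
  truth <- small_truth(seed = 43)
  qc <- simulate_year(truth, seed = 9)
  swapped <- qc
  swapped[c("high_ref", "high_alt", "valid_high")] <-
    qc[c("low_ref", "low_alt", "valid_low")]
  swapped[c("low_ref", "low_alt", "valid_low")] <-
    qc[c("high_ref", "high_alt", "valid_high")]
  a <- ed_scan(qc); b <- ed_scan(swapped)
  expect_equal(a$sites, b$sites)
  expect_equal(a$thresholds, b$thresholds)
  expect_equal(a$regions, b$regions)
})

test_that("a strong QTL lands inside a called region across seeds", {
  # a soybean-scale chromosome: the peak occupies a small fraction of the
  # profile, so the median + 3 SD threshold is driven by background
  hit <- vapply(1:20, function(s) {
    truth <- sim_bsa_panel(200, c(Chr1 = 50e6), snp_per_mb = 15,
                           qtls = list(qtl_spec("Chr1", 25e6, 1)),
                           h2 = 0.8, seed = s)
    qc <- simulate_year(truth, depth = 50, seed = s + 1000)
    covers(ed_scan(qc)$regions, "Chr1", 25e6)
  }, NA)
  expect_gte(sum(hit), 18L)
})

test_that("QTL recovery improves with bulk size and depth", {
  grid_tails <- c(0.05, 0.15, 0.3)
  grid_depth <- c(5, 20, 80)
  rate <- matrix(NA_real_, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    hit <- vapply(1:20, function(s) {
      truth <- sim_bsa_panel(100, c(Chr1 = 10e6), snp_per_mb = 15,
                             qtls = list(qtl_spec("Chr1", 5e6, 0.6)),
                             h2 = 0.6, seed = s)
      qc <- simulate_year(truth, low_q = grid_tails[a],
                          high_q = grid_tails[a],
                          depth = grid_depth[b], seed = 5000 + s)
      covers(ed_scan(qc, bandwidth = 1e6)$regions, "Chr1", 5e6)
    }, NA)
    rate[a, b] <- mean(hit)
  }
  # coverage should not degrade as bulks grow or sequencing deepens
  expect_true(all(diff(rowMeans(rate)) >= -0.05))
  expect_true(all(diff(colMeans(rate)) >= -0.05))
  expect_gte(rate[3, 3], rate[1, 1])
})

test_that("null scans stay almost entirely below median + 3 SD", {
  frac <- vapply(1:20, function(s) {
    truth <- sim_bsa_panel(100, c(Chr1 = 10e6), snp_per_mb = 15,
                           h2 = 0, seed = s)
    qc <- simulate_year(truth, depth = 30, seed = 7000 + s)
    scan <- ed_scan(qc)
    mean(scan$sites$fitted > scan$thresholds$value)
  }, 0)
  expect_lt(mean(frac), 0.02)
})
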