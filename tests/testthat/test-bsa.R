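test_that("contrast score reproduces the worked read-count example", {
  # 110 alt of 111 mutant reads vs 30 alt of (30 + 79) wildtype reads
  s <- data.frame(mut_alt = 110, mut_depth = 111, wt_alt = 30,
                  wt_depth = 109)
  expect_equal(contrast_score(s), 110 / 111 - 30 / 109)
  expect_equal(round(contrast_score(s), 4), 0.7158)

  # trivial endpoints
  eq <- data.frame(mut_alt = 45, mut_depth = 90, wt_alt = 50, wt_depth = 100)
  expect_equal(contrast_score(eq), 0)
  full <- data.frame(mut_alt = 80, mut_depth = 80, wt_alt = 0, wt_depth = 95)
  expect_equal(contrast_score(full), 1)

  # antisymmetric under swapping the pools
  set.seed(3)
  x <- data.frame(mut_depth = 100 + rpois(20, 10), wt_depth = 100 + rpois(20, 10))
  x$mut_alt <- rbinom(20, x$mut_depth, 0.7)
  x$wt_alt <- rbinom(20, x$wt_depth, 0.3)
  sw <- data.frame(mut_alt = x$wt_alt, mut_depth = x$wt_depth,
                   wt_alt = x$mut_alt, wt_depth = x$mut_depth)
  expect_equal(contrast_score(sw), -contrast_score(x))

  # zero depth -> NA with a message
  z <- data.frame(mut_alt = 0, mut_depth = 0, wt_alt = 5, wt_depth = 10)
  expect_message(out <- contrast_score(z), "zero depth")
  expect_true(is.na(out))
  bad <- data.frame(mut_alt = 5, mut_depth = 4, wt_alt = 0, wt_depth = 10)
  expect_error(contrast_score(bad), "alt")
})

test_that("linkage track filters, smooths, and normalizes as specified", {
  # depth filter: 10 sites, 3 with depth 80 in one pool, min_depth 100
  s <- data.frame(chrom = "c1", pos = seq(1e5, 1e6, length.out = 10),
                  mut_depth = c(rep(120, 7), rep(80, 3)),
                  wt_depth = 120, mut_alt = 110, wt_alt = 30,
                  impact = "NONE")
  tr <- build_linkage_track(s, min_depth = 100, window_bp = 1)
  expect_equal(nrow(tr), 7)

  # all 0.5/0.5 -> all-zero normalized track
  flat <- data.frame(chrom = "c1", pos = seq(1e5, 1e6, length.out = 10),
                     mut_depth = 200, wt_depth = 200, mut_alt = 100,
                     wt_alt = 100, impact = "NONE")
  trf <- build_linkage_track(flat)
  expect_true(all(trf$normalized == 0))

  # windowed mean verified against direct averaging, per chromosome
  set.seed(8)
  s2 <- data.frame(chrom = rep(c("c1", "c2"), each = 30),
                   pos = rep(sort(sample(1e6, 30)), 2),
                   mut_depth = 150, wt_depth = 150)
  s2$mut_alt <- rbinom(60, 150, 0.8)
  s2$wt_alt <- rbinom(60, 150, 0.3)
  w <- 2e5
  tr2 <- build_linkage_track(s2, window_bp = w)
  for (i in seq_len(nrow(tr2))) {
    j <- tr2$chrom == tr2$chrom[i] & abs(tr2$pos - tr2$pos[i]) <= w / 2
    expect_equal(tr2$smoothed[i], mean(tr2$raw[j]))
  }
  expect_equal(max(tr2$normalized), 1)

  expect_error(build_linkage_track(s[8:10, ], min_depth = 100),
               "no sites survive")
})

test_that("peak region follows the fraction-of-max run rule", {
  # derived run enumeration: scores [0.1, 0.95, 1.0, 0.92, 0.3] at 1..5 Mb
  s <- data.frame(chrom = "c1", pos = (1:5) * 1e6, mut_depth = 1000,
                  wt_depth = 1000, wt_alt = 0, impact = "NONE")
  s$mut_alt <- c(100, 950, 1000, 920, 300)
  tr <- build_linkage_track(s, window_bp = 1)
  expect_equal(tr$normalized, c(0.1, 0.95, 1.0, 0.92, 0.3))
  pk <- find_peak_region(tr, frac_of_max = 0.9)
  expect_equal(pk, list(chrom = "c1", start = 2e6, end = 4e6))

  # single site at the max
  pk1 <- find_peak_region(tr, frac_of_max = 0.99)
  expect_equal(pk1$start, 3e6)
  expect_equal(pk1$end, 3e6)

  # max on the second chromosome -> region on that chromosome
  s2 <- rbind(s, data.frame(chrom = "c2", pos = (1:3) * 1e6,
                            mut_depth = 1000, wt_depth = 1000,
                            wt_alt = 0, impact = "NONE",
                            mut_alt = c(990, 1000, 990)))
  pk2 <- find_peak_region(build_linkage_track(s2, window_bp = 1), 0.9)
  expect_equal(pk2$chrom, "c2")

  expect_error(find_peak_region(build_linkage_track(
    data.frame(chrom = "c1", pos = 1:3 * 1e5, mut_depth = 200,
               wt_depth = 200, mut_alt = 100, wt_alt = 100),
    window_bp = 1)), "all-zero")
})

test_that("candidate filtering and impact-ranked ordering", {
  region <- list(chrom = "c1", start = 1e6, end = 2e6)
  sites <- data.frame(
    chrom = "c1",
    pos = c(1.1e6, 1.2e6, 1.3e6, 1.4e6, 1.5e6, 2.5e6),
    mut_depth = c(100, 100, 100, 100, 4, 100),
    wt_depth = c(100, 100, 100, 4, 100, 100),
    mut_alt = c(95, 95, 50, 95, 95, 95),
    wt_alt = c(30, 20, 50, 10, 10, 0),
    impact = c("HIGH", "MODERATE", "HIGH", "HIGH", "HIGH", "HIGH"))
  cand <- candidate_variants(sites, region, min_depth = 5,
                             hom_threshold = 0.9)
  # v3 fails homozygosity; depth-4 sites fail min_depth; 2.5 Mb outside
  expect_equal(cand$pos, c(1.1e6, 1.2e6))
  expect_equal(cand$impact, c("HIGH", "MODERATE"))
  expect_equal(cand$mut_alt_freq, c(0.95, 0.95))

  # contrast tie-break within an impact class
  s2 <- data.frame(chrom = "c1", pos = c(1.1e6, 1.2e6),
                   mut_depth = 100, wt_depth = 100,
                   mut_alt = c(95, 98), wt_alt = c(10, 10),
                   impact = "HIGH")
  c2 <- candidate_variants(s2, region)
  expect_equal(c2$pos[1], 1.2e6)   # larger contrast first

  none <- candidate_variants(sites[0, ], region)
  expect_equal(nrow(none), 0L)
})

test_that("a default simulated cross maps to the causal chromosome and site", {
  sim <- generate_pool_counts(cross_sim_params(seed = 2024))
  tr <- build_linkage_track(sim$sites)
  expect_equal(max(tr$normalized), 1)
  pk <- find_peak_region(tr)
  expect_equal(pk$chrom, sim$truth$causal_chrom)
  # localization at the scale the cross supports (~half a chromosome)
  imax <- which.max(tr$smoothed)
  expect_equal(tr$chrom[imax], sim$truth$causal_chrom)
  cand <- candidate_variants(sim$sites, pk)
  expect_gt(nrow(cand), 0)
  expect_equal(cand$chrom[1], sim$truth$causal_chrom)
  expect_equal(cand$pos[1], sim$truth$causal_pos)
})
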