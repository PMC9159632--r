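# A clean fitted ellipse feature to hang geometry tests on.
ellipse_feature <- function(a = 20, b = 10, theta = 0, nr = 90, nc = 90) {
  m <- oracle_ellipse_mask(nr, nc, nr / 2, nc / 2, a, b, theta)
  extract_features(m)$features
}

test_that("pairing assigns each punctum to its max-overlap organelle", {
  grl <- matrix(FALSE, 40, 40)
  grl[5:15, 5:15] <- TRUE       # label A (smaller label by position)
  grl[5:15, 20:30] <- TRUE      # label B
  # mdl feature shares 6 px with A and 2 px with B (via two lobes)
  mdl <- matrix(FALSE, 40, 40)
  mdl[10, 10:15] <- TRUE        # 6 px in A
  mdl[10, 16:21] <- TRUE        # bridge + 2 px in B
  gf <- extract_features(grl, min_area = 1)
  mf <- extract_features(mdl, min_area = 1)
  a_label <- gf$features$label[which.min(gf$features$centroid_c)]
  pr <- pair_features(gf, mf)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$grl_label, a_label)
  expect_equal(pr$shared_pixels, 6L)

  # disjoint sets -> no pairs; punctum inside an ellipse -> one pair
  empty <- pair_features(gf, extract_features(matrix(FALSE, 40, 40)))
  expect_equal(nrow(empty), 0L)
})

test_that("tip angle follows the figure conventions", {
  f <- ellipse_feature(theta = 0)
  ctr <- c(f$centroid_r, f$centroid_c)
  # displacement along the long axis -> 0; along the short axis -> 90
  along <- mucocyst_pair(f, ctr + c(0, 8))
  expect_equal(along$angle_deg, 0)
  short <- mucocyst_pair(f, ctr + c(-6, 0))
  expect_equal(short$angle_deg, 90)
  # circular fit, displacement at 45 degrees -> 45
  circ <- data.frame(centroid_r = 50, centroid_c = 50, major_axis_len = 20,
                     minor_axis_len = 20, orientation_deg = 0)
  diag45 <- mucocyst_pair(circ, c(50 - 5, 50 + 5))
  expect_equal(diag45$angle_deg, 45)
  # folding: reversing the displacement leaves the angle unchanged
  p1 <- mucocyst_pair(f, ctr + c(-3, 5))
  p2 <- mucocyst_pair(f, ctr - c(-3, 5))
  expect_equal(p1$angle_deg, p2$angle_deg)
  # coincident centroids: angle undefined, offset zero
  p0 <- mucocyst_pair(f, ctr)
  expect_true(is.na(p0$angle_deg))
  expect_equal(p0$offset_norm, 0)
})

test_that("normalized offset is distance over half the major axis", {
  f <- ellipse_feature(theta = 30)
  ctr <- c(f$centroid_r, f$centroid_c)
  th <- f$orientation_deg * pi / 180
  L <- f$major_axis_len
  # at the vertex of the fitted long axis -> exactly 1
  vertex <- ctr + (L / 2) * c(-sin(th), cos(th))
  expect_equal(mucocyst_pair(f, vertex)$offset_norm, 1)
  # half the semi-major length -> 0.5
  halfway <- ctr + (L / 4) * c(-sin(th), cos(th))
  expect_equal(mucocyst_pair(f, halfway)$offset_norm, 0.5)
  expect_equal(mucocyst_pair(f, vertex)$angle_deg, 0, tolerance = 1e-8)
})

test_that("within-organelle null matches analytic disk oracles", {
  circ <- data.frame(centroid_r = 0, centroid_c = 0, major_axis_len = 24,
                     minor_axis_len = 24, orientation_deg = 0)
  pair <- mucocyst_pair(circ, c(0, 5))
  R <- 1e5
  nul <- randomize_within_mucocyst(pair, R = R, seed = 11)
  # E[r] for a uniform unit disk = 2/3, sd = sqrt(1/2 - 4/9)
  se_off <- sqrt(1 / 2 - 4 / 9) / sqrt(R)
  expect_lt(abs(mean(nul$null_offsets) - 2 / 3), 3 * se_off)
  # angles Uniform(0, 90) by rotational symmetry: mean 45
  se_ang <- (90 / sqrt(12)) / sqrt(R)
  expect_lt(abs(mean(nul$null_angles) - 45), 3 * se_ang)
  expect_true(all(nul$null_offsets <= 1 + 1e-12))
  expect_true(all(nul$null_angles >= 0 & nul$null_angles <= 90))
  # determinism
  n2 <- randomize_within_mucocyst(pair, R = 100, seed = 3)
  n3 <- randomize_within_mucocyst(pair, R = 100, seed = 3)
  expect_identical(n2$null_offsets, n3$null_offsets)
})

test_that("two-sample KS statistic and p-value", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:4, 11:14)$statistic, 1)
  # derived by pooled-ECDF enumeration
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(2, 3, 4, 5))$statistic, 0.25)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")

  # cross-check statistic and asymptotic p against stats::ks.test
  set.seed(14)
  for (k in 1:5) {
    x <- rnorm(40); y <- rnorm(60, mean = 0.4)
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("offset recovery is monotone in the true tip bias", {
  med <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(beta) {
    offs <- c()
    for (seed in 1:3) {
      sim <- generate_cell_image(fast_sim_params(tip_bias = beta,
                                                 seed = 400 + seed))
      grl <- segment_channel(sim$micrograph, "grl", 0.25)
      mdl <- segment_channel(sim$micrograph, "mdl", 0.25)
      offs <- c(offs, pair_features(grl, mdl)$offset_norm)
    }
    median(offs)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  expect_lt(med[1], 0.3)
  expect_gt(med[5], 0.8)
})

test_that("full analysis pools pairs and reports both KS tests", {
  sim <- generate_cell_image(fast_sim_params(seed = 55))
  an <- tip_localization_analysis(sim$micrograph, R = 300, seed = 5)
  expect_gt(an$n_pairs, 3)
  expect_lt(an$ks_offset$p.value, 0.01)   # beta = 0.9 is strongly tip-biased
  expect_lt(an$ks_angle$p.value, 0.01)
  expect_length(an$null_offsets, 300 * an$n_pairs)
  h <- tip_histograms(an)
  expect_equal(sum(h$offset$observed), an$n_pairs)
  expect_equal(h$angle$bin_lo[1], 0)
})
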