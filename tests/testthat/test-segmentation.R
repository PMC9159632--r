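test_that("adaptive threshold matches the brute-force windowed-mean oracle", {
  # derived fixture: zero image with one bright block, large window
  img <- matrix(0, 100, 100)
  img[41:50, 31:40] <- 100
  got <- adaptive_threshold(img, 0.5, 51)
  want <- oracle_adaptive_threshold(img, 0.5, 51)
  expect_identical(got, want)
  # the oracle says the mask is exactly the block
  block <- matrix(FALSE, 100, 100); block[41:50, 31:40] <- TRUE
  expect_identical(got, block)

  # random image, smaller window, several sensitivities
  set.seed(31)
  img2 <- matrix(runif(30 * 24), 30, 24)
  for (s in c(0, 0.15, 0.6)) {
    expect_identical(adaptive_threshold(img2, s, 7),
                     oracle_adaptive_threshold(img2, s, 7))
  }
})

test_that("adaptive threshold degenerate and monotone behaviour", {
  const <- matrix(3.7, 20, 20)
  expect_false(any(adaptive_threshold(const, 0, 5)))
  expect_false(any(adaptive_threshold(const, 0.9, 5)))

  set.seed(7)
  img <- matrix(runif(40 * 40), 40, 40)
  m_loose <- adaptive_threshold(img, 0.2, 11)
  m_tight <- adaptive_threshold(img, 0.8, 11)
  expect_true(all(m_loose[m_tight]))   # tight mask is a subset

  expect_error(adaptive_threshold(img, 0.5, 4), "odd")
  expect_error(adaptive_threshold(img, 0.5, 1), "odd")
  img[3, 3] <- NA
  expect_error(adaptive_threshold(img, 0.5, 5), "non-finite")
})

test_that("clean_mask agrees with set-arithmetic morphology oracles", {
  set.seed(11)
  mask <- matrix(FALSE, 25, 25)
  mask[6:12, 6:12] <- TRUE
  mask[16:20, 14:19] <- TRUE
  mask[8, 18] <- TRUE                       # isolated pixel
  for (r in 1:2) {
    se <- disc_se <- EBImage::makeBrush(2 * r + 1, "disc") > 0
    want <- oracle_close(oracle_open(mask, se), se)
    expect_identical(clean_mask(mask, r, r), want)
  }
})

test_that("clean_mask identity, singleton removal, and corner clipping", {
  mask <- matrix(runif(15 * 15) > 0.6, 15, 15)
  expect_identical(clean_mask(mask, 0, 0), mask)

  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_false(any(clean_mask(single, 1, 0)))

  # a 20x20 solid square survives radius-1 opening+closing exactly;
  # radius-2 disc opening clips its corners (frozen from the oracle)
  sq <- matrix(FALSE, 40, 40); sq[11:30, 11:30] <- TRUE
  expect_identical(clean_mask(sq, 1, 1), sq)
  se2 <- EBImage::makeBrush(5, "disc") > 0
  want2 <- oracle_close(oracle_open(sq, se2), se2)
  got2 <- clean_mask(sq, 2, 2)
  expect_identical(got2, want2)
  expect_false(got2[11, 11])   # corner is gone
  expect_true(all(got2[13:28, 13:28]))
})

test_that("extract_features labels 8-connected components like the BFS oracle", {
  set.seed(5)
  mask <- matrix(runif(30 * 30) > 0.7, 30, 30)
  want <- oracle_label8(mask)
  fs <- extract_features(mask, min_area = 1)
  expect_equal(nrow(fs$features), max(want))
  # identical partitions up to label permutation
  got <- fs$label_image
  expect_true(all((got > 0) == (want > 0)))
  for (l in seq_len(max(want))) {
    expect_length(unique(got[want == l]), 1L)
  }

  # diagonal-only touching pixels form one component
  diagm <- matrix(FALSE, 5, 5); diagm[2, 2] <- TRUE; diagm[3, 3] <- TRUE
  expect_equal(nrow(extract_features(diagm, min_area = 1)$features), 1L)
})

test_that("extract_features basic geometry and filtering", {
  expect_equal(nrow(extract_features(matrix(FALSE, 10, 10))$features), 0L)

  two <- matrix(FALSE, 30, 30)
  two[5:9, 5:9] <- TRUE
  two[20:24, 12:16] <- TRUE
  fs <- extract_features(two)
  expect_equal(nrow(fs$features), 2L)
  expect_equal(sort(fs$features$centroid_r), c(7, 22))
  expect_equal(sort(fs$features$centroid_c), c(7, 14))

  # min_area drops small components
  small <- matrix(FALSE, 10, 10); small[2, 2:3] <- TRUE; small[6:8, 6:8] <- TRUE
  fs2 <- extract_features(small, min_area = 4)
  expect_equal(nrow(fs2$features), 1L)
  expect_equal(fs2$features$area, 9)
  expect_equal(sort(unique(as.vector(fs2$label_image))), c(0L, 1L))

  # cell-mask restriction
  cm <- matrix(FALSE, 30, 30); cm[1:15, ] <- TRUE
  fs3 <- extract_features(two, cm)
  expect_equal(nrow(fs3$features), 1L)
  expect_equal(fs3$features$centroid_r, 7)
})

test_that("moment ellipse fit recovers rendered ellipse parameters", {
  # axis-aligned ellipse, semi-axes 20 and 10 px
  m <- oracle_ellipse_mask(90, 90, 45, 45, 20, 10, 0)
  fs <- extract_features(m)
  f <- fs$features
  expect_equal(nrow(f), 1L)
  expect_lt(min(abs(f$orientation_deg - c(0, 180))), 1)
  expect_lt(abs(f$major_axis_len - 40) / 40, 0.02)
  expect_lt(abs(f$minor_axis_len - 20) / 20, 0.03)

  # property: 20 random elongated ellipses (the regime the organelle
  # fits live in; orientation is ill-conditioned for near-circles)
  # recovered within 2 deg / 3%
  set.seed(99)
  for (k in 1:20) {
    a <- runif(1, 12, 20); b <- runif(1, 5, a * 0.8)
    th <- runif(1, 0, 180)
    m <- oracle_ellipse_mask(80, 80, runif(1, 35, 45), runif(1, 35, 45),
                             a, b, th)
    f <- extract_features(m)$features
    expect_equal(nrow(f), 1L)
    dang <- min(abs(f$orientation_deg - th),
                180 - abs(f$orientation_deg - th))
    expect_lt(dang, 2)
    expect_lt(abs(f$major_axis_len - 2 * a) / (2 * a), 0.03)
    expect_lt(abs(f$minor_axis_len - 2 * b) / (2 * b), 0.03)
  }
})

test_that("feature count is nonincreasing in sensitivity", {
  sim <- generate_cell_image(fast_sim_params(seed = 21))
  counts <- vapply(c(0.1, 0.2, 0.3, 0.45, 0.6), function(s) {
    nrow(segment_channel(sim$micrograph, "mdl", s)$features)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
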