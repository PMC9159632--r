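#' Pair overlapping Grl and Mdl features
#'
#' Each Mdl feature sharing at least one pixel with a Grl feature yields
#' exactly one pair, assigned to the Grl feature with the largest
#' shared-pixel count (ties broken toward the smaller Grl label). Mdl
#' features with no overlap yield no pair.
#'
#' @param grl,mdl `"feature_set"` objects from same-shape images.
#' @return A `"mucocyst_pairs"` data frame with one row per pair:
#'   identifiers, shared-pixel count, the Grl ellipse parameters, both
#'   centroids, and the derived `angle_deg` ([tip_angle()], `NA` when the
#'   centroids coincide) and `offset_norm` ([tip_offset()]).
#' @export
pair_features <- function(grl, mdl) {
  stopifnot(inherits(grl, "feature_set"), inherits(mdl, "feature_set"))
  if (!identical(dim(grl$label_image), dim(mdl$label_image))) {
    stop("feature sets come from images of different shapes", call. = FALSE)
  }
  idx <- which(mdl$label_image > 0L & grl$label_image > 0L)
  empty <- structure(
    data.frame(mdl_label = integer(), grl_label = integer(),
               shared_pixels = integer(), grl_centroid_r = numeric(),
               grl_centroid_c = numeric(), grl_major_axis_len = numeric(),
               grl_minor_axis_len = numeric(), grl_orientation_deg = numeric(),
               mdl_centroid_r = numeric(), mdl_centroid_c = numeric(),
               angle_deg = numeric(), offset_norm = numeric()),
    class = c("mucocyst_pairs", "data.frame"))
  if (length(idx) == 0L) return(empty)
  shared <- table(mdl = mdl$label_image[idx], grl = grl$label_image[idx])
  mdl_labels <- as.integer(rownames(shared))
  grl_labels <- as.integer(colnames(shared))
  best <- vapply(seq_along(mdl_labels), function(i) {
    counts <- shared[i, ]
    j <- which(counts == max(counts))
    j[which.min(grl_labels[j])]   # tie -> smaller Grl label
  }, integer(1))
  gi <- match(grl_labels[best], grl$features$label)
  mi <- match(mdl_labels, mdl$features$label)
  out <- data.frame(
    mdl_label = mdl_labels,
    grl_label = grl_labels[best],
    shared_pixels = as.integer(shared[cbind(seq_along(mdl_labels), best)]),
    grl_centroid_r = grl$features$centroid_r[gi],
    grl_centroid_c = grl$features$centroid_c[gi],
    grl_major_axis_len = grl$features$major_axis_len[gi],
    grl_minor_axis_len = grl$features$minor_axis_len[gi],
    grl_orientation_deg = grl$features$orientation_deg[gi],
    mdl_centroid_r = mdl$features$centroid_r[mi],
    mdl_centroid_c = mdl$features$centroid_c[mi]
  )
  out$angle_deg <- tip_angle(out)
  out$offset_norm <- tip_offset(out)
  class(out) <- c("mucocyst_pairs", "data.frame")
  out
}

#' Construct a pair from a fitted Grl feature and a point Mdl centroid
#'
#' Convenience constructor for worked examples and fixtures: takes one
#' row of a feature table as the Grl organelle and an explicit `(row,
#' col)` point as the Mdl centroid.
#'
#' @param grl_feature One-row data frame with `centroid_r, centroid_c,
#'   major_axis_len, minor_axis_len, orientation_deg` (e.g. one row of
#'   `feature_set$features`).
#' @param mdl_centroid Numeric `(row, col)` of the punctum centroid.
#' @return A one-row `"mucocyst_pairs"` data frame.
#' @export
mucocyst_pair <- function(grl_feature, mdl_centroid) {
  stopifnot(nrow(grl_feature) == 1L, length(mdl_centroid) == 2L)
  out <- data.frame(
    mdl_label = 1L, grl_label = 1L, shared_pixels = 1L,
    grl_centroid_r = grl_feature$centroid_r,
    grl_centroid_c = grl_feature$centroid_c,
    grl_major_axis_len = grl_feature$major_axis_len,
    grl_minor_axis_len = grl_feature$minor_axis_len,
    grl_orientation_deg = grl_feature$orientation_deg,
    mdl_centroid_r = mdl_centroid[1], mdl_centroid_c = mdl_centroid[2]
  )
  out$angle_deg <- tip_angle(out)
  out$offset_norm <- tip_offset(out)
  class(out) <- c("mucocyst_pairs", "data.frame")
  out
}

#' Angle between the Grl long axis and the centroid-connecting segment
#'
#' The acute angle in \[0, 90\] degrees between the (undirected) major
#' axis of the Grl ellipse and the segment joining the Grl and Mdl
#' centroids: 0 means the punctum lies along the long axis, 90 along the
#' short axis. `NA` when the centroids coincide (the angle is
#' undefined; such pairs are excluded from angle statistics).
#'
#' @param pairs A `"mucocyst_pairs"` data frame (vectorized over rows).
#' @return Numeric vector of angles in degrees.
#' @export
tip_angle <- function(pairs) {
  dx <- pairs$mdl_centroid_c - pairs$grl_centroid_c
  dy <- -(pairs$mdl_centroid_r - pairs$grl_centroid_r)
  out <- rep(NA_real_, nrow(pairs))
  ok <- dx != 0 | dy != 0
  out[ok] <- acute_angle(atan2(dy[ok], dx[ok]) * 180 / pi,
                         pairs$grl_orientation_deg[ok])
  out
}

#' Normalized centroid offset
#'
#' Euclidean distance between the Grl and Mdl centroids divided by half
#' the Grl major-axis length: 0 at the organelle centroid, 1 exactly at
#' the tip (the vertex of the fitted ellipse's long axis).
#'
#' @param pairs A `"mucocyst_pairs"` data frame (vectorized over rows).
#' @return Numeric vector of non-negative normalized offsets.
#' @export
tip_offset <- function(pairs) {
  if (any(pairs$grl_major_axis_len <= 0)) {
    stop("degenerate Grl ellipse fit: zero major axis", call. = FALSE)
  }
  d <- sqrt((pairs$mdl_centroid_c - pairs$grl_centroid_c)^2 +
              (pairs$mdl_centroid_r - pairs$grl_centroid_r)^2)
  d / (pairs$grl_major_axis_len / 2)
}

#' Within-organelle randomization null for angle and offset
#'
#' Samples `R` points uniformly over the interior of the fitted Grl
#' ellipse (rejection sampling from its bounding box) and recomputes the
#' angle and normalized offset with each point as the Mdl centroid.
#' For a circular organelle the null offset has mean 2/3 and the null
#' angle is Uniform(0, 90).
#'
#' @param pair One row of a `"mucocyst_pairs"` data frame.
#' @param R Number of null points.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list with `null_angles`, `null_offsets` (length `R`), `R`,
#'   `seed`.
#' @export
randomize_within_mucocyst <- function(pair, R = 1000L, seed = NULL) {
  stopifnot(nrow(pair) == 1L)
  stopifnot_scalar_number(R, "R", lower = 1)
  R <- as.integer(R)
  a <- pair$grl_major_axis_len / 2
  b <- pair$grl_minor_axis_len / 2
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("degenerate Grl ellipse: cannot build the randomization null",
         call. = FALSE)
  }
  with_seed_opt(seed, {
    u <- numeric(0); v <- numeric(0)
    while (length(u) < R) {
      need <- R - length(u)
      m <- ceiling(need / (pi / 4)) + 8L   # ~ acceptance rate pi/4
      uu <- stats::runif(m, -a, a); vv <- stats::runif(m, -b, b)
      ok <- (uu / a)^2 + (vv / b)^2 <= 1
      u <- c(u, uu[ok]); v <- c(v, vv[ok])
    }
    u <- u[seq_len(R)]; v <- v[seq_len(R)]
    list(null_angles = atan2(abs(v), abs(u)) * 180 / pi,
         null_offsets = sqrt(u^2 + v^2) / a,
         R = R, seed = seed)
  })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over the pooled sample points of the absolute
#' difference between the two empirical CDFs (which handles ties); the
#' p-value comes from the asymptotic Kolmogorov distribution evaluated
#' at `sqrt(n1 n2 / (n1 + n2)) * D`.
#'
#' @param observed,null Non-empty numeric samples.
#' @return A list with `statistic` (`D` in \[0, 1\]), `p.value`, `n1`,
#'   `n2`.
#' @examples
#' ks_two_sample(c(1, 2, 3, 4), c(2, 3, 4, 5))$statistic  # 0.25
#' @export
ks_two_sample <- function(observed, null) {
  observed <- observed[is.finite(observed)]
  null <- null[is.finite(null)]
  if (length(observed) == 0L || length(null) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  pooled <- sort(unique(c(observed, null)))
  d <- max(abs(stats::ecdf(observed)(pooled) - stats::ecdf(null)(pooled)))
  n1 <- length(observed); n2 <- length(null)
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * d
  p <- if (lambda < 1e-10) 1 else {
    k <- seq_len(100L)
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  list(statistic = d, p.value = p, n1 = n1, n2 = n2)
}

#' Full tip-localization analysis of one micrograph
#'
#' Segments both channels, pairs overlapping features, pools the
#' observed angle and offset statistics, builds the pooled
#' within-organelle randomization null (`R` points per pair), and tests
#' observed vs null with the two-sided two-sample KS test, separately
#' for offsets and for angles. Pairs with coincident centroids are
#' excluded from the angle sample (and counted) but retained, with
#' offset 0, in the offset sample.
#'
#' @param micrograph A [micrograph()].
#' @param grl_sensitivity,mdl_sensitivity Channel segmentation
#'   sensitivities.
#' @param R Null points per pair.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param window,min_area Segmentation parameters.
#' @return A list with `pairs`, `null_angles`, `null_offsets`,
#'   `ks_offset`, `ks_angle`, `n_pairs`, `n_angle_undefined`.
#' @export
tip_localization_analysis <- function(micrograph, grl_sensitivity = 0.25,
                                      mdl_sensitivity = 0.25, R = 1000L,
                                      seed = NULL, window = 51L,
                                      min_area = 4L) {
  grl <- segment_channel(micrograph, "grl", grl_sensitivity, window, min_area)
  mdl <- segment_channel(micrograph, "mdl", mdl_sensitivity, window, min_area)
  pairs <- pair_features(grl, mdl)
  analyze_pairs(pairs, R = R, seed = seed)
}

#' Tip statistics and KS tests for a pre-built set of pairs
#'
#' @param pairs A `"mucocyst_pairs"` data frame (possibly pooled across
#'   cells).
#' @inheritParams tip_localization_analysis
#' @return Same structure as [tip_localization_analysis()].
#' @export
analyze_pairs <- function(pairs, R = 1000L, seed = NULL) {
  if (nrow(pairs) == 0L) {
    stop("no overlapping feature pairs to analyze", call. = FALSE)
  }
  nulls <- with_seed_opt(seed, {
    lapply(seq_len(nrow(pairs)), function(i) {
      randomize_within_mucocyst(pairs[i, , drop = FALSE], R = R, seed = NULL)
    })
  })
  null_angles <- unlist(lapply(nulls, `[[`, "null_angles"))
  null_offsets <- unlist(lapply(nulls, `[[`, "null_offsets"))
  ang <- pairs$angle_deg[!is.na(pairs$angle_deg)]
  ks_angle <- if (length(ang) > 0) ks_two_sample(ang, null_angles) else NULL
  list(pairs = pairs,
       null_angles = null_angles, null_offsets = null_offsets,
       ks_offset = ks_two_sample(pairs$offset_norm, null_offsets),
       ks_angle = ks_angle,
       n_pairs = nrow(pairs),
       n_angle_undefined = sum(is.na(pairs$angle_deg)))
}

#' Histogram bin tables for tip statistics
#'
#' Counts observed and null values in fixed-width bins (10 degrees for
#' angles, 0.1 for offsets), with null counts rescaled to the observed
#' sample size for side-by-side display.
#'
#' @param analysis Result of [tip_localization_analysis()] or
#'   [analyze_pairs()].
#' @param angle_bin,offset_bin Bin widths.
#' @return A list of two data frames, `angle` and `offset`, with columns
#'   `bin_lo, bin_hi, observed, null_expected`.
#' @export
tip_histograms <- function(analysis, angle_bin = 10, offset_bin = 0.1) {
  bin_table <- function(obs, null, width, upper) {
    breaks <- seq(0, upper, by = width)
    if (max(c(obs, null, upper)) > upper) {
      breaks <- c(breaks, max(c(obs, null)) + width)
    }
    oc <- table(cut(obs, breaks, include.lowest = TRUE, right = FALSE))
    nc <- table(cut(null, breaks, include.lowest = TRUE, right = FALSE))
    data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
               observed = as.integer(oc),
               null_expected = as.numeric(nc) * length(obs) / length(null))
  }
  ang <- analysis$pairs$angle_deg[!is.na(analysis$pairs$angle_deg)]
  list(angle = bin_table(ang, analysis$null_angles, angle_bin, 90),
       offset = bin_table(analysis$pairs$offset_norm,
                          analysis$null_offsets, offset_bin, 1))
}
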