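#' Adaptive (local-mean) thresholding
#'
#' A pixel is foreground iff
#' `I(x) > mean_w(x) + s * (max(I) - min(I))`, where `mean_w` is the mean
#' over the `window`-sized square centred on the pixel (edge pixels use
#' the in-bounds part of the window) and the range is taken over the
#' whole image. The sensitivity `s` is a dimensionless, image-scale-free
#' knob: the mask is monotone non-increasing in `s` by construction, so
#' lowering the sensitivity never removes foreground pixels.
#'
#' @param image Numeric matrix with finite values.
#' @param sensitivity Sensitivity `s` in \[0, 1\].
#' @param window Odd window side length in pixels, `>= 3`.
#' @return Logical matrix of the same dimensions.
#' @examples
#' img <- matrix(0, 20, 20); img[8:12, 8:12] <- 1
#' sum(adaptive_threshold(img, 0.5, 11))
#' @export
adaptive_threshold <- function(image, sensitivity, window = 51L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop("`image` contains non-finite pixels", call. = FALSE)
  }
  stopifnot_scalar_number(sensitivity, "sensitivity", lower = 0, upper = 1)
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 3L ||
      window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  mu <- local_mean(image, (window - 1L) %/% 2L)
  image > mu + sensitivity * (max(image) - min(image))
}

# Box mean with edge truncation via a summed-area table: each pixel's
# mean is over the in-bounds part of the (2h+1)-sided window. The
# global mean is subtracted before accumulation so a constant image
# yields an exactly constant windowed mean (no cancellation error).
local_mean <- function(m, h) {
  mbar <- mean(m)
  m <- m - mbar
  nr <- nrow(m); nc <- ncol(m)
  sat <- function(x) {
    s <- apply(x, 2L, cumsum)
    s <- t(apply(s, 1L, cumsum))
    rbind(0, cbind(0, s))  # (nr+1) x (nc+1), zero-padded
  }
  S <- sat(m)
  box <- function(S) {
    r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
    c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
    S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
      S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  }
  sums <- box(S)
  counts <- box(sat(matrix(1, nr, nc)))
  sums / counts + mbar
}

#' Morphological cleanup of a binary mask
#'
#' Binary opening with a disc of radius `opening_radius` followed by
#' closing with a disc of radius `closing_radius` (EBImage disc brushes);
#' radius 0 skips that step.
#'
#' @param mask Logical matrix.
#' @param opening_radius,closing_radius Non-negative integer radii in px.
#' @return Logical matrix of the same dimensions.
#' @export
clean_mask <- function(mask, opening_radius = 1L, closing_radius = 1L) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  stopifnot_scalar_number(opening_radius, "opening_radius", lower = 0)
  stopifnot_scalar_number(closing_radius, "closing_radius", lower = 0)
  out <- mask * 1.0
  if (opening_radius >= 1) {
    out <- EBImage::opening(out, disc_brush(opening_radius))
  }
  if (closing_radius >= 1) {
    out <- EBImage::closing(out, disc_brush(closing_radius))
  }
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

# 8-connected labelling: EBImage::bwlabel (4-connected) followed by a
# union-find merge of label pairs that touch diagonally.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1.0)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  K <- max(lab)
  if (K <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(K)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(K), find, 1L)
  newid <- match(root, sort(unique(root)))
  lab[lab > 0L] <- newid[lab[lab > 0L]]
  lab
}

#' Extract measured features from a binary mask
#'
#' Labels 8-connected components of `mask` restricted to `cell_mask`,
#' drops components smaller than `min_area`, and fits each with a
#' moment-matched ellipse: the centroid is the intensity-unweighted pixel
#' mean; the orientation is `atan2(2 mu11, mu20 - mu02) / 2` mapped to
#' \[0, 180) degrees (counterclockwise from the +column axis, rows
#' pointing "down"); the axis lengths are `4 * sqrt(eigenvalue)` of the
#' area-normalized second central moment matrix, so a rendered solid
#' ellipse recovers its full axis lengths.
#'
#' @param mask Logical matrix of foreground pixels.
#' @param cell_mask Optional logical matrix; components are restricted to
#'   it (`NULL` keeps the whole image).
#' @param min_area Minimum component area in px^2.
#' @return A `"feature_set"`: list with `features` (data frame: `label,
#'   area, centroid_r, centroid_c, major_axis_len, minor_axis_len,
#'   orientation_deg`), `label_image` (integer matrix, 0 = background),
#'   `channel`, `sensitivity`.
#' @examples
#' m <- matrix(FALSE, 30, 30); m[5:9, 5:9] <- TRUE; m[20:24, 12:16] <- TRUE
#' extract_features(m)$features$area
#' @export
extract_features <- function(mask, cell_mask = NULL, min_area = 4L) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!is.null(cell_mask)) {
    if (!identical(dim(cell_mask), dim(mask))) {
      stop("`cell_mask` must match `mask` dimensions", call. = FALSE)
    }
    mask <- mask & cell_mask
  }
  lab <- label_components_8(mask)
  empty <- list(features = data.frame(label = integer(), area = numeric(),
                                      centroid_r = numeric(),
                                      centroid_c = numeric(),
                                      major_axis_len = numeric(),
                                      minor_axis_len = numeric(),
                                      orientation_deg = numeric()),
                label_image = lab, channel = NA_character_,
                sensitivity = NA_real_)
  class(empty) <- "feature_set"
  if (max(lab) == 0L) return(empty)

  idx <- which(lab > 0L)
  ij <- arrayInd(idx, dim(lab))
  g <- lab[idx]
  area <- tabulate(g)
  keep <- which(area >= min_area)
  if (length(keep) == 0L) {
    empty$label_image <- matrix(0L, nrow(lab), ncol(lab))
    return(empty)
  }

  cen_r <- rowsum(ij[, 1], g)[, 1] / area
  cen_c <- rowsum(ij[, 2], g)[, 1] / area
  # central second moments in maths coords (x = col, y = -row)
  dxy <- cbind((ij[, 2] - cen_c[g]), -(ij[, 1] - cen_r[g]))
  mu20 <- rowsum(dxy[, 1]^2, g)[, 1] / area
  mu02 <- rowsum(dxy[, 2]^2, g)[, 1] / area
  mu11 <- rowsum(dxy[, 1] * dxy[, 2], g)[, 1] / area
  tr <- mu20 + mu02
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr / 2 + disc
  l2 <- pmax(tr / 2 - disc, 0)
  orient <- fold_180(0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi)

  feats <- data.frame(label = seq_along(area), area = area,
                      centroid_r = cen_r, centroid_c = cen_c,
                      major_axis_len = 4 * sqrt(l1),
                      minor_axis_len = 4 * sqrt(l2),
                      orientation_deg = orient)[keep, , drop = FALSE]
  # renumber surviving labels 1..K in the label image
  remap <- integer(length(area))
  remap[keep] <- seq_along(keep)
  lab[idx] <- remap[g]
  feats$label <- seq_along(keep)
  rownames(feats) <- NULL
  structure(list(features = feats, label_image = lab,
                 channel = NA_character_, sensitivity = NA_real_),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features (channel %s, sensitivity %s)\n",
              nrow(x$features), x$channel, format(x$sensitivity)))
  invisible(x)
}

#' Segment one channel of a micrograph into a feature set
#'
#' Convenience pipeline: [adaptive_threshold()] on the chosen channel,
#' [clean_mask()], then [extract_features()] restricted to the cell mask.
#'
#' @param micrograph A [micrograph()].
#' @param channel `"grl"` or `"mdl"`.
#' @param sensitivity Adaptive-threshold sensitivity in \[0, 1\].
#' @param window Adaptive-threshold window (odd px).
#' @param min_area Minimum feature area, px^2.
#' @param opening_radius,closing_radius Cleanup radii, px.
#' @return A `"feature_set"` stamped with the channel and sensitivity.
#' @export
segment_channel <- function(micrograph, channel = c("grl", "mdl"),
                            sensitivity, window = 51L, min_area = 4L,
                            opening_radius = 1L, closing_radius = 1L) {
  stopifnot(inherits(micrograph, "micrograph"))
  channel <- match.arg(channel)
  img <- micrograph[[channel]]
  mask <- adaptive_threshold(img, sensitivity, window)
  mask <- clean_mask(mask, opening_radius, closing_radius)
  fs <- extract_features(mask, micrograph$cell_mask, min_area)
  fs$channel <- channel
  fs$sensitivity <- sensitivity
  fs
}

#' Write a feature set as CSV
#'
#' One row per feature; the label image can be written separately as a
#' single-page TIFF of label values scaled to \[0, 1\].
#'
#' @param fs A `"feature_set"`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  utils::write.csv(fs$features, path, row.names = FALSE)
  invisible(path)
}
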