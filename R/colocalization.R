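#' Fraction of Mdl features overlapping any Grl feature
#'
#' Object-based colocalization: a Mdl feature "overlaps" iff it shares at
#' least one pixel with any Grl feature (parameter-free overlap rule).
#'
#' @param mdl,grl `"feature_set"` objects from same-shape images.
#' @return The overlap fraction in \[0, 1\].
#' @export
overlap_fraction <- function(mdl, grl) {
  stopifnot(inherits(mdl, "feature_set"), inherits(grl, "feature_set"))
  if (!identical(dim(mdl$label_image), dim(grl$label_image))) {
    stop("feature sets come from images of different shapes", call. = FALSE)
  }
  n <- nrow(mdl$features)
  if (n == 0L) {
    stop("overlap fraction is undefined: the Mdl feature set is empty",
         call. = FALSE)
  }
  idx <- which(mdl$label_image > 0L)
  hit <- unique(mdl$label_image[idx][grl$label_image[idx] > 0L])
  length(hit) / n
}

#' Random-translocation null for the overlap fraction
#'
#' For each of `R` rounds, every Mdl feature's pixel set is rigidly
#' translated (no rotation) to a uniformly random position at which the
#' whole feature lies inside `cell_mask` (rejection sampling over
#' offsets), and the overlap fraction against the fixed Grl features is
#' recomputed. Translocated features may overlap each other.
#'
#' @param mdl,grl `"feature_set"` objects from same-shape images.
#' @param cell_mask Logical matrix; every feature must fit inside it
#'   under some translation.
#' @param R Number of randomization rounds.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param max_attempts Rejection-sampling bound per feature and round.
#' @return A list with `null_mean`, `null_sd`, `samples` (length `R`),
#'   `R`, `seed`.
#' @export
random_overlap_expectation <- function(mdl, grl, cell_mask, R = 1000L,
                                       seed = NULL, max_attempts = 2000L) {
  stopifnot(inherits(mdl, "feature_set"), inherits(grl, "feature_set"))
  if (!is.logical(cell_mask)) storage.mode(cell_mask) <- "logical"
  if (!identical(dim(cell_mask), dim(mdl$label_image))) {
    stop("`cell_mask` must match the label-image dimensions", call. = FALSE)
  }
  stopifnot_scalar_number(R, "R", lower = 1)
  n <- nrow(mdl$features)
  if (n == 0L) stop("no Mdl features to translocate", call. = FALSE)
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  grl_occ <- grl$label_image > 0L

  # per-feature pixel offsets relative to the bounding-box corner
  feats <- lapply(mdl$features$label, function(l) {
    ij <- arrayInd(which(mdl$label_image == l), dim(cell_mask))
    list(dr = ij[, 1] - min(ij[, 1]), dc = ij[, 2] - min(ij[, 2]),
         h = diff(range(ij[, 1])) + 1L, w = diff(range(ij[, 2])) + 1L)
  })
  for (f in feats) {
    if (f$h > nr || f$w > nc) {
      stop("a feature is larger than the image and cannot be placed",
           call. = FALSE)
    }
  }

  samples <- with_seed_opt(seed, {
    vapply(seq_len(as.integer(R)), function(round) {
      hits <- 0L
      for (f in feats) {
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          r0 <- sample.int(nr - f$h + 1L, 1L)
          c0 <- sample.int(nc - f$w + 1L, 1L)
          px <- cbind(r0 + f$dr, c0 + f$dc)
          if (all(cell_mask[px])) {
            hits <- hits + as.integer(any(grl_occ[px]))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place a translocated feature inside the cell ",
               "mask within ", max_attempts, " attempts", call. = FALSE)
        }
      }
      hits / length(feats)
    }, numeric(1))
  })
  list(null_mean = mean(samples), null_sd = stats::sd(samples),
       samples = samples, R = as.integer(R), seed = seed)
}

#' Overlap fraction across a sweep of Mdl segmentation sensitivities
#'
#' Re-segments the Mdl channel at each sensitivity (the Grl segmentation
#' is held fixed) and reports the observed overlap fraction together
#' with its random-translocation null. More restrictive thresholding
#' (higher sensitivity) keeps fewer, brighter Mdl features.
#'
#' @param micrograph A [micrograph()].
#' @param sensitivities Non-empty numeric vector of sensitivities in
#'   \[0, 1\], reported in input order.
#' @param grl_sensitivity Fixed sensitivity for the Grl channel.
#' @param R Randomization rounds per sensitivity.
#' @param seed Integer seed for the whole sweep; `NULL` uses the current
#'   RNG stream.
#' @param window,min_area Segmentation parameters (see
#'   [segment_channel()]).
#' @return A data frame with one row per sensitivity: `sensitivity,
#'   n_mdl_features, overlap_fraction, null_mean, null_sd, z, R`.
#' @export
sensitivity_sweep <- function(micrograph, sensitivities,
                              grl_sensitivity = 0.25, R = 1000L, seed = NULL,
                              window = 51L, min_area = 4L) {
  stopifnot(inherits(micrograph, "micrograph"))
  if (length(sensitivities) == 0L ||
      any(sensitivities < 0 | sensitivities > 1)) {
    stop("`sensitivities` must be a non-empty vector in [0, 1]",
         call. = FALSE)
  }
  grl <- segment_channel(micrograph, "grl", grl_sensitivity, window, min_area)
  with_seed_opt(seed, {
    rows <- lapply(sensitivities, function(s) {
      tryCatch({
        mdl <- segment_channel(micrograph, "mdl", s, window, min_area)
        obs <- overlap_fraction(mdl, grl)
        nul <- random_overlap_expectation(mdl, grl, micrograph$cell_mask,
                                          R = R, seed = NULL)
        z <- if (nul$null_sd > 0) (obs - nul$null_mean) / nul$null_sd else NA_real_
        data.frame(sensitivity = s, n_mdl_features = nrow(mdl$features),
                   overlap_fraction = obs, null_mean = nul$null_mean,
                   null_sd = nul$null_sd, z = z, R = as.integer(R))
      }, error = function(e) {
        stop(sprintf("sensitivity %.3g: %s", s, conditionMessage(e)),
             call. = FALSE)
      })
    })
    do.call(rbind, rows)
  })
}
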