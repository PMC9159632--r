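#' Parameters for the synthetic micrograph generator
#'
#' Describes a single simulated cell: an elliptical cell mask containing
#' elongated elliptical organelles ("Grl" channel) each carrying one small
#' punctum ("Mdl" channel) placed with a configurable bias toward the
#' organelle tip, then blurred with a Gaussian point-spread function and
#' corrupted with Poisson and Gaussian noise.
#'
#' All lengths are in micrometres and converted internally using
#' `pixel_size`. `tip_bias` is the normalized distance from the organelle
#' centroid to the punctum centroid along the major axis toward the tip:
#' 0 places the punctum at the centroid, 1 exactly at the tip.
#' `punctum_placement = "uniform"` ignores `tip_bias` and draws the
#' punctum centroid uniformly over the organelle ellipse interior - the
#' unbiased condition matching the within-organelle randomization null.
#'
#' @param image_shape Integer vector `(rows, cols)` in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param cell_semi_axes Cell ellipse semi-axes `(A, B)` in um; `A` runs
#'   along image columns, `B` along rows.
#' @param mode `"docked"` (organelles in the peripheral band, major axes
#'   perpendicular to the local cell boundary) or `"cytoplasmic"`
#'   (uniform positions and orientations inside the cell).
#' @param n_mucocysts Number of organelles.
#' @param muc_semi_axes Organelle semi-axes `(a, b)` in um, `a > b`.
#' @param tip_bias Tip bias beta in \[0, 1\].
#' @param punctum_placement `"tip_biased"` or `"uniform"`.
#' @param punctum_radius Punctum disk radius in um.
#' @param psf_sigma Gaussian blur sigma in um (0 disables).
#' @param gauss_noise_sd Additive Gaussian noise sd, intensity units.
#' @param poisson_scale Photons per intensity unit (0 disables shot
#'   noise).
#' @param n_autofluor_blobs Number of broad dim autofluorescent blobs
#'   added to the Mdl channel (mimicking mitochondrial background).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A validated parameter list of class `"image_sim_params"`.
#' @seealso [generate_cell_image()]
#' @export
image_sim_params <- function(image_shape = c(220L, 220L),
                             pixel_size = 0.08,
                             cell_semi_axes = c(7.5, 6),
                             mode = c("docked", "cytoplasmic"),
                             n_mucocysts = 12L,
                             muc_semi_axes = c(0.5, 0.2),
                             tip_bias = 0.9,
                             punctum_placement = c("tip_biased", "uniform"),
                             punctum_radius = 0.15,
                             psf_sigma = 0.1,
                             gauss_noise_sd = 0.02,
                             poisson_scale = 200,
                             n_autofluor_blobs = 2L,
                             seed = NULL) {
  mode <- match.arg(mode)
  punctum_placement <- match.arg(punctum_placement)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8))
  stopifnot_scalar_number(pixel_size, "pixel_size", lower = 1e-6)
  stopifnot(length(cell_semi_axes) == 2L, all(cell_semi_axes > 0))
  stopifnot(length(muc_semi_axes) == 2L, all(muc_semi_axes > 0))
  if (muc_semi_axes[1] <= muc_semi_axes[2]) {
    stop("organelle semi-axes must satisfy a > b", call. = FALSE)
  }
  stopifnot_scalar_number(tip_bias, "tip_bias", lower = 0, upper = 1)
  stopifnot_scalar_number(punctum_radius, "punctum_radius", lower = 1e-6)
  stopifnot_scalar_number(psf_sigma, "psf_sigma", lower = 0)
  stopifnot_scalar_number(gauss_noise_sd, "gauss_noise_sd", lower = 0)
  stopifnot_scalar_number(poisson_scale, "poisson_scale", lower = 0)
  stopifnot(n_mucocysts >= 0, n_autofluor_blobs >= 0)
  # the cell ellipse (plus a 1 px margin) must fit inside the image
  ctr <- (image_shape + 1) / 2
  semi_px <- cell_semi_axes / pixel_size
  if (semi_px[2] + 1 > ctr[1] - 0.5 || semi_px[1] + 1 > ctr[2] - 0.5) {
    stop("image too small to contain the cell ellipse", call. = FALSE)
  }
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size,
                 cell_semi_axes = cell_semi_axes, mode = mode,
                 n_mucocysts = as.integer(n_mucocysts),
                 muc_semi_axes = muc_semi_axes, tip_bias = tip_bias,
                 punctum_placement = punctum_placement,
                 punctum_radius = punctum_radius, psf_sigma = psf_sigma,
                 gauss_noise_sd = gauss_noise_sd,
                 poisson_scale = poisson_scale,
                 n_autofluor_blobs = as.integer(n_autofluor_blobs),
                 seed = seed),
            class = "image_sim_params")
}

# Render a filled ellipse into `img` (amplitude by max-combine).
# Geometry convention used throughout the package: (row, col) pixel
# centres, 1-based; angles in degrees counterclockwise from the +column
# axis with "up" = decreasing row (i.e. y = -row).
render_ellipse <- function(img, centre_rc, a, b, theta_deg, amplitude = 1) {
  th <- theta_deg * pi / 180
  r0 <- centre_rc[1]; c0 <- centre_rc[2]
  rr <- max(1L, floor(r0 - a)):min(nrow(img), ceiling(r0 + a))
  cc <- max(1L, floor(c0 - a)):min(ncol(img), ceiling(c0 + a))
  dx <- matrix(cc - c0, length(rr), length(cc), byrow = TRUE)
  dy <- matrix(-(rr - r0), length(rr), length(cc))
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  img[rr, cc][inside] <- pmax(img[rr, cc][inside], amplitude)
  img
}

render_disk <- function(img, centre_rc, radius, amplitude = 1) {
  render_ellipse(img, centre_rc, radius + 1e-9, radius, 0, amplitude)
}

render_gaussian_blob <- function(img, centre_rc, sigma, amplitude) {
  r0 <- centre_rc[1]; c0 <- centre_rc[2]
  ext <- ceiling(3 * sigma)
  rr <- max(1L, floor(r0 - ext)):min(nrow(img), ceiling(r0 + ext))
  cc <- max(1L, floor(c0 - ext)):min(ncol(img), ceiling(c0 + ext))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  img[rr, cc] <- img[rr, cc] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

#' Simulate a two-channel micrograph of one cell with known ground truth
#'
#' Generates the Grl channel (filled organelle ellipses), the Mdl channel
#' (one punctum per organelle plus optional autofluorescent blobs), and
#' the elliptical cell mask described by `params`, applies Gaussian blur
#' and Poisson/Gaussian noise, and returns the pre-noise geometry as
#' ground truth. Organelle placement is non-overlapping by bounded
#' rejection sampling (500 attempts per organelle). Identical parameters
#' and seed give bit-identical output.
#'
#' @param params An [image_sim_params()] object.
#' @return A list with elements `micrograph` (a [micrograph()]) and
#'   `truth` (a data frame with one row per organelle: centroid, semi-axes
#'   and orientation in pixels/degrees, tip and punctum coordinates, true
#'   `offset_norm` and `angle_deg`).
#' @examples
#' sim <- generate_cell_image(image_sim_params(n_mucocysts = 4, seed = 1))
#' sim$truth$offset_norm
#' @export
generate_cell_image <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  with_seed_opt(params$seed, generate_cell_image_impl(params))
}

generate_cell_image_impl <- function(p) {
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  ctr <- (p$image_shape + 1) / 2               # (row, col) centre
  A <- p$cell_semi_axes[1] / p$pixel_size      # along columns
  B <- p$cell_semi_axes[2] / p$pixel_size      # along rows
  a <- p$muc_semi_axes[1] / p$pixel_size
  b <- p$muc_semi_axes[2] / p$pixel_size
  pr <- p$punctum_radius / p$pixel_size

  cell_mask <- {
    dx <- matrix(seq_len(nc) - ctr[2], nr, nc, byrow = TRUE)
    dy <- matrix(seq_len(nr) - ctr[1], nr, nc)
    (dx / A)^2 + (dy / B)^2 <= 1
  }

  margin <- a + pr + 2                          # keeps organelle + punctum inside
  n <- p$n_mucocysts
  cen_r <- cen_c <- ori <- tip_r <- tip_c <- numeric(n)
  if (n > 0) {
    if (p$mode == "docked") {
      u_max <- min(0.92, 1 - margin / min(A, B))
      u_min <- 0.76
      if (u_max <= u_min) {
        stop("cell too small for the docked peripheral band: ",
             "organelles of this size cannot fit inside the outer band",
             call. = FALSE)
      }
    }
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(500L)) {
        if (p$mode == "docked") {
          t <- stats::runif(1, 0, 2 * pi)
          u <- stats::runif(1, u_min, u_max)
          x <- u * A * cos(t); y <- u * B * sin(t)   # maths coords, y up
          nrm <- c(cos(t) / A, sin(t) / B)
          nrm <- nrm / sqrt(sum(nrm^2))              # outward unit normal
          th <- fold_180(atan2(nrm[2], nrm[1]) * 180 / pi)
          tip <- c(x, y) + a * nrm
        } else {
          s <- sqrt(stats::runif(1)); t <- stats::runif(1, 0, 2 * pi)
          x <- (A - margin) * s * cos(t); y <- (B - margin) * s * sin(t)
          th <- stats::runif(1, 0, 180)
          sign_tip <- sample(c(-1, 1), 1)
          tip <- c(x, y) +
            sign_tip * a * c(cos(th * pi / 180), sin(th * pi / 180))
        }
        ri <- ctr[1] - y; ci <- ctr[2] + x
        if (i > 1) {
          d2 <- (cen_r[seq_len(i - 1)] - ri)^2 + (cen_c[seq_len(i - 1)] - ci)^2
          if (min(d2) < (2 * a)^2) next
        }
        cen_r[i] <- ri; cen_c[i] <- ci; ori[i] <- th
        tip_r[i] <- ctr[1] - tip[2]; tip_c[i] <- ctr[2] + tip[1]
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(paste0("failed to place organelle %d without overlap ",
                            "(minimum centre separation %.1f px) after 500 ",
                            "attempts; reduce n_mucocysts or organelle size"),
                     i, 2 * a), call. = FALSE)
      }
    }
  }

  # punctum centroids
  pun_r <- pun_c <- off <- ang <- numeric(n)
  for (i in seq_len(n)) {
    if (p$punctum_placement == "tip_biased") {
      pun_r[i] <- cen_r[i] + p$tip_bias * (tip_r[i] - cen_r[i])
      pun_c[i] <- cen_c[i] + p$tip_bias * (tip_c[i] - cen_c[i])
      off[i] <- p$tip_bias
      ang[i] <- if (p$tip_bias > 0) 0 else NA_real_
    } else {
      repeat {
        u <- stats::runif(1, -a, a); v <- stats::runif(1, -b, b)
        if ((u / a)^2 + (v / b)^2 <= 1) break
      }
      th <- ori[i] * pi / 180
      dx <- u * cos(th) - v * sin(th); dy <- u * sin(th) + v * cos(th)
      pun_r[i] <- cen_r[i] - dy; pun_c[i] <- cen_c[i] + dx
      off[i] <- sqrt(u^2 + v^2) / a
      ang[i] <- if (off[i] > 0) {
        acute_angle(atan2(dy, dx) * 180 / pi, ori[i])
      } else NA_real_
    }
  }

  grl <- matrix(0, nr, nc)
  mdl <- matrix(0, nr, nc)
  for (i in seq_len(n)) {
    grl <- render_ellipse(grl, c(cen_r[i], cen_c[i]), a, b, ori[i])
    mdl <- render_disk(mdl, c(pun_r[i], pun_c[i]), pr)
  }
  if (p$n_autofluor_blobs > 0) {
    blob_sigma <- 0.5 / p$pixel_size
    for (i in seq_len(p$n_autofluor_blobs)) {
      repeat {
        x <- stats::runif(1, -A, A); y <- stats::runif(1, -B, B)
        if ((x / (A - margin))^2 + (y / (B - margin))^2 <= 1) break
      }
      mdl <- render_gaussian_blob(mdl, c(ctr[1] - y, ctr[2] + x),
                                  blob_sigma, 0.25)
    }
  }

  if (p$psf_sigma > 0) {
    s_px <- p$psf_sigma / p$pixel_size
    grl <- pmax(as.matrix(EBImage::gblur(grl, sigma = s_px)), 0)
    mdl <- pmax(as.matrix(EBImage::gblur(mdl, sigma = s_px)), 0)
  }
  if (p$poisson_scale > 0) {
    grl <- matrix(stats::rpois(nr * nc, grl * p$poisson_scale), nr, nc) /
      p$poisson_scale
    mdl <- matrix(stats::rpois(nr * nc, mdl * p$poisson_scale), nr, nc) /
      p$poisson_scale
  }
  if (p$gauss_noise_sd > 0) {
    grl <- grl + matrix(stats::rnorm(nr * nc, sd = p$gauss_noise_sd), nr, nc)
    mdl <- mdl + matrix(stats::rnorm(nr * nc, sd = p$gauss_noise_sd), nr, nc)
  }
  grl <- pmin(pmax(grl, 0), 1)
  mdl <- pmin(pmax(mdl, 0), 1)

  truth <- data.frame(
    id = seq_len(n),
    centroid_r = cen_r, centroid_c = cen_c,
    semi_major_px = rep(a, n), semi_minor_px = rep(b, n),
    orientation_deg = ori,
    tip_r = tip_r, tip_c = tip_c,
    punctum_r = pun_r, punctum_c = pun_c,
    offset_norm = off, angle_deg = ang
  )[seq_len(n), , drop = FALSE]

  list(micrograph = micrograph(grl, mdl, p$pixel_size, cell_mask),
       truth = truth)
}
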