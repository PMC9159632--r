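#' @importFrom withr with_seed
NULL

# Run code under a fixed RNG seed when `seed` is non-NULL, otherwise use
# the current RNG stream. Restores the caller's RNG state either way in
# the seeded case, so seeded calls are side-effect free.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Disc structuring element of integer radius r (EBImage convention:
# odd-sided brush of width 2r + 1). r = 0 has no meaning here; callers
# treat radius 0 as the identity.
disc_brush <- function(r) {
  EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

# Fold an angle in degrees into [0, 180).
fold_180 <- function(theta) {
  out <- theta %% 180
  out[out >= 180 - 1e-12] <- 0
  out
}

# Acute angle in [0, 90] between two undirected directions given in
# degrees (difference folded across both symmetries).
acute_angle <- function(theta1, theta2) {
  d <- abs(theta1 - theta2) %% 180
  pmin(d, 180 - d)
}
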