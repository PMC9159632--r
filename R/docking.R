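#' Peripheral fraction of signal in a cross-sectional image
#'
#' Quantifies organelle docking as the fraction of total channel
#' intensity inside a peripheral band of the cell: the band is the cell
#' mask minus its erosion by a disc of radius `band_width`, so the
#' measure is reproducible where a hand-drawn peripheral region would
#' not be. The fraction is invariant under global intensity rescaling
#' and non-decreasing in `band_width`.
#'
#' @param image Numeric intensity matrix.
#' @param cell_mask Logical matrix delimiting the cell.
#' @param band_width Band width in px; default 10% of the cell mask's
#'   equivalent radius `sqrt(area / pi)` (at least 1 px).
#' @return A list with `peripheral_fraction`, `band_width`,
#'   `total_intensity`, `band_area`, `mask_area`.
#' @examples
#' img <- matrix(1, 40, 40)
#' mask <- matrix(FALSE, 40, 40); mask[11:30, 11:30] <- TRUE
#' peripheral_fraction(img, mask, band_width = 3)$peripheral_fraction
#' @export
peripheral_fraction <- function(image, cell_mask, band_width = NULL) {
  if (!is.matrix(image) || !identical(dim(image), dim(cell_mask))) {
    stop("`image` and `cell_mask` must be matrices of the same shape",
         call. = FALSE)
  }
  if (!is.logical(cell_mask)) storage.mode(cell_mask) <- "logical"
  if (!any(cell_mask)) stop("empty cell mask", call. = FALSE)
  if (is.null(band_width)) {
    band_width <- max(1L, round(0.1 * sqrt(sum(cell_mask) / pi)))
  }
  stopifnot_scalar_number(band_width, "band_width", lower = 1)
  total <- sum(image[cell_mask])
  if (total <= 0) {
    stop("zero total intensity inside the cell mask", call. = FALSE)
  }
  eroded <- EBImage::erode(cell_mask * 1.0, disc_brush(round(band_width)))
  eroded <- matrix(as.numeric(eroded) > 0.5, nrow(image), ncol(image))
  if (!any(eroded)) {
    warning("band_width erases the whole cell interior; fraction = 1")
  }
  band <- cell_mask & !eroded
  list(peripheral_fraction = sum(image[band]) / total,
       band_width = band_width, total_intensity = total,
       band_area = sum(band), mask_area = sum(cell_mask))
}

#' Classical single-factor ANOVA
#'
#' One-way fixed-effects ANOVA, `F = MS_between / MS_within`, with the
#' p-value from the F distribution (delegated to
#' [stats::oneway.test()] with `var.equal = TRUE`).
#'
#' @param groups A list of at least two numeric vectors, each with at
#'   least two values; the values must not all be identical.
#' @return A list with `F`, `p`, `df_between`, `df_within`.
#' @examples
#' anova_single_factor(list(c(1, 2, 3), c(2, 3, 4)))$F  # 1.5
#' @export
anova_single_factor <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("each group needs at least two values", call. = FALSE)
  }
  values <- unlist(groups)
  if (!all(is.finite(values))) stop("non-finite values", call. = FALSE)
  if (stats::var(values) == 0) {
    stop("all values identical: F is undefined", call. = FALSE)
  }
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df_between = unname(fit$parameter["num df"]),
       df_within = unname(fit$parameter["denom df"]))
}
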