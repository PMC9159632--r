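#' Two-channel micrograph container
#'
#' Bundles the two registered intensity channels of a surface- or
#' cross-sectional fluorescence image of a single cell, together with the
#' pixel size and a boolean cell mask. The "grl" channel carries the
#' organelle (mucocyst core) stain; the "mdl" channel carries the punctate
#' tip-protein signal.
#'
#' @param grl,mdl Numeric matrices of identical dimensions with finite,
#'   non-negative intensities.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param cell_mask Logical matrix of the same dimensions with at least one
#'   `TRUE` pixel, delimiting the cell.
#' @return An object of class `"micrograph"`: a list with elements `grl`,
#'   `mdl`, `pixel_size`, `cell_mask`.
#' @examples
#' m <- micrograph(matrix(0, 8, 8), matrix(0, 8, 8), 0.1,
#'                 matrix(TRUE, 8, 8))
#' dim(m$grl)
#' @export
micrograph <- function(grl, mdl, pixel_size, cell_mask) {
  if (!is.matrix(grl) || !is.matrix(mdl) || !identical(dim(grl), dim(mdl))) {
    stop("`grl` and `mdl` must be matrices of identical dimensions",
         call. = FALSE)
  }
  if (!all(is.finite(grl)) || !all(is.finite(mdl)) ||
      any(grl < 0) || any(mdl < 0)) {
    stop("channel intensities must be finite and >= 0", call. = FALSE)
  }
  stopifnot_scalar_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  if (!is.logical(cell_mask)) storage.mode(cell_mask) <- "logical"
  if (!identical(dim(cell_mask), dim(grl))) {
    stop("`cell_mask` must match the channel dimensions", call. = FALSE)
  }
  if (!any(cell_mask)) stop("`cell_mask` has no TRUE pixel", call. = FALSE)
  structure(list(grl = grl, mdl = mdl, pixel_size = pixel_size,
                 cell_mask = cell_mask),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %.3g um/px, cell mask %d px (%.0f%%)\n",
              nrow(x$grl), ncol(x$grl), x$pixel_size, sum(x$cell_mask),
              100 * mean(x$cell_mask)))
  invisible(x)
}

#' Read and write micrographs as multi-page TIFF
#'
#' Page 1 is the Grl channel, page 2 the Mdl channel, page 3 the cell mask
#' (0/1). Intensities are stored as 16-bit samples and must lie in
#' \[0, 1\] (the package's normalized-detector convention; the synthetic
#' generator always satisfies it). The pixel size is not stored in the
#' TIFF and must be supplied when reading.
#'
#' @param x A [micrograph()].
#' @param path File path of the TIFF.
#' @param pixel_size Pixel size in micrometres per pixel (reader only).
#' @return `write_micrograph()` returns `path` invisibly;
#'   `read_micrograph()` returns a [micrograph()].
#' @export
write_micrograph <- function(x, path) {
  stopifnot(inherits(x, "micrograph"))
  if (max(x$grl) > 1 || max(x$mdl) > 1) {
    stop("channel intensities must be in [0, 1] to be written as TIFF",
         call. = FALSE)
  }
  pages <- list(x$grl, x$mdl, x$cell_mask * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_micrograph
#' @export
read_micrograph <- function(path, pixel_size) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3L) stop("expected a 3-page TIFF", call. = FALSE)
  micrograph(pages[[1L]], pages[[2L]], pixel_size, pages[[3L]] > 0.5)
}
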