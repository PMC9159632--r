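#' Pooled allele-frequency contrast score
#'
#' The per-site linkage score contrasting the allelic composition of the
#' mutant pool with the wildtype pool:
#' `(mut_alt / mut_depth) - (wt_alt / wt_depth)`, in \[-1, 1\]. Sites
#' with zero depth in either pool get `NA` (they carry no frequency
#' information) with a message.
#'
#' @param sites Data frame with columns `mut_alt, mut_depth, wt_alt,
#'   wt_depth` (vectorized over rows).
#' @return Numeric vector of contrast scores.
#' @examples
#' contrast_score(data.frame(mut_alt = 110, mut_depth = 111,
#'                           wt_alt = 30, wt_depth = 109))
#' @export
contrast_score <- function(sites) {
  need <- c("mut_alt", "mut_depth", "wt_alt", "wt_depth")
  stopifnot(all(need %in% names(sites)))
  if (any(sites$mut_alt > sites$mut_depth | sites$wt_alt > sites$wt_depth |
            sites$mut_alt < 0 | sites$wt_alt < 0)) {
    stop("alt counts must satisfy 0 <= alt <= depth", call. = FALSE)
  }
  bad <- sites$mut_depth == 0 | sites$wt_depth == 0
  if (any(bad)) {
    message(sum(bad), " site(s) with zero depth in a pool: contrast set NA")
  }
  out <- sites$mut_alt / sites$mut_depth - sites$wt_alt / sites$wt_depth
  out[bad] <- NA_real_
  out
}

#' Build a smoothed, genome-normalized linkage track
#'
#' Excludes sites with depth below `min_depth` in either pool, scores the
#' survivors with [contrast_score()], smooths per chromosome with a
#' centred sliding-window mean over `window_bp`, and normalizes the
#' smoothed scores so the genome-wide maximum is 1 (an all-non-positive
#' genome stays unnormalized at 0).
#'
#' @param sites Site data frame (`chrom, pos, mut_depth, mut_alt,
#'   wt_depth, wt_alt`, ...), any order.
#' @param min_depth Minimum per-pool depth (default 100).
#' @param window_bp Smoothing window in bp (default 200000).
#' @return A `"linkage_track"` data frame sorted by `(chrom, pos)` with
#'   columns `chrom, pos, raw, smoothed, normalized`; the filter and
#'   window settings are kept as attributes.
#' @export
build_linkage_track <- function(sites, min_depth = 100, window_bp = 2e5) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  stopifnot_scalar_number(min_depth, "min_depth", lower = 0)
  stopifnot_scalar_number(window_bp, "window_bp", lower = 1)
  keep <- sites$mut_depth >= min_depth & sites$wt_depth >= min_depth
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0L) {
    stop("no sites survive the depth filter (min_depth = ", min_depth, ")",
         call. = FALSE)
  }
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  raw <- contrast_score(sites)
  ok <- !is.na(raw)
  sites <- sites[ok, , drop = FALSE]
  raw <- raw[ok]

  smoothed <- numeric(length(raw))
  h <- window_bp / 2
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    pos <- sites$pos[i]
    cs <- c(0, cumsum(raw[i]))
    left <- findInterval(pos - h, pos, left.open = TRUE) + 1L
    right <- findInterval(pos + h, pos)
    smoothed[i] <- (cs[right + 1L] - cs[left]) / (right - left + 1L)
  }
  m <- max(smoothed)
  normalized <- if (m > 0) smoothed / m else rep(0, length(smoothed))
  out <- data.frame(chrom = sites$chrom, pos = sites$pos, raw = raw,
                    smoothed = smoothed, normalized = normalized,
                    row.names = NULL)
  attr(out, "min_depth") <- min_depth
  attr(out, "window_bp") <- window_bp
  class(out) <- c("linkage_track", "data.frame")
  out
}

#' Locate the peak region of a linkage track
#'
#' On the chromosome carrying the genome-wide maximum normalized score,
#' returns the maximal (longest) contiguous run of sites whose
#' normalized scores are all `>= frac_of_max`, expanded to its bounding
#' positions; among equally long runs the one containing the global
#' maximum is preferred (then the leftmost). This replaces by-eye peak
#' calling with a reproducible fraction-of-maximum rule.
#'
#' @param track A `"linkage_track"`.
#' @param frac_of_max Fraction of the maximum defining the peak run.
#' @return A list with `chrom`, `start`, `end` (1-based bp, inclusive).
#' @export
find_peak_region <- function(track, frac_of_max = 0.9) {
  stopifnot(inherits(track, "linkage_track"))
  stopifnot_scalar_number(frac_of_max, "frac_of_max", lower = 0, upper = 1)
  if (max(track$normalized) <= 0) {
    stop("all-zero track: no linkage peak to locate", call. = FALSE)
  }
  imax <- which.max(track$normalized)
  ch <- track$chrom[imax]
  i <- which(track$chrom == ch)
  above <- track$normalized[i] >= frac_of_max
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  len <- r$lengths[runs]
  jmax <- match(imax, i)
  has_max <- starts[runs] <= jmax & ends[runs] >= jmax
  best <- runs[order(-len, -has_max)][1L]
  list(chrom = ch, start = track$pos[i[starts[best]]],
       end = track$pos[i[ends[best]]])
}

#' Filter and rank candidate causal variants in a region
#'
#' Keeps sites inside the region with at least `min_depth` reads in both
#' pools, an apparently homozygous alt allele in the mutant pool
#' (`mut_alt_freq >= hom_threshold`) but not in the wildtype pool
#' (`wt_alt_freq < hom_threshold`), and ranks them by predicted
#' functional impact (`HIGH > MODERATE > LOW > MODIFIER > NONE`), ties
#' broken by descending contrast, then position.
#'
#' @param sites Site data frame with an `impact` column.
#' @param region A list `chrom/start/end` (e.g. from
#'   [find_peak_region()]).
#' @param min_depth Minimum per-pool depth (default 5).
#' @param hom_threshold Alt-frequency threshold taken to mean
#'   "appears homozygous" (default 0.9).
#' @return A data frame of ranked candidates with `mut_alt_freq,
#'   wt_alt_freq, contrast, impact_rank` appended; empty when nothing
#'   qualifies.
#' @export
candidate_variants <- function(sites, region, min_depth = 5,
                               hom_threshold = 0.9) {
  stopifnot(all(c("chrom", "pos", "impact") %in% names(sites)))
  stopifnot(all(c("chrom", "start", "end") %in% names(region)))
  impact_levels <- c("HIGH", "MODERATE", "LOW", "MODIFIER", "NONE")
  x <- sites[sites$chrom == region$chrom & sites$pos >= region$start &
               sites$pos <= region$end, , drop = FALSE]
  x <- x[x$mut_depth >= min_depth & x$wt_depth >= min_depth, , drop = FALSE]
  if (nrow(x) == 0L) return(empty_candidates(x))
  x$mut_alt_freq <- x$mut_alt / x$mut_depth
  x$wt_alt_freq <- x$wt_alt / x$wt_depth
  x <- x[x$mut_alt_freq >= hom_threshold & x$wt_alt_freq < hom_threshold, ,
         drop = FALSE]
  if (nrow(x) == 0L) return(empty_candidates(x))
  x$contrast <- x$mut_alt_freq - x$wt_alt_freq
  imp <- ifelse(x$impact %in% impact_levels, x$impact, "NONE")
  x$impact_rank <- match(imp, impact_levels)
  x <- x[order(x$impact_rank, -x$contrast, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  x
}

empty_candidates <- function(x) {
  x$mut_alt_freq <- numeric(0)
  x$wt_alt_freq <- numeric(0)
  x$contrast <- numeric(0)
  x$impact_rank <- integer(0)
  x
}

#' Write a peak region as a BED line
#'
#' BED uses 0-based half-open coordinates, so `start` is decremented.
#'
#' @param region A list `chrom/start/end` in 1-based inclusive bp.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(region, path) {
  writeLines(sprintf("%s\t%d\t%d", region$chrom,
                     as.integer(region$start) - 1L,
                     as.integer(region$end)), path)
  invisible(path)
}
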