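#' Normalize an expression profile to unit maximum
#'
#' Divides every value by the profile maximum, so the gene's maximum
#' expression level becomes 1; idempotent and invariant to positive
#' rescaling. All-zero profiles have no defined normalization.
#'
#' @param values Non-negative finite numeric vector, length >= 2.
#' @return The normalized profile (max = 1), same order.
#' @examples
#' max_normalize(c(2, 4, 8))
#' @export
max_normalize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("a profile needs at least two conditions", call. = FALSE)
  }
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("profile values must be finite and >= 0", call. = FALSE)
  }
  m <- max(values)
  if (m <= 0) stop("all-zero profile cannot be normalized", call. = FALSE)
  values / m
}

#' Similarity of two expression profiles
#'
#' Correlation of the max-normalized profiles over matched conditions.
#' Pearson by default; Spearman available.
#'
#' @param p1,p2 Numeric profiles of equal length over the same ordered
#'   conditions; each must be non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation in \[-1, 1\].
#' @examples
#' profile_similarity(c(1, 2, 3), c(3, 2, 1))  # -1
#' @export
profile_similarity <- function(p1, p2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(p1) != length(p2)) {
    stop("profiles must cover the same conditions", call. = FALSE)
  }
  n1 <- max_normalize(p1)
  n2 <- max_normalize(p2)
  if (stats::sd(n1) == 0 || stats::sd(n2) == 0) {
    stop("constant profile: correlation undefined", call. = FALSE)
  }
  stats::cor(n1, n2, method = method)
}
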