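# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the implementation under test.

# Windowed mean at every pixel by direct summation over the in-bounds
# part of the window.
oracle_local_mean <- function(img, window) {
  h <- (window - 1) %/% 2
  out <- matrix(NA_real_, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      rr <- max(1, r - h):min(nrow(img), r + h)
      cc <- max(1, c - h):min(ncol(img), c + h)
      out[r, c] <- mean(img[rr, cc])
    }
  }
  out
}

oracle_adaptive_threshold <- function(img, s, window) {
  img > oracle_local_mean(img, window) + s * (max(img) - min(img))
}

# Set-arithmetic binary morphology with an explicit structuring element
# (logical matrix with odd sides, origin at the centre).
oracle_erode <- function(mask, se) {
  hr <- (nrow(se) - 1) / 2; hc <- (ncol(se) - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  offs <- which(se, arr.ind = TRUE)
  offs <- cbind(offs[, 1] - hr - 1, offs[, 2] - hc - 1)
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      px <- cbind(r + offs[, 1], c + offs[, 2])
      inb <- px[, 1] >= 1 & px[, 1] <= nrow(mask) &
        px[, 2] >= 1 & px[, 2] <= ncol(mask)
      out[r, c] <- all(inb) && all(mask[px])
    }
  }
  out
}

oracle_dilate <- function(mask, se) {
  hr <- (nrow(se) - 1) / 2; hc <- (ncol(se) - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  offs <- which(se, arr.ind = TRUE)
  offs <- cbind(offs[, 1] - hr - 1, offs[, 2] - hc - 1)
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      px <- cbind(r - offs[, 1], c - offs[, 2])
      inb <- px[, 1] >= 1 & px[, 1] <= nrow(mask) &
        px[, 2] >= 1 & px[, 2] <= ncol(mask)
      out[r, c] <- any(mask[px[inb, , drop = FALSE]])
    }
  }
  out
}

oracle_open <- function(mask, se) oracle_dilate(oracle_erode(mask, se), se)
oracle_close <- function(mask, se) oracle_erode(oracle_dilate(mask, se), se)

# 8-connected labelling by breadth-first search.
oracle_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  nbr <- expand.grid(dr = -1:1, dc = -1:1)
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1) %% nrow(mask) + 1
      c <- (cur - 1) %/% nrow(mask) + 1
      for (j in seq_len(nrow(nbr))) {
        rr <- r + nbr$dr[j]; cc <- c + nbr$dc[j]
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          queue <- c(queue, (cc - 1) * nrow(mask) + rr)
        }
      }
    }
  }
  lab
}

# Render a filled ellipse as a logical mask (independent of the
# package's renderer: different parameterization, scans the full grid).
oracle_ellipse_mask <- function(nr, nc, r0, c0, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    dx <- seq_len(nc) - c0
    dy <- -(r - r0)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    out[r, ] <- (u / a)^2 + (v / b)^2 <= 1
  }
  out
}

# Brute-force overlap fraction from explicit per-feature pixel sets.
oracle_overlap_fraction <- function(mdl_lab, grl_lab) {
  labs <- setdiff(unique(as.vector(mdl_lab)), 0L)
  hits <- vapply(labs, function(l) any(grl_lab[mdl_lab == l] > 0L), TRUE)
  mean(hits)
}

# Default small, fast image-simulation settings shared by tests.
fast_sim_params <- function(...) {
  args <- utils::modifyList(list(image_shape = c(160L, 160L),
                                 cell_semi_axes = c(5.4, 4.4),
                                 n_mucocysts = 8L),
                            list(...))
  do.call(image_sim_params, args)
}
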