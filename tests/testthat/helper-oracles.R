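# Brute-force reference implementations, deliberately naive, used to check
# the fast paths. Everything here is plain R loops over small arrays.

oracle_mean_filter <- function(m, size) {
  r <- (size - 1) / 2
  h <- nrow(m); w <- ncol(m)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i          # half-sample reflection: x[0] -> x[1]
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      acc <- acc + m[refl(i + di, h), refl(j + dj, w)]
    }
    out[i, j] <- acc / size^2
  }
  out
}

oracle_convolve2d <- function(m, k2d) {
  # full 2-D correlation with half-sample reflected borders
  h <- nrow(m); w <- ncol(m)
  kr <- (nrow(k2d) - 1) / 2; kc <- (ncol(k2d) - 1) / 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -kr:kr) for (dj in -kc:kc) {
      acc <- acc + k2d[di + kr + 1, dj + kc + 1] *
        m[refl(i + di, h), refl(j + dj, w)]
    }
    out[i, j] <- acc
  }
  out
}

oracle_erode <- function(mask, count) {
  h <- nrow(mask); w <- ncol(mask)
  for (it in seq_len(count)) {
    out <- matrix(FALSE, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      keep <- TRUE
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        v <- if (ii < 1 || ii > h || jj < 1 || jj > w) FALSE else mask[ii, jj]
        if (!v) keep <- FALSE
      }
      out[i, j] <- keep
    }
    mask <- out
  }
  mask
}

oracle_fill_holes <- function(mask) {
  # flood fill background from the border (4-connectivity)
  h <- nrow(mask); w <- ncol(mask)
  reach <- matrix(FALSE, h, w)
  queue <- list()
  for (i in seq_len(h)) for (j in c(1L, w)) {
    if (!mask[i, j]) queue[[length(queue) + 1L]] <- c(i, j)
  }
  for (j in seq_len(w)) for (i in c(1L, h)) {
    if (!mask[i, j]) queue[[length(queue) + 1L]] <- c(i, j)
  }
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    if (reach[p[1], p[2]]) next
    reach[p[1], p[2]] <- TRUE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- p[1] + d[1]; jj <- p[2] + d[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
          !mask[ii, jj] && !reach[ii, jj]) {
        queue[[length(queue) + 1L]] <- c(ii, jj)
      }
    }
  }
  mask | !reach
}

oracle_mip <- function(slices_by_channel) {
  # slices_by_channel: list over channels of list over z of matrices
  lapply(slices_by_channel, function(zs) {
    out <- zs[[1]]
    for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
      out[i, j] <- max(vapply(zs, function(m) m[i, j], numeric(1)))
    }
    out
  })
}

oracle_potts_min <- function(p_obj, p_bg, lambda) {
  # exhaustive enumeration over all labelings of a tiny grid
  n <- length(p_obj)
  stopifnot(n <= 16)
  best <- Inf; best_lab <- NULL
  for (code in 0:(2^n - 1)) {
    lab <- matrix(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L) == 1L,
                  nrow(p_obj), ncol(p_obj))  # TRUE = object
    p <- ifelse(lab, p_obj, p_bg)
    e <- sum(-log(pmax(pmin(p, 1), 1e-10)))
    h <- nrow(lab); w <- ncol(lab)
    if (h > 1) e <- e + lambda * sum(lab[-h, ] != lab[-1, ])
    if (w > 1) e <- e + lambda * sum(lab[, -w] != lab[, -1])
    if (e < best) { best <- e; best_lab <- lab }
  }
  list(energy = best, labeling = best_lab)
}

oracle_segment_igg <- function(igg, extravascular, threshold, lowpass_size,
                               min_px) {
  sm <- if (lowpass_size > 1) oracle_mean_filter(igg, lowpass_size) else igg
  mask <- sm >= threshold & extravascular
  # region filter by naive repeated 8-neighborhood growth
  if (min_px > 1 && any(mask)) {
    h <- nrow(mask); w <- ncol(mask)
    seen <- matrix(FALSE, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (!mask[i, j] || seen[i, j]) next
      comp <- list(c(i, j)); seen[i, j] <- TRUE; q <- list(c(i, j))
      while (length(q)) {
        p <- q[[length(q)]]; q[[length(q)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
              mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            comp[[length(comp) + 1L]] <- c(ii, jj)
            q[[length(q) + 1L]] <- c(ii, jj)
          }
        }
      }
      if (length(comp) < min_px) {
        for (p in comp) mask[p[1], p[2]] <- FALSE
      }
    }
  }
  mask
}

random_mask <- function(h, w, p = 0.5) matrix(runif(h * w) < p, h, w)
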