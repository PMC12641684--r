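# Separable 3D filters: Gaussian smoothing, Laplacian-of-Gaussian, and a
# one-level Haar wavelet decomposition.

# 1D convolution along one axis of a 3D array with a centred kernel,
# replicating the border (used by Gaussian smoothing).
conv_axis <- function(arr, k, axis, pad_value = NULL) {
  h <- (length(k) - 1L) %/% 2L
  d <- dim(arr)
  n <- d[axis]
  # index with clamped (replicated) or zero border
  out <- array(0, d)
  for (o in -h:h) {
    idx <- seq_len(n) + o
    w <- k[o + h + 1L]
    if (is.null(pad_value)) {
      idx <- pmin(pmax(idx, 1L), n)
      sl <- switch(axis, arr[idx, , ], arr[, idx, ], arr[, , idx])
      out <- out + w * array(sl, d)
    } else {
      ok <- idx >= 1L & idx <= n
      sl <- array(pad_value, d)
      src <- idx[ok]
      if (axis == 1) sl[ok, , ] <- arr[src, , ]
      else if (axis == 2) sl[, ok, ] <- arr[, src, ]
      else sl[, , ok] <- arr[, , src]
      out <- out + w * sl
    }
  }
  out
}

gauss_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k / sum(k)
}

# Isotropic-in-voxel-units Gaussian smoothing (sigma per axis allowed).
gaussian_smooth3 <- function(arr, sigma, pad_value = NULL) {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3)
    if (sigma[ax] > 0) arr <- conv_axis(arr, gauss_kernel(sigma[ax]), ax,
                                        pad_value)
  arr
}

# Laplacian of Gaussian: Gaussian smoothing at sigma_mm (converted to voxel
# units per axis) followed by the 6-neighbour discrete Laplacian, scaled by
# sigma^2 (scale-normalized response).
log_filter <- function(arr, spacing, sigma_mm) {
  sv <- sigma_mm / spacing
  s <- gaussian_smooth3(arr, sv)
  d <- dim(arr)
  lap <- array(0, d)
  for (ax in 1:3) {
    k <- c(1, -2, 1) / spacing[ax]^2
    lap <- lap + conv_axis(s, k, ax)
  }
  sigma_mm^2 * lap
}

# One-level 3D Haar decomposition: returns the 8 decimated subbands named
# by the per-axis filter (L = average, H = difference), each of dimension
# ceiling(d / 2).
haar_subbands <- function(arr) {
  pairup <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    if (n %% 2L == 1L) {             # replicate last slice to even length
      idx <- c(seq_len(n), n)
      a <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                  a[, , idx, drop = FALSE])
      n <- n + 1L
    }
    odd <- seq(1L, n, by = 2L); evn <- odd + 1L
    lo <- switch(axis,
                 (a[odd, , , drop = FALSE] + a[evn, , , drop = FALSE]),
                 (a[, odd, , drop = FALSE] + a[, evn, , drop = FALSE]),
                 (a[, , odd, drop = FALSE] + a[, , evn, drop = FALSE])) / sqrt(2)
    hi <- switch(axis,
                 (a[odd, , , drop = FALSE] - a[evn, , , drop = FALSE]),
                 (a[, odd, , drop = FALSE] - a[, evn, , drop = FALSE]),
                 (a[, , odd, drop = FALSE] - a[, , evn, drop = FALSE])) / sqrt(2)
    list(L = lo, H = hi)
  }
  out <- list(arr)
  labs <- ""
  for (ax in 1:3) {
    nxt <- list(); nlabs <- character(0)
    for (i in seq_along(out)) {
      pr <- pairup(out[[i]], ax)
      nxt <- c(nxt, list(pr$L, pr$H))
      nlabs <- c(nlabs, paste0(labs[i], "L"), paste0(labs[i], "H"))
    }
    out <- nxt; labs <- nlabs
  }
  names(out) <- labs
  out
}
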