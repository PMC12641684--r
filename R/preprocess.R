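# Volume preprocessing: isotropic resampling and windowed z-normalization.

# Vectorized trilinear sampling of a 3D array at fractional voxel indices
# (1-based). Queries are clamped to the array border.
interp3_trilinear <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  xi <- pmin(pmax(xi, 1), d[1]); yi <- pmin(pmax(yi, 1), d[2])
  zi <- pmin(pmax(zi, 1), d[3])
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  z0 <- pmin(floor(zi), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(xi))
  if (d[2] == 1L) y0 <- rep(1, length(yi))
  if (d[3] == 1L) z0 <- rep(1, length(zi))
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  idx <- function(i, j, k) i + d[1] * ((j - 1) + d[2] * (k - 1))
  a <- as.vector(arr)
  a[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    a[idx(x1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
    a[idx(x0, y1, z0)] * (1 - fx) * fy * (1 - fz) +
    a[idx(x1, y1, z0)] * fx * fy * (1 - fz) +
    a[idx(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
    a[idx(x1, y0, z1)] * fx * (1 - fy) * fz +
    a[idx(x0, y1, z1)] * (1 - fx) * fy * fz +
    a[idx(x1, y1, z1)] * fx * fy * fz
}

# Nearest-neighbour sampling at fractional voxel indices (1-based).
interp3_nearest <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  xi <- pmin(pmax(round(xi), 1), d[1])
  yi <- pmin(pmax(round(yi), 1), d[2])
  zi <- pmin(pmax(round(zi), 1), d[3])
  arr[cbind(xi, yi, zi)]
}

# Resample `arr` (with per-axis spacing `sp`) onto a new grid of `newdim`
# voxels with spacing `newsp`, aligning voxel centres in world space.
resample_grid <- function(arr, sp, newdim, newsp, nearest = FALSE) {
  ix <- (seq_len(newdim[1]) - 0.5) * newsp[1] / sp[1] + 0.5
  iy <- (seq_len(newdim[2]) - 0.5) * newsp[2] / sp[2] + 0.5
  iz <- (seq_len(newdim[3]) - 0.5) * newsp[3] / sp[3] + 0.5
  g <- expand.grid(x = ix, y = iy, z = iz)
  f <- if (nearest) interp3_nearest else interp3_trilinear
  array(f(arr, g$x, g$y, g$z), newdim)
}

#' Resample a volume to isotropic voxel spacing
#'
#' Intensity volumes are interpolated trilinearly; masks nearest-neighbour so
#' that the output stays binary. Output grid size is chosen to preserve the
#' physical field of view.
#'
#' @param vol an `image_volume` or `lesion_mask`.
#' @param target_mm desired isotropic voxel edge length, mm (> 0).
#' @param is_mask force nearest-neighbour interpolation; defaults to `TRUE`
#'   for `lesion_mask` input.
#' @return A resampled object of the same class as `vol`.
#' @export
resample_isotropic <- function(vol, target_mm,
                               is_mask = inherits(vol, "lesion_mask")) {
  if (!is.numeric(target_mm) || length(target_mm) != 1 || target_mm <= 0)
    stop("target_mm must be a positive scalar")
  d <- dim(vol$data)
  newdim <- pmax(1L, as.integer(round(d * vol$spacing_mm / target_mm)))
  out <- resample_grid(vol$data, vol$spacing_mm, newdim,
                       rep(target_mm, 3), nearest = is_mask)
  sp <- rep(target_mm, 3)
  if (is_mask) lesion_mask(out != 0, sp) else image_volume(out, sp)
}

#' Windowed intensity normalization
#'
#' Clips intensities to a fixed window (a soft-tissue CT window analogue by
#' default) and z-scores using the mean and standard deviation of the clipped
#' values. A constant volume maps to all zeros.
#'
#' @param vol an `image_volume`.
#' @param clip_lo,clip_hi window bounds in intensity units, `clip_lo < clip_hi`.
#' @return A normalized `image_volume` (unit variance inside the window).
#' @export
normalize_intensity <- function(vol, clip_lo = 0, clip_hi = 100) {
  if (clip_lo >= clip_hi) stop("clip_lo must be < clip_hi")
  x <- pmin(pmax(vol$data, clip_lo), clip_hi)
  s <- stats::sd(x)
  x <- if (!is.finite(s) || s < 1e-12) x * 0 else (x - mean(x)) / s
  image_volume(array(x, dim(vol$data)), vol$spacing_mm, vol$affine)
}
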