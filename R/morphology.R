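# Binary morphology on 3D arrays: cubic dilation and connected components.

# Running maximum of a 3D 0/1 array along one axis with half-width h,
# implemented by shift-and-pmax (no loops over voxels).
axis_max <- function(arr, axis, h) {
  if (h == 0) return(arr)
  d <- dim(arr)
  out <- arr
  for (o in seq_len(h)) {
    n <- d[axis]
    src_lo <- seq_len(n - o)          # shift towards high indices
    dst_hi <- src_lo + o
    if (axis == 1) {
      out[dst_hi, , ] <- pmax(out[dst_hi, , ], arr[src_lo, , ])
      out[src_lo, , ] <- pmax(out[src_lo, , ], arr[dst_hi, , ])
    } else if (axis == 2) {
      out[, dst_hi, ] <- pmax(out[, dst_hi, ], arr[, src_lo, ])
      out[, src_lo, ] <- pmax(out[, src_lo, ], arr[, dst_hi, ])
    } else {
      out[, , dst_hi] <- pmax(out[, , dst_hi], arr[, , src_lo])
      out[, , src_lo] <- pmax(out[, , src_lo], arr[, , dst_hi])
    }
  }
  out
}

dilate_array <- function(arr, size) {
  h <- (size - 1L) %/% 2L
  arr <- axis_max(arr, 1L, h)
  arr <- axis_max(arr, 2L, h)
  axis_max(arr, 3L, h)
}

#' Binary dilation of a lesion mask with a cubic structuring element
#'
#' Dilates with a `size`x`size`x`size` cube (clipped at the volume borders),
#' the operation used to grow the lesion region so that peri-lesional tissue
#' enters the autoencoder patch.
#'
#' @param mask a `lesion_mask`.
#' @param size odd integer edge length of the cubic structuring element;
#'   `size = 1` is the identity.
#' @return The dilated `lesion_mask` (always a superset of the input).
#' @export
dilate_mask <- function(mask, size = 5L) {
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("structuring element size must be an odd integer >= 1")
  lesion_mask(dilate_array(mask$data, size) != 0, mask$spacing_mm, mask$affine)
}

# 26-connected components of a 0/1 array by seeded dilation-growth.
# Returns an integer label array (0 = background).
label_components_26 <- function(arr) {
  lab <- array(0L, dim(arr))
  remaining <- arr != 0
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    seed <- array(0, dim(arr))
    seed[which(remaining)[1]] <- 1
    repeat {
      grown <- dilate_array(seed, 3L) * remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    lab[seed != 0] <- k
    remaining <- remaining & seed == 0
  }
  lab
}

# Keep only the largest 26-connected component of a 0/1 array
# (labelling runs on the bounding box only).
largest_component <- function(arr) {
  idx <- which(arr != 0, arr.ind = TRUE)
  if (!nrow(idx)) return(arr != 0)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  lab <- label_components_26(sub)
  keep <- sub != 0
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0])
    keep <- lab == which.max(sizes)
  }
  out <- array(FALSE, dim(arr))
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- keep
  out
}
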