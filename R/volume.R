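#' Volumetric image container
#'
#' A minimal 3D image container: an intensity array plus per-axis voxel
#' spacing in millimetres and a 4x4 voxel-to-world affine. All pipeline
#' stages pass these around rather than bare arrays so that spacing is never
#' silently lost.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing_mm numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   affine built from `spacing_mm`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing_mm, affine = NULL) {
  stopifnot(length(dim(data)) == 3, length(spacing_mm) == 3)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (!all(is.finite(data))) stop("image data must be finite")
  if (is.null(affine)) {
    affine <- diag(c(spacing_mm, 1))
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 affine = affine),
            class = "image_volume")
}

#' Binary lesion mask aligned to an image volume
#'
#' @param data 3D array coercible to 0/1.
#' @param spacing_mm voxel edge lengths in mm.
#' @param affine optional 4x4 affine.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, spacing_mm, affine = NULL) {
  stopifnot(length(dim(data)) == 3)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1, FALSE, TRUE)))
    stop("mask must be binary")
  v <- image_volume(array(as.numeric(data != 0), dim(data)), spacing_mm, affine)
  class(v) <- c("lesion_mask", "image_volume")
  v
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels @ %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  invisible(x)
}

#' Physical volume of one voxel in mm^3
#' @param x an `image_volume` or `lesion_mask`.
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing_mm)

#' Mask volume in millilitres
#' @param mask a `lesion_mask`.
#' @return scalar, mL (1 mL = 1000 mm^3).
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$data) * voxel_volume_mm3(mask) / 1000
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti keeping spacing and affine attached.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param as_mask logical; read as a binary `lesion_mask`.
#' @return `read_volume`: an `image_volume` (or `lesion_mask`).
#' @export
read_volume <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  arr <- array(as.numeric(img), dim(img)[1:3])
  if (as_mask) lesion_mask(arr != 0, spacing, aff) else
    image_volume(arr, spacing, aff)
}

#' @rdname read_volume
#' @param vol an `image_volume` or `lesion_mask` to write.
#' @return `write_volume`: the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing_mm
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
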