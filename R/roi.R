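#' Tight bounding box of a segmentation mask
#'
#' Returns the smallest half-open box `[lo, hi)` (0-based voxel indices, one
#' pair per axis) containing every positive voxel, dilated by `margin_mm`
#' converted to voxels per axis (rounded up) and clipped to the volume bounds.
#' The margin cushions imperfect organ masks from an upstream segmenter.
#'
#' @param mask 3D binary array with at least one positive voxel.
#' @param margin_mm non-negative margin in millimetres.
#' @param spacing voxel spacing in mm (length 3); used to convert the margin.
#' @return object of class `bounding_box`: list with integer vectors `lo`,
#'   `hi` (0-based, half-open) and `shape` (the mask dims).
#' @export
mask_bounding_box <- function(mask, margin_mm = 0, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L) stop("`mask` must be a 3D array", call. = FALSE)
  if (margin_mm < 0) stop_config("margin_mm", "must be >= 0")
  pos <- which(mask > 0)
  if (length(pos) == 0L) {
    stop("empty mask: no positive voxels (upstream segmentation failure?)",
         call. = FALSE)
  }
  idx <- arrayInd(pos, d)
  lo <- apply(idx, 2, min) - 1L   # 0-based
  hi <- apply(idx, 2, max)        # exclusive == max 1-based index
  m <- as.integer(ceiling(margin_mm / spacing))
  lo <- pmax(lo - m, 0L)
  hi <- pmin(hi + m, d)
  structure(list(lo = as.integer(lo), hi = as.integer(hi), shape = d),
            class = "bounding_box")
}

box_slice <- function(box, axis) (box$lo[axis] + 1L):box$hi[axis]

#' Axial slices containing the organ
#'
#' @param mask 3D binary array (axis 3 axial).
#' @return ascending integer vector of 1-based axial indices whose slice has
#'   at least one positive voxel; empty for an empty mask.
#' @export
slices_with_organ <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L) stop("`mask` must be a 3D array", call. = FALSE)
  which(apply(mask > 0, 3, any))
}

# separable bilinear resize of a 2D matrix to shape `target` (corner-aligned)
resize_bilinear <- function(img, target) {
  mk <- function(n_in, n_out) {
    if (n_in == 1L) return(matrix(1, n_out, 1))
    x <- if (n_out == 1L) (n_in - 1) / 2 else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
    i0 <- pmin(floor(x), n_in - 2)
    w <- x - i0
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), i0 + 1)] <- A[cbind(seq_len(n_out), i0 + 1)] + (1 - w)
    A[cbind(seq_len(n_out), i0 + 2)] <- A[cbind(seq_len(n_out), i0 + 2)] + w
    A
  }
  mk(nrow(img), target[1]) %*% img %*% t(mk(ncol(img), target[2]))
}

#' Build the bag of 2D instances for one patient
#'
#' For every axial slice on which the organ mask is positive, crops the shared
#' in-plane bounding box (the union box over all slices, dilated by
#' `margin_mm`) and rescales the crop to `target_size` with bilinear
#' interpolation. One instance per organ slice; all instances share a shape
#' and are spatially aligned across slices.
#'
#' @param image 3D array (typically already resampled and normalized).
#' @param mask 3D binary organ mask, same shape.
#' @param margin_mm in-plane margin in mm (default 5).
#' @param target_size length-2 integer, instance height/width (default 64).
#' @param spacing voxel spacing in mm.
#' @param patient_id optional identifier carried on the stack.
#' @return object of class `instance_stack`: list with `instances` (3D array
#'   `target_size[1] x target_size[2] x n`), `slice_indices` (1-based axial
#'   indices), `patient_id`.
#' @export
build_instances <- function(image, mask, margin_mm = 5, target_size = c(64, 64),
                            spacing = c(1, 1, 1), patient_id = NA_character_) {
  if (!identical(dim(image), dim(mask))) stop("image/mask shape mismatch", call. = FALSE)
  if (length(target_size) == 1L) target_size <- rep(target_size, 2)
  target_size <- as.integer(target_size)
  if (any(target_size < 2L)) stop_config("target_size", "must be >= 2 per axis")
  box <- mask_bounding_box(mask, margin_mm, spacing)
  zs <- slices_with_organ(mask)
  n <- length(zs)
  rows <- box_slice(box, 1)
  cols <- box_slice(box, 2)
  inst <- array(0, c(target_size, n))
  for (k in seq_len(n)) {
    crop <- image[rows, cols, zs[k], drop = FALSE]
    inst[, , k] <- resize_bilinear(matrix(crop, nrow = length(rows)), target_size)
  }
  structure(list(instances = inst, slice_indices = zs,
                 patient_id = as.character(patient_id)),
            class = "instance_stack")
}

#' @export
print.instance_stack <- function(x, ...) {
  cat(sprintf("<instance_stack> %s: %d instances of %dx%d (slices %d..%d)\n",
              x$patient_id, dim(x$instances)[3], dim(x$instances)[1],
              dim(x$instances)[2], min(x$slice_indices), max(x$slice_indices)))
  invisible(x)
}
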