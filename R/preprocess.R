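#' Describe one acquired axial series for screening
#'
#' A lightweight record of per-slice acquisition metadata, the unit on which
#' [screen_series()] decides inclusion. Real cohorts lose patients to broken
#' exports and acquisition drift; the four screening rules here mirror the
#' usual failure modes: missing slices, pixel-spacing drift within a series,
#' mixed orientations, and images flagged unusable downstream.
#'
#' @param patient_id character scalar.
#' @param slice_indices integer vector of acquired slice numbers (non-empty).
#' @param pixel_spacing numeric matrix, one row per slice, two columns
#'   (in-plane mm); a single row is recycled to all slices.
#' @param orientation character vector of per-slice orientation tags (a single
#'   value is recycled).
#' @param qa_flag `TRUE` if the series was flagged for unusable image quality
#'   or a failed segmentation.
#' @return an object of class `series_record`.
#' @export
series_record <- function(patient_id, slice_indices,
                          pixel_spacing = c(1, 1),
                          orientation = "axial",
                          qa_flag = FALSE) {
  if (length(slice_indices) < 1L) stop_config("slice_indices", "must be non-empty")
  if (is.null(dim(pixel_spacing))) pixel_spacing <- matrix(pixel_spacing, nrow = 1)
  if (ncol(pixel_spacing) != 2L) stop_config("pixel_spacing", "must have two columns")
  if (nrow(pixel_spacing) == 1L) {
    pixel_spacing <- pixel_spacing[rep(1L, length(slice_indices)), , drop = FALSE]
  }
  if (length(orientation) == 1L) orientation <- rep(orientation, length(slice_indices))
  if (nrow(pixel_spacing) != length(slice_indices) ||
      length(orientation) != length(slice_indices)) {
    stop_config("pixel_spacing/orientation", "must match the number of slices")
  }
  structure(list(patient_id = as.character(patient_id),
                 slice_indices = as.integer(slice_indices),
                 pixel_spacing = pixel_spacing,
                 orientation = as.character(orientation),
                 qa_flag = isTRUE(qa_flag)),
            class = "series_record")
}

#' Screen series and report exclusions
#'
#' Applies the four exclusion checks in a fixed priority order, the first
#' failing check determining the recorded reason: `incomplete_series` (a gap
#' in the sorted slice indices), `inconsistent_spacing` (per-slice pixel
#' spacings differ beyond `spacing_tol`), `inconsistent_orientation` (mixed
#' orientation tags), `segmentation_error` (quality flag set).
#'
#' @param records list of [series_record()] objects (may be empty).
#' @param spacing_tol absolute tolerance in mm for spacing equality.
#' @return an object of class `exclusion_report`: a data.frame with columns
#'   `patient_id`, `status` (`"included"`/`"excluded"`), `reason` (`NA` for
#'   included records).
#' @export
screen_series <- function(records, spacing_tol = 1e-3) {
  if (inherits(records, "series_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    stopifnot(inherits(r, "series_record"))
    reason <- NA_character_
    idx <- sort(r$slice_indices)
    if (anyDuplicated(idx) || (length(idx) > 1L && any(diff(idx) != 1L))) {
      reason <- "incomplete_series"
    } else if (any(abs(sweep(r$pixel_spacing, 2, r$pixel_spacing[1, ])) > spacing_tol)) {
      reason <- "inconsistent_spacing"
    } else if (length(unique(r$orientation)) > 1L) {
      reason <- "inconsistent_orientation"
    } else if (r$qa_flag) {
      reason <- "segmentation_error"
    }
    data.frame(patient_id = r$patient_id,
               status = if (is.na(reason)) "included" else "excluded",
               reason = reason, stringsAsFactors = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), status = character(),
               reason = character(), stringsAsFactors = FALSE)
  structure(report, class = c("exclusion_report", "data.frame"))
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d series: %d included, %d excluded\n",
              nrow(x), sum(x$status == "included"), sum(x$status == "excluded")))
  if (any(x$status == "excluded")) print(table(reason = x$reason[x$status == "excluded"]))
  invisible(x)
}

out_shape <- function(dims, spacing, target) pmax(as.integer(round(dims * spacing / target)), 1L)

check_spacing_pair <- function(spacing, target) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_config("spacing", "must be 3 positive numbers")
  }
  if (length(target) != 3L || any(!is.finite(target)) || any(target <= 0)) {
    stop_config("target_spacing", "must be 3 positive numbers")
  }
}

# Interpolation matrix (n_out x n_in) for one axis. Natural cubic spline
# interpolation is linear in the sample values, so the matrix is built once by
# passing unit vectors through stats::splinefun and is then applied to every
# line of the volume at once.
axis_interp_matrix <- function(n_in, n_out, ratio, method = c("spline", "nearest")) {
  method <- match.arg(method)
  coords <- pmin(pmax((seq_len(n_out) - 1) * ratio, 0), n_in - 1)
  if (method == "nearest") {
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), pmin(pmax(round(coords) + 1, 1), n_in))] <- 1
    return(A)
  }
  if (n_in < 4L) {
    # too few knots for a cubic fit; splinefun falls back gracefully but keep
    # behaviour explicit: linear for 2-3 points, constant for 1
    if (n_in == 1L) return(matrix(1, n_out, 1))
  }
  vapply(seq_len(n_in), function(j) {
    e <- numeric(n_in); e[j] <- 1
    stats::splinefun(0:(n_in - 1), e, method = "natural")(coords)
  }, numeric(n_out))
}

apply_axis_matrix <- function(x, A, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(x, perm), nrow = d[axis])
  out <- A %*% m
  d2 <- d; d2[axis] <- nrow(A)
  aperm(array(out, dim = d2[perm]), order(perm))
}

resample_core <- function(x, spacing, target_spacing, method) {
  check_spacing_pair(spacing, target_spacing)
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("expected a 3D array", call. = FALSE)
  nd <- out_shape(d, spacing, target_spacing)
  for (axis in 1:3) {
    same <- nd[axis] == d[axis] && abs(spacing[axis] - target_spacing[axis]) < 1e-9
    if (same) next
    A <- axis_interp_matrix(d[axis], nd[axis], target_spacing[axis] / spacing[axis], method)
    x <- apply_axis_matrix(x, A, axis)
    d <- dim(x)
  }
  list(data = x, spacing = as.numeric(target_spacing))
}

#' Resample a volume to a homogeneous target spacing
#'
#' Image data are resampled with third-order (cubic natural) spline
#' interpolation applied separably per axis; segmentation masks use
#' nearest-neighbor interpolation so no new label values can appear. Output
#' shape per axis is `round(shape * spacing / target_spacing)`; the identity
#' case (`target_spacing == spacing`) returns the array unchanged.
#'
#' @param image,mask 3D array.
#' @param spacing current voxel spacing (mm, length 3).
#' @param target_spacing desired spacing (mm, length 3, all > 0).
#' @return list with `data` (resampled 3D array) and `spacing`
#'   (`target_spacing`).
#' @examples
#' v <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
#' r <- resample_image(v, spacing = c(1, 1, 2), target_spacing = c(1, 1, 1))
#' dim(r$data)  # 16 16 16
#' @export
resample_image <- function(image, spacing, target_spacing) {
  resample_core(image, spacing, target_spacing, "spline")
}

#' @rdname resample_image
#' @export
resample_mask <- function(mask, spacing, target_spacing) {
  resample_core(mask, spacing, target_spacing, "nearest")
}

#' Global intensity normalization
#'
#' `normalization_stats()` computes a global mean and standard deviation over
#' a reference set of intensities (typically the training cohort's organ
#' voxels, frozen and reused at test time); `normalize_global()` applies the
#' affine transform `(x - mean) / sd`.
#'
#' @param values numeric vector (or array) of reference intensities.
#' @param image array or numeric vector to normalize.
#' @param stats list with elements `mean` and `sd` (`sd > 0`).
#' @return `normalization_stats()`: list with `mean`, `sd`, `n`;
#'   `normalize_global()`: object shaped like `image`.
#' @export
normalization_stats <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 finite values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s <= 0) stop("reference intensities have sd <= 0", call. = FALSE)
  list(mean = mean(values), sd = s, n = length(values))
}

#' @rdname normalization_stats
#' @export
normalize_global <- function(image, stats) {
  if (!is.list(stats) || is.null(stats$mean) || is.null(stats$sd)) {
    stop("`stats` must be a list with `mean` and `sd`", call. = FALSE)
  }
  if (!is.finite(stats$sd) || stats$sd <= 0) stop("`stats$sd` must be > 0", call. = FALSE)
  (image - stats$mean) / stats$sd
}
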