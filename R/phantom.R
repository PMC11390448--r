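#' Configuration for the synthetic CT phantom cohort
#'
#' The phantom emulates the structure the detection pipeline assumes: an
#' abdominal-CT-like volume with anisotropic voxel spacing, a small ellipsoidal
#' organ (the pancreas stand-in) occupying a strict minority of axial slices,
#' and — for case patients — a small hypoattenuating spherical lesion fully
#' contained in the organ. Intensities are HU-like; defaults mimic a portal
#' venous phase scan where pancreatic adenocarcinoma is hypodense relative to
#' enhancing parenchyma.
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 8). Axis 3 is
#'   axial (slice) direction.
#' @param spacing numeric length-3, mm per voxel; may be anisotropic.
#' @param organ_radius organ semi-axis scale in mm; the ellipsoid semi-axes are
#'   `organ_radius * c(1, 0.8, 0.5)` (flattened along the axial axis so the
#'   organ spans a minority of slices).
#' @param tumor_radius lesion radius in mm; `0` means a control phantom even
#'   for label-1 requests is impossible (cases need `tumor_radius > 0`).
#' @param organ_intensity,tumor_intensity,background_intensity HU-like means.
#' @param noise_sd additive Gaussian noise standard deviation (same units).
#' @param n_cases,n_controls cohort composition for [generate_cohort()].
#' @param seed integer master seed; patient `i` uses `seed + i`.
#' @return an object of class `phantom_config` (a validated list).
#' @seealso [generate_patient()], [generate_cohort()], [write_study()]
#' @export
phantom_config <- function(grid_shape = c(64, 64, 32),
                           spacing = c(1, 1, 2.5),
                           organ_radius = 20,
                           tumor_radius = 6,
                           organ_intensity = 80,
                           tumor_intensity = 40,
                           background_intensity = -80,
                           noise_sd = 10,
                           n_cases = 10,
                           n_controls = 10,
                           seed = 1) {
  cfg <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
              organ_radius = organ_radius, tumor_radius = tumor_radius,
              organ_intensity = organ_intensity, tumor_intensity = tumor_intensity,
              background_intensity = background_intensity, noise_sd = noise_sd,
              n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3L || any(is.na(cfg$grid_shape)) || any(cfg$grid_shape < 8L)) {
    stop_config("grid_shape", "must be 3 integers, all >= 8")
  }
  if (length(cfg$spacing) != 3L || any(!is.finite(cfg$spacing)) || any(cfg$spacing <= 0)) {
    stop_config("spacing", "must be 3 positive numbers")
  }
  check_scalar_number(cfg$organ_radius, "organ_radius")
  check_scalar_number(cfg$tumor_radius, "tumor_radius")
  if (cfg$organ_radius <= 0) stop_config("organ_radius", "must be > 0")
  if (cfg$tumor_radius < 0) stop_config("tumor_radius", "must be >= 0")
  if (cfg$tumor_radius > 0 && cfg$tumor_radius >= cfg$organ_radius) {
    stop_config("tumor_radius", "must be smaller than organ_radius")
  }
  check_scalar_number(cfg$noise_sd, "noise_sd")
  if (cfg$noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  for (f in c("organ_intensity", "tumor_intensity", "background_intensity")) {
    check_scalar_number(cfg[[f]], f)
  }
  if (is.na(cfg$n_cases) || cfg$n_cases < 0L) stop_config("n_cases", "must be >= 0")
  if (is.na(cfg$n_controls) || cfg$n_controls < 0L) stop_config("n_controls", "must be >= 0")
  if (is.na(cfg$seed)) stop_config("seed", "must be an integer")
  invisible(cfg)
}

organ_semi_axes <- function(cfg) cfg$organ_radius * c(1, 0.8, 0.5)

#' Generate one phantom patient volume
#'
#' Deterministic for a fixed `(config, label, seed)` triple. The organ is an
#' axis-aligned ellipsoid centred near the volume middle (with a small seeded
#' jitter); a label-1 patient additionally carries a spherical tumor whose
#' centre is drawn uniformly from the organ ellipsoid shrunk so the sphere
#' fits, guaranteeing the tumor mask is a subset of the organ mask. Gaussian
#' noise with sd `config$noise_sd` is added to the painted image.
#'
#' @param config a [phantom_config()].
#' @param label patient label, 0 (control) or 1 (case).
#' @param seed integer seed for this patient.
#' @return an object of class `phantom_volume`: list with `image`,
#'   `organ_mask`, `tumor_mask` (3D arrays), `spacing`, `axis_order`
#'   (`"xyz-axial3"`), `label`.
#' @export
generate_patient <- function(config, label, seed) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  validate_phantom_config(config)
  if (!label %in% c(0, 1)) stop_config("label", "must be 0 or 1")
  if (label == 1 && config$tumor_radius <= 0) {
    stop_config("tumor_radius", "must be > 0 to generate a case (label 1)")
  }
  dims <- config$grid_shape
  sp <- config$spacing
  semi <- organ_semi_axes(config)
  extent <- dims * sp
  if (any(2 * semi > 0.9 * extent)) {
    stop_config("organ_radius", "is too large for grid_shape * spacing")
  }

  with_seed(seed, {
    # organ centre: volume middle plus jitter, kept so the ellipsoid fits
    centre <- extent / 2
    slack <- pmax(extent / 2 - semi - sp, 0)
    centre <- centre + stats::runif(3, -1, 1) * pmin(0.5 * slack, 0.1 * extent)

    ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) * sp[a] - centre[a]))
    # ellipsoid indicator via separable squared terms
    q <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, "+"),
               (ax[[3]] / semi[3])^2, "+")
    organ <- q <= 1

    tumor <- array(FALSE, dims)
    if (label == 1) {
      shrink <- pmax(1 - config$tumor_radius / semi, 0)
      if (min(shrink) <= 1e-6) {
        u <- c(0, 0, 0)  # lesion barely fits: place at the organ centre
      } else {
        # uniform point in the shrunk ellipsoid by rejection from its bounding box
        repeat {
          u <- stats::runif(3, -1, 1) * shrink
          if (sum((u / shrink)^2) <= 1) break
        }
      }
      tc <- centre + u * semi
      d2 <- outer(outer((ax[[1]] - (tc[1] - centre[1]))^2,
                        (ax[[2]] - (tc[2] - centre[2]))^2, "+"),
                  (ax[[3]] - (tc[3] - centre[3]))^2, "+")
      tumor <- (d2 <= config$tumor_radius^2) & organ
      if (!any(tumor)) {
        # degenerate voxelization (very small lesion): mark the voxel nearest
        # the tumor centre so the label invariant holds
        idx <- arrayInd(which.min(d2), dims)
        tumor[idx] <- organ[idx]
        tumor[idx] <- TRUE
        organ[idx] <- TRUE
      }
    }

    img <- array(config$background_intensity, dims)
    img[organ] <- config$organ_intensity
    img[tumor] <- config$tumor_intensity
    if (config$noise_sd > 0) {
      img <- img + array(stats::rnorm(prod(dims), 0, config$noise_sd), dims)
    }

    structure(list(image = img,
                   organ_mask = array(as.integer(organ), dims),
                   tumor_mask = array(as.integer(tumor), dims),
                   spacing = sp, axis_order = "xyz-axial3",
                   label = as.integer(label)),
              class = "phantom_volume")
  })
}

#' Generate a seeded phantom cohort
#'
#' Produces `n_cases` label-1 and `n_controls` label-0 volumes. Patient `i`
#' (in the order cases first, then controls) is generated with seed
#' `config$seed + i`, so a cohort is reproducible from its config alone.
#'
#' @param config a [phantom_config()].
#' @return list of `phantom_volume`, each with a `patient_id` field
#'   (`"case_001"`, `"control_001"`, ...).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  validate_phantom_config(config)
  if (config$n_cases + config$n_controls < 1L) {
    stop_config("n_cases", "+ n_controls must be >= 1")
  }
  labels <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  ids <- c(sprintf("case_%03d", seq_len(config$n_cases)),
           sprintf("control_%03d", seq_len(config$n_controls)))
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    v <- generate_patient(config, labels[i], seed = config$seed + i)
    v$patient_id <- ids[i]
    out[[i]] <- v
  }
  out
}

#' Write / read one phantom study as NIfTI
#'
#' Writes `image.nii.gz` (float32), `organ_mask.nii.gz` and
#' `tumor_mask.nii.gz` (uint8) plus a one-line `label.txt` into `directory`.
#' `read_study()` reverses the operation.
#'
#' @param volume a `phantom_volume`.
#' @param directory output directory (created if needed).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return named character vector of file paths, invisibly for `write_study()`.
#' @export
write_study <- function(volume, directory, gzip = TRUE) {
  stopifnot(inherits(volume, "phantom_volume"))
  if (!dir.exists(directory)) {
    if (!dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
      stop(sprintf("cannot create directory: %s", directory), call. = FALSE)
    }
  }
  ext <- if (gzip) ".nii.gz" else ".nii"
  paths <- c(image = file.path(directory, paste0("image", ext)),
             organ_mask = file.path(directory, paste0("organ_mask", ext)),
             tumor_mask = file.path(directory, paste0("tumor_mask", ext)),
             label = file.path(directory, "label.txt"))
  write_nifti(volume$image, paths[["image"]], volume$spacing, "float32")
  write_nifti(volume$organ_mask, paths[["organ_mask"]], volume$spacing, "uint8")
  write_nifti(volume$tumor_mask, paths[["tumor_mask"]], volume$spacing, "uint8")
  writeLines(as.character(volume$label), paths[["label"]])
  invisible(paths)
}

#' @rdname write_study
#' @export
read_study <- function(directory) {
  pick <- function(stem) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(directory, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    stop(sprintf("missing %s volume under %s", stem, directory), call. = FALSE)
  }
  img <- read_nifti(pick("image"))
  org <- read_nifti(pick("organ_mask"))
  tum <- read_nifti(pick("tumor_mask"))
  lab_path <- file.path(directory, "label.txt")
  label <- if (file.exists(lab_path)) as.integer(readLines(lab_path)[1]) else
    as.integer(any(tum$data > 0))
  structure(list(image = img$data,
                 organ_mask = array(as.integer(org$data > 0.5), dim(org$data)),
                 tumor_mask = array(as.integer(tum$data > 0.5), dim(tum$data)),
                 spacing = img$spacing, axis_order = "xyz-axial3",
                 label = label),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %s  dims %s  spacing %s mm  label %d\n",
              if (is.null(x$patient_id)) "" else x$patient_id,
              paste(dim(x$image), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"), x$label))
  cat(sprintf("  organ voxels: %d on %d axial slices; tumor voxels: %d\n",
              sum(x$organ_mask), length(slices_with_organ(x$organ_mask)),
              sum(x$tumor_mask)))
  invisible(x)
}
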