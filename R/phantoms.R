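#' Synthetic multi-modal brain-tumor phantoms
#'
#' The phantom generator emulates the layout of skull-stripped multi-modal
#' brain MRI with expert labels: four co-registered intensity volumes
#' (FLAIR, T1, T1ce, T2) plus an integer label volume with values
#' 0 (healthy), 1 (necrotic), 2 (edema) and 4 (enhancing). Tumor
#' compartments are concentric ellipsoids inside a spherical brain mask —
#' an edema shell around a core whose nucleus is enhancing — which
#' guarantees the nesting enhancing ⊆ core ⊆ whole-tumor that the
#' evaluation regions assume. Intensities are compartment means plus
#' additive Gaussian noise, clipped at zero; background outside the brain
#' is exactly zero, as in skull-stripped data.
#'
#' @param grid_shape integer(3), voxel counts per axis (depth, height, width).
#' @param brain_radius_frac brain sphere radius as a fraction of the
#'   smallest grid dimension.
#' @param tumor_center integer(3) voxel coordinate of the tumor center, or
#'   `NULL` to place it at the grid center.
#' @param radii numeric(3), strictly decreasing ellipsoid semi-axes in
#'   voxels for the whole-tumor, core and enhancing compartments.
#' @param modality_contrast 4 x 4 numeric matrix of mean intensities,
#'   rows = modalities (flair, t1, t1ce, t2), columns = compartments
#'   (brain, edema, necrotic, enhancing).
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   the same arbitrary intensity units as `modality_contrast`.
#' @param seed integer seed; the phantom is a deterministic function of
#'   its spec.
#' @return A `phantom_spec` object (a validated list).
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         brain_radius_frac = 0.42,
                         tumor_center = NULL,
                         radii = c(10, 6, 3),
                         modality_contrast = default_modality_contrast(),
                         noise_sd = 10,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8)) {
    stopf_("grid_shape must be three voxel counts >= 8")
  }
  if (length(radii) != 3 || any(diff(radii) >= 0)) {
    stopf_("radii must be three strictly decreasing semi-axes (whole > core > enhancing)")
  }
  if (noise_sd < 0) stopf_("noise_sd must be >= 0")
  if (is.null(tumor_center)) tumor_center <- as.integer(round(grid_shape / 2))
  brain_r <- brain_radius_frac * min(grid_shape)
  center_off <- sqrt(sum((tumor_center - grid_shape / 2)^2))
  if (center_off + radii[1] > brain_r) {
    stopf_("tumor (center offset %.1f + radius %.1f) does not fit inside the brain mask (radius %.1f)",
           center_off, radii[1], brain_r)
  }
  stopifnot(is.matrix(modality_contrast),
            nrow(modality_contrast) == 4, ncol(modality_contrast) == 4)
  structure(list(grid_shape = grid_shape,
                 brain_radius_frac = brain_radius_frac,
                 tumor_center = as.numeric(tumor_center),
                 radii = as.numeric(radii),
                 modality_contrast = modality_contrast,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default per-modality, per-compartment mean intensities
#'
#' Qualitatively mimics glioma MRI contrast: edema is brightest on FLAIR
#' and T2, the enhancing rim is by far brightest on contrast-enhanced T1,
#' and the necrotic core is dark on T1/T1ce. Units are arbitrary.
#'
#' @return 4 x 4 numeric matrix (modality x compartment).
#' @export
default_modality_contrast <- function() {
  m <- rbind(flair = c(100, 190, 130, 140),
             t1    = c(100,  80,  55,  90),
             t1ce  = c(100,  90,  60, 210),
             t2    = c(100, 175, 145, 130))
  colnames(m) <- c("brain", "edema", "necrotic", "enhancing")
  m
}

ellipsoid_mask_ <- function(grid_shape, center, radii3) {
  d <- seq_len(grid_shape[1]) - center[1]
  h <- seq_len(grid_shape[2]) - center[2]
  w <- seq_len(grid_shape[3]) - center[3]
  q <- outer(outer((d / radii3[1])^2, (h / radii3[2])^2, `+`),
             (w / radii3[3])^2, `+`)
  q <= 1
}

#' Generate one phantom case
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_case`: list with `stack` (a `modality_stack`),
#'   `label` (a `label_volume`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  gs <- spec$grid_shape
  brain <- ellipsoid_mask_(gs, gs / 2 + 0.5, rep(spec$brain_radius_frac * min(gs), 3))
  whole <- ellipsoid_mask_(gs, spec$tumor_center, rep(spec$radii[1], 3))
  core <- ellipsoid_mask_(gs, spec$tumor_center, rep(spec$radii[2], 3))
  enh <- ellipsoid_mask_(gs, spec$tumor_center, rep(spec$radii[3], 3))
  core <- core & whole
  enh <- enh & core
  label <- array(0L, gs)
  label[brain] <- 0L
  label[whole] <- 2L          # edema shell
  label[core] <- 1L           # necrotic rim
  label[enh] <- 4L            # enhancing nucleus
  comp <- array(0L, gs)       # compartment index: 0 bg, 1 brain, 2..4 tumor
  comp[brain] <- 1L
  comp[whole] <- 2L
  comp[core] <- 3L
  comp[enh] <- 4L
  data <- array(0, c(gs, 4L))
  with_seed_(spec$seed, {
    for (m in 1:4) {
      vol <- array(0, gs)
      means <- c(0, spec$modality_contrast[m, ])
      vol[] <- means[comp + 1L]
      if (spec$noise_sd > 0) {
        inside <- comp > 0L
        vol[inside] <- vol[inside] + rnorm(sum(inside), sd = spec$noise_sd)
      }
      data[, , , m] <- pmax(vol, 0)
    }
  })
  case_id <- sprintf("phantom_%08d", spec$seed %% 100000000L)
  stack <- new_modality_stack(data, affine = diag(4), case_id = case_id)
  lab <- new_label_volume(label, affine = diag(4))
  structure(list(stack = stack, label = lab, spec = spec),
            class = "phantom_case")
}

#' Generate a reproducible cohort of phantom cases
#'
#' Tumor centers and radii are randomized within bounds that keep every
#' tumor inside the brain mask; each case's seed is derived from
#' `base_seed` so the whole cohort is a pure function of its arguments.
#'
#' @param n number of cases (>= 1).
#' @param base_seed integer seed for the cohort.
#' @param grid_shape integer(3) passed to every case.
#' @param noise_sd per-case noise level.
#' @return list of `phantom_case` objects.
#' @export
generate_cohort <- function(n, base_seed = 1L, grid_shape = c(64L, 64L, 64L),
                            noise_sd = 10) {
  if (n < 1) stopf_("n must be >= 1")
  grid_shape <- as.integer(grid_shape)
  seeds <- derive_seeds_(base_seed, n)
  brain_r <- 0.42 * min(grid_shape)
  specs <- with_seed_(base_seed + 1L, {
    lapply(seq_len(n), function(i) {
      r_whole <- runif(1, 0.28, 0.45) * brain_r
      r_core <- runif(1, 0.45, 0.7) * r_whole
      r_enh <- runif(1, 0.4, 0.7) * r_core
      max_off <- max(0, brain_r - r_whole - 2)
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      off <- runif(1, 0, max_off) * dir
      phantom_spec(grid_shape = grid_shape,
                   tumor_center = round(grid_shape / 2 + off),
                   radii = c(r_whole, r_core, r_enh),
                   noise_sd = noise_sd,
                   seed = seeds[i])
    })
  })
  lapply(specs, generate_phantom)
}

#' Write a phantom case to disk as NIfTI
#'
#' Emits five files following the naming convention
#' `<caseID>_<modality>.nii.gz` (modality in flair, t1, t1ce, t2) and
#' `<caseID>_seg.nii.gz`, with an identity affine by default.
#'
#' @param case a `phantom_case` (or a list with `stack` and `label`).
#' @param directory output directory; created if absent.
#' @param case_id optional identifier overriding the stack's.
#' @return invisibly, the vector of file paths written.
#' @export
write_case <- function(case, directory, case_id = NULL) {
  if (is.null(case_id)) case_id <- case$stack$case_id
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf_("cannot create directory '%s'", directory)
  paths <- character(0)
  for (m in seq_along(MODALITIES)) {
    p <- file.path(directory, sprintf("%s_%s.nii.gz", case_id, MODALITIES[m]))
    img <- RNifti::asNifti(case$stack$data[, , , m])
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  if (!is.null(case$label)) {
    p <- file.path(directory, sprintf("%s_seg.nii.gz", case_id))
    img <- RNifti::asNifti(array(as.integer(case$label$data), dim(case$label$data)))
    RNifti::writeNifti(img, p, datatype = "int16")
    paths <- c(paths, p)
  }
  invisible(paths)
}
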