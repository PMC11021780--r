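#' Modality stack and label volume containers
#'
#' A `modality_stack` holds the four co-registered MRI contrasts of one
#' case as a single channel-last array with dim (depth, height, width, 4),
#' channel order FLAIR, T1, T1ce, T2, plus the 4x4 NIfTI affine and a case
#' identifier. A `label_volume` holds the integer segmentation with values
#' in \{0, 1, 2, 4\}.
#'
#' @param data numeric array, dim (D, H, W, 4) for stacks and (D, H, W)
#'   for labels.
#' @param affine 4x4 spatial metadata matrix (identity by default).
#' @param case_id case identifier string.
#' @return the validated container.
#' @export
new_modality_stack <- function(data, affine = diag(4), case_id = "case") {
  d <- dim(data)
  if (length(d) != 4 || d[4] != 4) {
    stopf_("a modality stack must have dim (depth, height, width, 4); got (%s)",
           paste(d, collapse = ", "))
  }
  structure(list(data = data, affine = affine, case_id = case_id),
            class = "modality_stack")
}

#' @rdname new_modality_stack
#' @export
new_label_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3) stopf_("a label volume must be a rank-3 array")
  check_label_values_(data)
  structure(list(data = data, affine = affine), class = "label_volume")
}

#' Load one case from a directory of NIfTI files
#'
#' Expects the naming convention `<case_id>_<modality>.nii.gz` with
#' modality in flair, t1, t1ce, t2; `<case_id>_seg.nii.gz` is optional
#' (validation cases ship without labels).
#'
#' @param directory directory containing the files.
#' @param case_id the case identifier prefix.
#' @return list with `stack` (a `modality_stack`) and `label` (a
#'   `label_volume`, or `NULL` when no segmentation file exists).
#' @export
load_case <- function(directory, case_id) {
  vols <- vector("list", 4)
  affine <- NULL
  for (m in seq_along(MODALITIES)) {
    p <- file.path(directory, sprintf("%s_%s.nii.gz", case_id, MODALITIES[m]))
    if (!file.exists(p)) p <- sub("\\.gz$", "", p)
    if (!file.exists(p)) {
      stopf_("missing modality file for '%s' in '%s' (expected %s_%s.nii.gz)",
             MODALITIES[m], directory, case_id, MODALITIES[m])
    }
    img <- RNifti::readNifti(p)
    if (is.null(affine)) affine <- structure(RNifti::xform(img), class = "matrix")
    vols[[m]] <- array(as.numeric(img), dim(img))
  }
  shp <- dim(vols[[1]])
  data <- array(0, c(shp, 4L))
  for (m in 1:4) data[, , , m] <- vols[[m]]
  stack <- new_modality_stack(data, affine = unclass(affine), case_id = case_id)
  seg_path <- file.path(directory, sprintf("%s_seg.nii.gz", case_id))
  if (!file.exists(seg_path)) seg_path <- sub("\\.gz$", "", seg_path)
  label <- NULL
  if (file.exists(seg_path)) {
    seg <- RNifti::readNifti(seg_path)
    label <- new_label_volume(array(as.integer(round(as.numeric(seg))), dim(seg)),
                              affine = unclass(structure(RNifti::xform(seg), class = "matrix")))
  }
  list(stack = stack, label = label)
}

#' Z-score standardization over the nonzero (brain) region
#'
#' Per modality and per case, intensities are mapped to
#' \eqn{A' = (A - \mu) / \delta}, with the mean \eqn{\mu} and population
#' standard deviation \eqn{\delta} computed over nonzero voxels only, so
#' that the skull-stripped zero background cannot dominate the statistics.
#' Background voxels remain exactly zero. A channel whose nonzero spread
#' is below `1e-8` is degenerate and is set to all zeros with a warning.
#'
#' @param stack a `modality_stack`.
#' @return the standardized `modality_stack`.
#' @export
zscore_normalize <- function(stack) {
  data <- stack$data
  for (m in 1:4) {
    vol <- data[, , , m]
    nz <- vol != 0
    n <- sum(nz)
    if (n < 2) {
      warning(sprintf("modality %s: fewer than 2 nonzero voxels; channel zeroed",
                      MODALITIES[m]))
      data[, , , m] <- 0
      next
    }
    v <- vol[nz]
    mu <- mean(v)
    delta <- sqrt(mean((v - mu)^2))   # population sd
    if (delta < 1e-8) {
      warning(sprintf("modality %s: degenerate spread (%.2e); channel zeroed",
                      MODALITIES[m], delta))
      data[, , , m] <- 0
      next
    }
    vol[nz] <- (v - mu) / delta
    vol[!nz] <- 0
    data[, , , m] <- vol
  }
  new_modality_stack(data, affine = stack$affine, case_id = stack$case_id)
}

#' Map raw labels \{0,1,2,4\} to contiguous class indices \{0,1,2,3\}
#'
#' @param label a `label_volume` or integer array with values in
#'   \{0, 1, 2, 4\}.
#' @return integer array of class indices (same shape).
#' @export
remap_labels <- function(label) {
  x <- if (inherits(label, "label_volume")) label$data else label
  check_label_values_(x)
  out <- x
  out[x == 4L] <- 3L
  out
}

#' Invert [remap_labels()]: class indices \{0,1,2,3\} back to raw labels
#'
#' @param classes integer array with values in \{0, 1, 2, 3\}.
#' @return integer array with values in \{0, 1, 2, 4\}.
#' @export
labels_from_classes <- function(classes) {
  bad <- setdiff(unique(as.vector(classes)), 0:3)
  if (length(bad) > 0) stopf_("class indices must be in {0,1,2,3}; got %s",
                              paste(sort(bad), collapse = ", "))
  out <- classes
  out[classes == 3L] <- 4L
  out
}

#' One-hot encode a class-index volume
#'
#' @param classes integer array (D, H, W) of class indices.
#' @param n_classes number of classes (default 4).
#' @return binary array (D, H, W, n_classes) whose channels sum to one at
#'   every voxel; `argmax` along the last axis inverts the encoding.
#' @export
onehot <- function(classes, n_classes = 4L) {
  v <- as.vector(classes)
  if (any(v < 0 | v >= n_classes)) {
    stopf_("class index out of range [0, %d)", n_classes)
  }
  shp <- dim(classes)
  out <- matrix(0, length(v), n_classes)
  out[cbind(seq_along(v), v + 1L)] <- 1
  array(out, c(shp, n_classes))
}

# argmax over the channel (last) axis of a (D,H,W,C) array -> 0-based classes
channel_argmax_ <- function(x) {
  shp <- dim(x)
  C <- shp[length(shp)]
  m <- matrix(x, ncol = C)
  array(max.col(m, ties.method = "first") - 1L, shp[-length(shp)])
}

#' Random (optionally tumor-biased) cubic crop of a labeled case
#'
#' Volumes smaller than the crop size are zero-padded symmetrically first.
#' With probability `tumor_bias` the crop window is centered on a
#' uniformly drawn tumor voxel (labels 1, 2 or 4) when one exists,
#' otherwise the window is uniform over valid positions; this counters
#' the extreme foreground/background imbalance of whole-volume sampling
#' while keeping crops random.
#'
#' @param stack a (normalized) `modality_stack`.
#' @param label the matching `label_volume`.
#' @param size cube side of the crop.
#' @param tumor_bias probability of centering on a tumor voxel.
#' @return a training sample: list with `inputs` (size^3 x 4 array),
#'   `target_classes` (size^3 integer array, values 0-3) and
#'   `target_onehot` (size^3 x 4 binary array).
#' @export
random_crop <- function(stack, label, size, tumor_bias = 0.5) {
  x <- stack$data
  y <- if (inherits(label, "label_volume")) label$data else label
  shp <- dim(y)
  pad <- pmax(0L, as.integer(size) - shp)
  if (any(pad > 0)) {
    lo <- pad %/% 2L
    nshp <- pmax(shp, size)
    xp <- array(0, c(nshp, 4L))
    yp <- array(0L, nshp)
    xp[lo[1] + seq_len(shp[1]), lo[2] + seq_len(shp[2]), lo[3] + seq_len(shp[3]), ] <- x
    yp[lo[1] + seq_len(shp[1]), lo[2] + seq_len(shp[2]), lo[3] + seq_len(shp[3])] <- y
    x <- xp; y <- yp; shp <- nshp
  }
  tumor_idx <- which(y %in% c(1L, 2L, 4L))
  use_tumor <- length(tumor_idx) > 0 && runif(1) < tumor_bias
  if (use_tumor) {
    center <- arrayInd(tumor_idx[sample.int(length(tumor_idx), 1)], shp)
    start <- pmin(pmax(as.integer(center) - size %/% 2L, 1L), shp - size + 1L)
  } else {
    start <- vapply(shp - size + 1L, function(m) sample.int(m, 1), integer(1))
  }
  ix <- lapply(1:3, function(a) start[a] + seq_len(size) - 1L)
  inputs <- x[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
  cls <- remap_labels(y[ix[[1]], ix[[2]], ix[[3]]])
  list(inputs = inputs,
       target_classes = cls,
       target_onehot = onehot(cls))
}

#' Label-safe data augmentation
#'
#' Applies, with probability 1/2 each: a flip along each spatial axis and
#' a rotation by a random multiple of 90 degrees in the axial
#' (height-width) plane — the same transform to inputs and both target
#' representations — plus an intensity affine transform (scale ~
#' U(0.9, 1.1), shift ~ U(-0.1, 0.1) on normalized intensities) on the
#' inputs only.
#'
#' @param sample a training sample from [random_crop()].
#' @param flip optional logical(3) forcing the per-axis flips.
#' @param k_rot optional rotation count (0-3) forcing the axial rotation.
#' @param intensity optional numeric(2) `c(scale, shift)` forcing the
#'   intensity transform.
#' @return the augmented training sample.
#' @export
augment <- function(sample, flip = NULL, k_rot = NULL, intensity = NULL) {
  if (is.null(flip)) flip <- runif(3) < 0.5
  if (is.null(k_rot)) k_rot <- sample.int(4L, 1L) - 1L
  if (is.null(intensity)) intensity <- c(runif(1, 0.9, 1.1), runif(1, -0.1, 0.1))
  tf_vol <- function(v) {
    if (flip[1]) v <- v[rev(seq_len(dim(v)[1])), , , drop = FALSE]
    if (flip[2]) v <- v[, rev(seq_len(dim(v)[2])), , drop = FALSE]
    if (flip[3]) v <- v[, , rev(seq_len(dim(v)[3])), drop = FALSE]
    for (i in seq_len(k_rot %% 4L)) {
      # 90 deg rotation in the (height, width) plane: transpose + reverse
      v <- aperm(v, c(1, 3, 2))
      v <- v[, rev(seq_len(dim(v)[2])), , drop = FALSE]
    }
    v
  }
  inputs <- sample$inputs
  for (m in seq_len(dim(inputs)[4])) inputs[, , , m] <- tf_vol(inputs[, , , m])
  inputs <- inputs * intensity[1] + intensity[2]
  cls <- tf_vol(sample$target_classes)
  oh <- sample$target_onehot
  for (c in seq_len(dim(oh)[4])) oh[, , , c] <- tf_vol(oh[, , , c])
  list(inputs = inputs,
       target_classes = array(as.integer(cls), dim(cls)),
       target_onehot = oh)
}
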