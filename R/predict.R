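#' Sliding-window inference on a full volume
#'
#' The stack is z-score normalized, zero-padded up to the window size if
#' needed, and covered by cubic windows of side `crop_size` at stride
#' `crop_size / 2`; the stage-2 softmax probabilities are averaged over
#' overlapping windows before the voxelwise argmax, and class index 3 is
#' mapped back to raw label 4. The output grid matches the input grid.
#'
#' Two postprocessing steps reflect the conventions of the domain:
#' voxels outside the brain mask (zero intensity in every modality, the
#' background convention of skull-stripped data) are fixed to healthy,
#' and only the largest 6-connected component of the predicted
#' whole-tumor mask is kept — the tumors this pipeline models are
#' single-focal, so detached satellite predictions are spurious. Both
#' steps can be disabled.
#'
#' @param checkpoint an `icunet_checkpoint` (or a bare `icunet_model`).
#' @param stack a `modality_stack`.
#' @param crop_size window side; defaults to the training crop size.
#' @param normalize z-score the stack first (disable when the stack is
#'   already normalized).
#' @param mask_background force all-zero-intensity voxels to label 0.
#' @param largest_component keep only the largest 6-connected component
#'   of the predicted whole-tumor mask.
#' @return a `label_volume` with values in \{0, 1, 2, 4\}.
#' @export
predict_case <- function(checkpoint, stack, crop_size = NULL, normalize = TRUE,
                         mask_background = TRUE, largest_component = TRUE) {
  brain <- apply(stack$data != 0, 1:3, any)
  model <- if (inherits(checkpoint, "icunet_checkpoint")) checkpoint$model else checkpoint
  if (is.null(crop_size)) {
    crop_size <- if (inherits(checkpoint, "icunet_checkpoint"))
      checkpoint$config$crop_size else 128L
  }
  if (normalize) stack <- zscore_normalize(stack)
  x <- stack$data
  shp0 <- dim(x)[1:3]
  shp <- pmax(shp0, crop_size)
  lo <- (shp - shp0) %/% 2L
  if (any(shp > shp0)) {
    xp <- array(0, c(shp, 4L))
    xp[lo[1] + seq_len(shp0[1]), lo[2] + seq_len(shp0[2]),
       lo[3] + seq_len(shp0[3]), ] <- x
    x <- xp
  }
  starts <- lapply(1:3, function(a) {
    s <- unique(c(seq(1L, shp[a] - crop_size + 1L, by = max(1L, crop_size %/% 2L)),
                  shp[a] - crop_size + 1L))
    as.integer(s)
  })
  prob_sum <- array(0, c(shp, 4L))
  count <- array(0, shp)
  for (sd_ in starts[[1]]) for (sh in starts[[2]]) for (sw in starts[[3]]) {
    ix <- list(sd_ + seq_len(crop_size) - 1L, sh + seq_len(crop_size) - 1L,
               sw + seq_len(crop_size) - 1L)
    win <- x[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
    fw <- icunet_forward(model, win, training = FALSE)
    probs <- channel_softmax_(fw$stage2_logits)
    prob_sum[ix[[1]], ix[[2]], ix[[3]], ] <-
      prob_sum[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE] + probs
    count[ix[[1]], ix[[2]], ix[[3]]] <- count[ix[[1]], ix[[2]], ix[[3]]] + 1
  }
  probs <- prob_sum / as.vector(count)   # count recycles over the channel axis
  cls <- channel_argmax_(probs)
  cls <- cls[lo[1] + seq_len(shp0[1]), lo[2] + seq_len(shp0[2]),
             lo[3] + seq_len(shp0[3]), drop = FALSE]
  if (mask_background) cls[!brain] <- 0L
  if (largest_component) cls[!largest_component_(cls > 0L)] <- 0L
  new_label_volume(array(labels_from_classes(as.integer(cls)), shp0),
                   affine = stack$affine)
}

# Largest 6-connected component of a logical 3D mask (all-FALSE passes
# through unchanged).
largest_component_ <- function(mask) {
  d <- dim(mask)
  ids <- label_components6(as.vector(mask), d[1], d[2], d[3])
  if (max(ids) == 0L) return(mask)
  keep <- which.max(tabulate(ids))
  array(ids == keep, d)
}
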