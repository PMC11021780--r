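#' Loss weights of the two-stage composite objective
#'
#' The composite objective is
#' `total = 0.5 * CE(stage1) + 0.5 * CE(stage2) + Dice(stage2)`:
#' cross-entropy supervises both the coarse and the refined class scores,
#' while the Dice term — which directly targets the class-imbalanced
#' overlap — applies to the refinement stage only.
#'
#' @param w_ce1,w_ce2,w_dc2 nonnegative weights of the stage-1
#'   cross-entropy, stage-2 cross-entropy and stage-2 Dice terms.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(w_ce1 = 0.5, w_ce2 = 0.5, w_dc2 = 1.0) {
  stopifnot(w_ce1 >= 0, w_ce2 >= 0, w_dc2 >= 0)
  structure(list(w_ce1 = w_ce1, w_ce2 = w_ce2, w_dc2 = w_dc2),
            class = "loss_weights")
}

check_loss_shapes_ <- function(logits, target) {
  if (!identical(dim(logits), dim(target))) {
    stopf_("logits and target shapes differ: (%s) vs (%s)",
           paste(dim(logits), collapse = ","), paste(dim(target), collapse = ","))
  }
}

# log-softmax over the channel (last) axis, numerically stabilized
channel_log_softmax_ <- function(logits) {
  C <- dim(logits)[length(dim(logits))]
  m <- matrix(logits, ncol = C)
  z <- m - row_max(m)
  z - log(rowSums(exp(z)))
}

#' Voxel-mean multi-class cross-entropy
#'
#' \eqn{-\frac{1}{N}\sum_n \sum_i x_{ni} \log \hat x_{ni}} with
#' \eqn{\hat x} the channelwise softmax of the class scores; the mean
#' over voxels makes the value independent of crop size.
#'
#' @param logits class-score array (D, H, W, 4).
#' @param target_onehot matching one-hot target array.
#' @return nonnegative scalar.
#' @export
cross_entropy <- function(logits, target_onehot) {
  check_loss_shapes_(logits, target_onehot)
  ls <- channel_log_softmax_(logits)
  C <- dim(logits)[length(dim(logits))]
  -sum(matrix(target_onehot, ncol = C) * ls) / (length(logits) / C)
}

#' Soft Dice loss over the foreground classes
#'
#' Per foreground class c:
#' \eqn{1 - (2\sum x_c \hat x_c + \epsilon) / (\sum x_c + \sum \hat x_c + \epsilon)},
#' with \eqn{\hat x} the softmax probabilities; the returned value is the
#' mean over the three foreground classes (necrotic, edema, enhancing).
#' The background class is excluded so that the empty space that
#' dominates brain volumes cannot swamp the overlap signal.
#'
#' @param logits class-score array (D, H, W, 4).
#' @param target_onehot matching one-hot target array.
#' @param epsilon smoothing added to numerator and denominator.
#' @return scalar in approximately [0, 1].
#' @export
dice_loss <- function(logits, target_onehot, epsilon = 1e-5) {
  check_loss_shapes_(logits, target_onehot)
  C <- dim(logits)[length(dim(logits))]
  P <- exp(channel_log_softmax_(logits))
  Tm <- matrix(target_onehot, ncol = C)
  terms <- vapply(2:C, function(c) {
    inter <- sum(P[, c] * Tm[, c])
    1 - (2 * inter + epsilon) / (sum(Tm[, c]) + sum(P[, c]) + epsilon)
  }, numeric(1))
  mean(terms)
}

#' The two-stage composite loss
#'
#' @param stage1_logits,stage2_logits class-score arrays of the two
#'   stages.
#' @param target_onehot one-hot target.
#' @param weights a [loss_weights()].
#' @return a `loss_report` list with components `ce1`, `ce2`, `dc2` and
#'   `total`.
#' @export
composite_loss <- function(stage1_logits, stage2_logits, target_onehot,
                           weights = loss_weights()) {
  ce1 <- cross_entropy(stage1_logits, target_onehot)
  ce2 <- cross_entropy(stage2_logits, target_onehot)
  dc2 <- dice_loss(stage2_logits, target_onehot)
  structure(list(ce1 = ce1, ce2 = ce2, dc2 = dc2,
                 total = weights$w_ce1 * ce1 + weights$w_ce2 * ce2 +
                   weights$w_dc2 * dc2),
            class = "loss_report")
}

# --- gradients ---------------------------------------------------------------

# d(cross-entropy)/d(logits): (softmax - target) / Nvox
cross_entropy_grad_ <- function(logits, target_onehot) {
  C <- dim(logits)[length(dim(logits))]
  N <- length(logits) / C
  P <- exp(channel_log_softmax_(logits))
  array((P - matrix(target_onehot, ncol = C)) / N, dim(logits))
}

# d(dice_loss)/d(logits), through the per-class ratios and the softmax
dice_loss_grad_ <- function(logits, target_onehot, epsilon = 1e-5) {
  C <- dim(logits)[length(dim(logits))]
  P <- exp(channel_log_softmax_(logits))
  Tm <- matrix(target_onehot, ncol = C)
  dP <- matrix(0, nrow(P), C)
  nf <- C - 1
  for (c in 2:C) {
    inter <- sum(P[, c] * Tm[, c])
    denom <- sum(Tm[, c]) + sum(P[, c]) + epsilon
    num <- 2 * inter + epsilon
    # d term_c / d P[,c] = -(2*T*denom - num) / denom^2 ; mean over classes
    dP[, c] <- -(2 * Tm[, c] * denom - num) / denom^2 / nf
  }
  dlog <- P * (dP - rowSums(dP * P))
  array(dlog, dim(logits))
}

composite_loss_grads_ <- function(stage1_logits, stage2_logits, target_onehot,
                                  weights = loss_weights()) {
  list(dlogits1 = weights$w_ce1 * cross_entropy_grad_(stage1_logits, target_onehot),
       dlogits2 = weights$w_ce2 * cross_entropy_grad_(stage2_logits, target_onehot) +
         weights$w_dc2 * dice_loss_grad_(stage2_logits, target_onehot))
}
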