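#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with first-moment decay
#' 0.95, decoupled weight decay 1e-5, constant learning rate 0.001,
#' batches of 3 random 128-voxel crops, 550 optimizer steps. For
#' desk-scale experiments on phantoms, shrink `crop_size`, `base_width`
#' and the attention capacities.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param beta1 Adam first-moment decay ("momentum").
#' @param beta2 Adam second-moment decay.
#' @param batch_size crops per optimizer step.
#' @param iterations optimizer steps.
#' @param crop_size cubic patch side (divisible by 16).
#' @param base_width first-level channel width of both stages.
#' @param dyconv_kernels parallel kernels K of the dynamic convolutions.
#' @param ema_bases bases K of the EM-attention module.
#' @param seed master seed: fixes initialization, sampling and
#'   augmentation.
#' @param loss_weights a [loss_weights()].
#' @param tumor_bias tumor-centered cropping probability.
#' @param augment_data apply random flips/rotations/intensity shifts.
#' @param temperature_anneal anneal the dynamic-convolution softmax
#'   temperature from 30 to 1 over the first 30\% of steps (avoids early
#'   winner-take-all collapse of the kernel attention).
#' @param checkpoint_every write a checkpoint every this many steps
#'   (in addition to the final one); `Inf` for final-only.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 1e-5,
                         beta1 = 0.95, beta2 = 0.999, batch_size = 3L,
                         iterations = 550L, crop_size = 128L,
                         base_width = 16L, dyconv_kernels = 4L,
                         ema_bases = 64L, seed = 1L,
                         loss_weights = icunet::loss_weights(),
                         tumor_bias = 0.5, augment_data = TRUE,
                         temperature_anneal = TRUE,
                         checkpoint_every = Inf) {
  stopifnot(learning_rate > 0, batch_size >= 1, iterations >= 1,
            crop_size %% 16 == 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 crop_size = as.integer(crop_size),
                 base_width = as.integer(base_width),
                 dyconv_kernels = as.integer(dyconv_kernels),
                 ema_bases = as.integer(ema_bases),
                 seed = as.integer(seed), loss_weights = loss_weights,
                 tumor_bias = tumor_bias, augment_data = augment_data,
                 temperature_anneal = temperature_anneal,
                 checkpoint_every = checkpoint_every),
            class = "train_config")
}

set_stage_temperature_ <- function(stage, tau) {
  walk <- function(node) {
    if (!is.list(node)) return(node)
    if (!is.null(node$kind) && node$kind == "dyconv") {
      node$config$temperature <- tau
      return(node)
    }
    for (i in seq_along(node)) if (is.list(node[[i]])) node[[i]] <- walk(node[[i]])
    node
  }
  stage$blocks <- walk(stage$blocks)
  stage
}

adam_init_ <- function(stage, paths) {
  lapply(paths, function(p) {
    w <- get_path_(stage, p)
    list(m = array(0, dim(w) %||% length(w)), v = array(0, dim(w) %||% length(w)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update_ <- function(stage, paths, gradtree, state, step, cfg) {
  lr <- cfg$learning_rate
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^step; bc2 <- 1 - b2^step
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    g <- get_path_(gradtree, grad_path_(p))
    w <- get_path_(stage, p)
    st <- state[[i]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    upd <- (st$m / bc1) / (sqrt(st$v / bc2) + 1e-8)
    decay <- if (is.matrix(w) || length(dim(w)) > 1) cfg$weight_decay else 0
    w <- w - lr * upd - lr * decay * w
    stage <- set_path_(stage, p, w)
    state[[i]] <- st
  }
  list(stage = stage, state = state)
}

#' Train the cascaded network
#'
#' Per optimizer step: draw a batch of random (tumor-biased) crops from
#' the labeled cases, augment, run the cascade forward, evaluate the
#' composite loss, backpropagate through both stages (including the
#' coupling through the fused stage-1 probabilities) and take one Adam
#' step. The EM-attention global bases are maintained by momentum as a
#' side effect of the training-mode forward pass. Everything is a pure
#' function of the configuration seed and the input cases.
#'
#' @param config a [train_config()].
#' @param cases a list of labeled cases (each a list with `stack` and
#'   `label`, e.g. `phantom_case`s), or a directory containing NIfTI
#'   cases.
#' @param verbose print the loss every 25 steps.
#' @return an `icunet_checkpoint`: list with `model`, `config`,
#'   `iteration` and `log` (a tibble with columns `iteration`, `ce1`,
#'   `ce2`, `dc2`, `total`).
#' @export
train <- function(config, cases, verbose = FALSE) {
  if (is.character(cases)) cases <- load_case_directory_(cases)
  cases <- Filter(function(cs) !is.null(cs$label), cases)
  if (length(cases) < 1) stopf_("training requires at least one labeled case")
  norm_cases <- lapply(cases, function(cs) {
    list(stack = zscore_normalize(cs$stack), label = cs$label)
  })
  model <- with_seed_(config$seed,
                      build_icunet(base_width = config$base_width,
                                   dyconv_kernels = config$dyconv_kernels,
                                   ema_bases = config$ema_bases,
                                   seed = derive_seeds_(config$seed, 1)))
  paths1 <- enumerate_params_(model$stage1)
  paths2 <- enumerate_params_(model$stage2)
  st1 <- adam_init_(model$stage1, paths1)
  st2 <- adam_init_(model$stage2, paths2)
  log <- vector("list", config$iterations)
  anneal_until <- ceiling(0.3 * config$iterations)
  with_seed_(config$seed + 1L, {
    for (it in seq_len(config$iterations)) {
      if (config$temperature_anneal && it <= anneal_until + 1) {
        tau <- if (it > anneal_until) 1 else 30 - (30 - 1) * (it - 1) / anneal_until
        model$stage2 <- set_stage_temperature_(model$stage2, tau)
      }
      g1 <- NULL; g2 <- NULL
      rep_loss <- c(ce1 = 0, ce2 = 0, dc2 = 0, total = 0)
      for (b in seq_len(config$batch_size)) {
        cs <- norm_cases[[sample.int(length(norm_cases), 1)]]
        smp <- random_crop(cs$stack, cs$label, config$crop_size,
                           tumor_bias = config$tumor_bias)
        if (config$augment_data) smp <- augment(smp)
        fw <- icunet_forward(model, smp$inputs, training = TRUE)
        model <- fw$model
        rep <- composite_loss(fw$stage1_logits, fw$stage2_logits,
                              smp$target_onehot, config$loss_weights)
        if (!is.finite(rep$total)) {
          stopf_("non-finite loss at iteration %d (ce1=%.4g ce2=%.4g dc2=%.4g)",
                 it, rep$ce1, rep$ce2, rep$dc2)
        }
        gr <- composite_loss_grads_(fw$stage1_logits, fw$stage2_logits,
                                    smp$target_onehot, config$loss_weights)
        bw <- icunet_backward_(model, gr$dlogits1, gr$dlogits2, fw$cache)
        g1 <- add_trees_(g1, bw$grads1)
        g2 <- add_trees_(g2, bw$grads2)
        rep_loss <- rep_loss + c(rep$ce1, rep$ce2, rep$dc2, rep$total)
      }
      g1 <- scale_tree_(g1, 1 / config$batch_size)
      g2 <- scale_tree_(g2, 1 / config$batch_size)
      u1 <- adam_update_(model$stage1, paths1, g1, st1, it, config)
      model$stage1 <- u1$stage; st1 <- u1$state
      u2 <- adam_update_(model$stage2, paths2, g2, st2, it, config)
      model$stage2 <- u2$stage; st2 <- u2$state
      rep_loss <- rep_loss / config$batch_size
      log[[it]] <- tibble::tibble(iteration = it, ce1 = unname(rep_loss[1]),
                                  ce2 = unname(rep_loss[2]),
                                  dc2 = unname(rep_loss[3]),
                                  total = unname(rep_loss[4]))
      if (verbose && (it %% 25 == 0 || it == 1)) {
        message(sprintf("step %4d  total %.4f (ce1 %.4f ce2 %.4f dc2 %.4f)",
                        it, rep_loss[4], rep_loss[1], rep_loss[2], rep_loss[3]))
      }
    }
  })
  structure(list(model = model, config = config,
                 iteration = config$iterations,
                 log = do.call(rbind, log)),
            class = "icunet_checkpoint")
}

load_case_directory_ <- function(directory) {
  segs <- list.files(directory, pattern = "_seg\\.nii(\\.gz)?$")
  flairs <- list.files(directory, pattern = "_flair\\.nii(\\.gz)?$")
  ids <- sub("_flair\\.nii(\\.gz)?$", "", flairs)
  if (length(ids) == 0) stopf_("no cases found in '%s'", directory)
  lapply(ids, function(id) load_case(directory, id))
}

#' Save / load a training checkpoint
#'
#' The checkpoint carries all weights, the EM-attention global bases,
#' the full configuration and the loss log; reloading reproduces
#' identical predictions.
#'
#' @param checkpoint an `icunet_checkpoint`.
#' @param path file path (RDS).
#' @return `load_checkpoint` returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "icunet_checkpoint")) stopf_("'%s' is not a checkpoint", path)
  ck
}
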