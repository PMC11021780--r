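#' Stage configuration for one 3D encoder-decoder
#'
#' Each stage is a 3D U-Net with four resolution levels: four encoder
#' blocks (two 3x3x3 convolutions each, group normalization, ReLU)
#' separated by 2x max pooling, a bottleneck block, and four decoder
#' steps (trilinear 2x upsampling, pointwise channel reduction,
#' concatenation with the same-resolution encoder feature, two
#' convolutions), closed by a pointwise convolution to the class scores.
#' Channel width doubles per level, so with `base_width` 16 the deepest
#' (fourth) lateral connection carries 128 channels at 1/8 resolution.
#'
#' @param in_channels input channels (4 for the coarse stage, 8 for the
#'   refinement stage).
#' @param out_channels output channels (4 classes).
#' @param base_width channels of the first level (default 16).
#' @param conv_kind "standard" or "dynamic" for the 3x3x3 convolutions.
#' @param ema_on_fourth_lateral apply EM attention to the deepest skip
#'   tensor before concatenation.
#' @param gn_groups group-normalization groups (clipped to the channel
#'   count).
#' @param dyconv_kernels,dyconv_reduction dynamic-convolution bank size K
#'   and attention-head reduction r.
#' @param ema_bases number of EM-attention bases.
#' @return a `stage_config` list.
#' @export
stage_config <- function(in_channels = 4L, out_channels = 4L, base_width = 16L,
                         conv_kind = c("standard", "dynamic"),
                         ema_on_fourth_lateral = FALSE, gn_groups = 8L,
                         dyconv_kernels = 4L, dyconv_reduction = 4L,
                         ema_bases = 64L) {
  conv_kind <- match.arg(conv_kind)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_width = as.integer(base_width),
                 levels = 4L,
                 conv_kind = conv_kind,
                 ema_on_fourth_lateral = ema_on_fourth_lateral,
                 gn_groups = as.integer(gn_groups),
                 dyconv_kernels = as.integer(dyconv_kernels),
                 dyconv_reduction = as.integer(dyconv_reduction),
                 ema_bases = as.integer(ema_bases)),
            class = "stage_config")
}

# --- primitive layers --------------------------------------------------------

new_conv_ <- function(cin, cout, k = 3L) {
  list(kind = "conv", k = as.integer(k), cin = cin, cout = cout,
       par = list(W = matrix(rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))),
                             k^3 * cin, cout),
                  b = numeric(cout)))
}

new_dyconv_ <- function(cin, cout, config_proto) {
  cfg <- dyconv_config(cin, cout, kernel_size = 3L,
                       n_kernels = config_proto$dyconv_kernels,
                       reduction = config_proto$dyconv_reduction)
  ly <- init_dyconv_layer_(cfg)
  list(kind = "dyconv", config = cfg,
       par = ly[c("W", "b", "hW1", "hb1", "hW2", "hb2")])
}

new_gn_ <- function(channels, groups) {
  list(kind = "gn", groups = as.integer(min(groups, channels)),
       par = list(gamma = rep(1, channels), beta = numeric(channels)))
}

new_ema_ <- function(channels, n_bases) {
  ly <- init_ema_layer_(channels, n_bases)
  list(kind = "ema", config = ema_config(channels, n_bases = n_bases),
       par = ly[c("win", "bin", "wout", "bout")],
       mu = ly$mu)
}

conv_fwd_ <- function(ly, x) {
  shp <- dim(x)
  N <- prod(shp[1:3])
  if (ly$k == 1L) {
    Xm <- matrix(x, ncol = shp[4])
    y <- Xm %*% ly$par$W
    y <- y + rep(ly$par$b, each = N)
    dim(y) <- c(shp[1:3], ly$cout)
    return(list(out = y, cache = list(Xm = Xm, shp = shp)))
  }
  y <- conv3d_fwd(x, shp[1], shp[2], shp[3], shp[4], ly$par$W, ly$par$b, ly$k)
  dim(y) <- c(shp[1:3], ly$cout)
  list(out = y, cache = list(x = x, shp = shp))
}

conv_bwd_ <- function(ly, dout, cache) {
  shp <- cache$shp
  N <- prod(shp[1:3])
  if (ly$k == 1L) {
    dy <- matrix(dout, N, ly$cout)
    dW <- crossprod(cache$Xm, dy)
    dx <- dy %*% t(ly$par$W)
    dim(dx) <- shp
    return(list(dx = dx, grads = list(W = dW, b = colSums(dy))))
  }
  r <- conv3d_bwd(cache$x, dout, shp[1], shp[2], shp[3], shp[4], ly$par$W, ly$k)
  dx <- r$dx
  dim(dx) <- shp
  list(dx = dx, grads = list(W = r$dW, b = r$db))
}

gn_fwd_ <- function(ly, x) {
  shp <- dim(x)
  C <- shp[4]
  G <- ly$groups
  cs <- C %/% G
  Xm <- matrix(x, ncol = C)            # N x C
  N <- nrow(Xm)
  dim(Xm) <- c(N * cs, G)              # columns are groups
  mu <- colMeans(Xm)
  xc <- sweep(Xm, 2, mu)
  inv_sd <- 1 / sqrt(colMeans(xc^2) + 1e-5)
  xhat <- sweep(xc, 2, inv_sd, "*")
  dim(xhat) <- c(N, C)
  y <- sweep(sweep(xhat, 2, ly$par$gamma, "*"), 2, ly$par$beta, "+")
  list(out = array(y, shp),
       cache = list(xhat = xhat, inv_sd = inv_sd, shp = shp, cs = cs, G = G))
}

gn_bwd_ <- function(ly, dout, cache) {
  shp <- cache$shp
  C <- shp[4]
  N <- prod(shp[1:3])
  dy <- matrix(dout, N, C)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, ly$par$gamma, "*")
  cs <- cache$cs; G <- cache$G
  dim(dxhat) <- c(N * cs, G)
  dim(xhat) <- c(N * cs, G)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat - sweep(xhat, 2, m2, "*"), 2, m1) # dxhat - mean - xhat*mean
  dx <- sweep(dx, 2, cache$inv_sd, "*")
  dim(dx) <- c(N, C)
  list(dx = array(dx, shp), grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd_ <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

layer_fwd_ <- function(ly, x) {
  switch(ly$kind,
         conv = conv_fwd_(ly, x),
         dyconv = {
           r <- dyconv_fwd_(x, ly$par, ly$config)
           list(out = r$out, cache = r$cache)
         },
         gn = gn_fwd_(ly, x),
         stopf_("unknown layer kind %s", ly$kind))
}

layer_bwd_ <- function(ly, dout, cache) {
  switch(ly$kind,
         conv = conv_bwd_(ly, dout, cache),
         dyconv = dyconv_bwd_(dout, ly$par, ly$config, cache),
         gn = gn_bwd_(ly, dout, cache),
         stopf_("unknown layer kind %s", ly$kind))
}

# conv -> gn -> relu
unit_fwd_ <- function(blk, x) {
  c1 <- layer_fwd_(blk$c, x)
  n1 <- layer_fwd_(blk$n, c1$out)
  r1 <- relu_fwd_(n1$out)
  list(out = r1$out, cache = list(c = c1$cache, n = n1$cache, r = r1$cache))
}

unit_bwd_ <- function(blk, dout, cache) {
  d <- dout * cache$r
  nb <- layer_bwd_(blk$n, d, cache$n)
  cb <- layer_bwd_(blk$c, nb$dx, cache$c)
  list(dx = cb$dx, grads = list(c = cb$grads, n = nb$grads))
}

block_fwd_ <- function(blk, x) {
  u1 <- unit_fwd_(list(c = blk$c1, n = blk$n1), x)
  u2 <- unit_fwd_(list(c = blk$c2, n = blk$n2), u1$out)
  list(out = u2$out, cache = list(u1 = u1$cache, u2 = u2$cache))
}

block_bwd_ <- function(blk, dout, cache) {
  b2 <- unit_bwd_(list(c = blk$c2, n = blk$n2), dout, cache$u2)
  b1 <- unit_bwd_(list(c = blk$c1, n = blk$n1), b2$dx, cache$u1)
  list(dx = b1$dx,
       grads = list(c1 = b1$grads$c, n1 = b1$grads$n,
                    c2 = b2$grads$c, n2 = b2$grads$n))
}

# --- stage construction ------------------------------------------------------

#' Build one encoder-decoder stage
#'
#' @param config a [stage_config()].
#' @param seed integer seed for weight initialization.
#' @return a `stage` object: the configuration plus all parameter arrays.
#' @export
build_stage <- function(config, seed = 1L) {
  w <- config$base_width
  g <- config$gn_groups
  mk_conv <- function(cin, cout) {
    if (config$conv_kind == "dynamic") new_dyconv_(cin, cout, config)
    else new_conv_(cin, cout, 3L)
  }
  with_seed_(seed, {
    widths <- w * 2^(0:3)
    enc <- vector("list", 4)
    cin <- config$in_channels
    for (l in 1:4) {
      enc[[l]] <- list(c1 = mk_conv(cin, widths[l]), n1 = new_gn_(widths[l], g),
                       c2 = mk_conv(widths[l], widths[l]), n2 = new_gn_(widths[l], g))
      cin <- widths[l]
    }
    bott <- list(c1 = mk_conv(widths[4], w * 16L), n1 = new_gn_(w * 16L, g),
                 c2 = mk_conv(w * 16L, w * 16L), n2 = new_gn_(w * 16L, g))
    dec <- vector("list", 4)
    prev <- w * 16L
    for (l in 4:1) {
      dec[[l]] <- list(up = new_conv_(prev, widths[l], 1L),
                       c1 = mk_conv(2L * widths[l], widths[l]),
                       n1 = new_gn_(widths[l], g),
                       c2 = mk_conv(widths[l], widths[l]),
                       n2 = new_gn_(widths[l], g))
      prev <- widths[l]
    }
    final <- new_conv_(widths[1], config$out_channels, 1L)
    ema <- if (config$ema_on_fourth_lateral) new_ema_(widths[4], config$ema_bases) else NULL
    structure(list(config = config,
                   blocks = list(enc = enc, bott = bott, dec = dec,
                                 final = final, ema = ema)),
              class = "icunet_stage")
  })
}

check_side_ <- function(shp) {
  if (any(shp[1:3] %% 16 != 0)) {
    stopf_("spatial size (%s) must be divisible by 16 (four 2x poolings)",
           paste(shp[1:3], collapse = "x"))
  }
}

#' Forward pass through one stage
#'
#' @param stage a built stage.
#' @param x input array (D, H, W, in_channels), spatial sides divisible
#'   by 16.
#' @param training logical; enables EM-attention basis maintenance.
#' @return list with `out` (class-score array), `stage` (with updated
#'   attention state when training), `cache` (for the backward pass) and
#'   `internals` (lateral shapes, for structural audits).
#' @export
stage_forward <- function(stage, x, training = FALSE) {
  shp <- dim(x)
  check_side_(shp)
  if (shp[4] != stage$config$in_channels) {
    stopf_("stage expects %d input channels, got %d", stage$config$in_channels, shp[4])
  }
  bl <- stage$blocks
  caches <- list(enc = vector("list", 4), pool = vector("list", 4),
                 dec = vector("list", 4))
  skips <- vector("list", 4)
  feats <- x
  for (l in 1:4) {
    b <- block_fwd_(bl$enc[[l]], feats)
    caches$enc[[l]] <- b$cache
    skips[[l]] <- b$out
    d <- dim(b$out)
    p <- maxpool3d_fwd(b$out, d[1], d[2], d[3], d[4])
    caches$pool[[l]] <- list(idx = p$idx, in_dim = d)
    feats <- array(p$y, c(d[1:3] %/% 2L, d[4]))
  }
  b <- block_fwd_(bl$bott, feats)
  caches$bott <- b$cache
  feats <- b$out
  internals <- list(lateral4_shape = dim(skips[[4]]))
  if (!is.null(bl$ema)) {
    er <- ema_forward(skips[[4]], c(bl$ema$par, list(mu = bl$ema$mu)),
                      bl$ema$config, training = training)
    caches$ema <- er$cache
    skips[[4]] <- er$out
    if (training) stage$blocks$ema$mu <- er$layer$mu
  }
  for (l in 4:1) {
    d <- dim(feats)
    up <- array(upsample2x_fwd(feats, d[1], d[2], d[3], d[4]),
                c(2L * d[1:3], d[4]))
    u <- conv_fwd_(bl$dec[[l]]$up, up)
    cat_in <- array(c(u$out, skips[[l]]), c(dim(u$out)[1:3],
                                            dim(u$out)[4] + dim(skips[[l]])[4]))
    b <- block_fwd_(bl$dec[[l]][c("c1", "n1", "c2", "n2")], cat_in)
    caches$dec[[l]] <- list(up_in_dim = d, up = u$cache, blk = b$cache,
                            n_up = dim(u$out)[4])
    feats <- b$out
  }
  fin <- conv_fwd_(bl$final, feats)
  caches$final <- fin$cache
  list(out = fin$out, stage = stage, cache = caches, internals = internals)
}

stage_backward_ <- function(stage, dout, caches) {
  bl <- stage$blocks
  grads <- list(enc = vector("list", 4), dec = vector("list", 4))
  fb <- conv_bwd_(bl$final, dout, caches$final)
  grads$final <- fb$grads
  d <- fb$dx
  dskips <- vector("list", 4)
  for (l in 1:4) {
    cc <- caches$dec[[l]]
    b <- block_bwd_(bl$dec[[l]][c("c1", "n1", "c2", "n2")], d, cc$blk)
    n_up <- cc$n_up
    dcat <- b$dx
    dup_out <- dcat[, , , seq_len(n_up), drop = FALSE]
    dskips[[l]] <- dcat[, , , n_up + seq_len(dim(dcat)[4] - n_up), drop = FALSE]
    ub <- conv_bwd_(bl$dec[[l]]$up, dup_out, cc$up)
    di <- cc$up_in_dim
    d <- array(upsample2x_bwd(ub$dx, di[1], di[2], di[3], di[4]), di)
    grads$dec[[l]] <- c(b$grads, list(up = ub$grads))
  }
  b <- block_bwd_(bl$bott, d, caches$bott)
  grads$bott <- b$grads
  d <- b$dx
  if (!is.null(bl$ema)) {
    eb <- ema_backward_(dskips[[4]], c(bl$ema$par, list(mu = bl$ema$mu)),
                        caches$ema)
    grads$ema <- eb$grads
    dskips[[4]] <- eb$dx
  }
  for (l in 4:1) {
    pc <- caches$pool[[l]]
    dpool <- maxpool3d_bwd(d, pc$idx, prod(pc$in_dim))
    dblock <- array(dpool, pc$in_dim) + dskips[[l]]
    b <- block_bwd_(bl$enc[[l]], dblock, caches$enc[[l]])
    grads$enc[[l]] <- b$grads
    d <- b$dx
  }
  list(dx = d, grads = grads)
}

# --- the two-stage cascade ---------------------------------------------------

#' Build the full two-stage cascaded network
#'
#' Stage 1 segments the four-modality input coarsely with standard
#' convolutions; its class probabilities are concatenated with the input
#' (8 channels) and refined by stage 2, which uses dynamic convolutions
#' throughout and EM attention on its fourth lateral connection.
#'
#' @param base_width first-level channel width (16 reproduces the
#'   reference geometry: a 128-channel, 1/8-resolution fourth lateral for
#'   a 128-voxel input side).
#' @param dyconv_kernels,ema_bases capacity of the dynamic-convolution
#'   bank and the EM-attention basis set.
#' @param seed integer seed for weight initialization.
#' @return an `icunet_model`.
#' @export
build_icunet <- function(base_width = 16L, dyconv_kernels = 4L,
                         ema_bases = 64L, seed = 1L) {
  s1 <- build_stage(stage_config(in_channels = 4L, base_width = base_width,
                                 conv_kind = "standard"),
                    seed = seed)
  s2 <- build_stage(stage_config(in_channels = 8L, base_width = base_width,
                                 conv_kind = "dynamic",
                                 ema_on_fourth_lateral = TRUE,
                                 dyconv_kernels = dyconv_kernels,
                                 ema_bases = ema_bases),
                    seed = seed + 1L)
  structure(list(stage1 = s1, stage2 = s2), class = "icunet_model")
}

#' Fuse the coarse result with the input for the refinement stage
#'
#' Channelwise softmax of the stage-1 class scores concatenated with the
#' (normalized) modality stack; keeping probabilities rather than a hard
#' argmax keeps the cascade differentiable end to end.
#'
#' @param stack_arr input array (D, H, W, 4).
#' @param stage1_logits class-score array (D, H, W, 4).
#' @return fused array (D, H, W, 8): probabilities then modalities.
#' @export
fuse_inputs <- function(stack_arr, stage1_logits) {
  if (!identical(dim(stack_arr)[1:3], dim(stage1_logits)[1:3])) {
    stopf_("fuse_inputs: spatial shapes differ")
  }
  probs <- channel_softmax_(stage1_logits)
  array(c(probs, stack_arr), c(dim(stack_arr)[1:3], 8L))
}

channel_softmax_ <- function(logits) {
  shp <- dim(logits)
  m <- matrix(logits, ncol = shp[4])
  array(softmax_rows_(m), shp)
}

#' Full cascade forward pass
#'
#' @param model an `icunet_model`.
#' @param x normalized input array (D, H, W, 4).
#' @param training logical; enables attention-state maintenance.
#' @return list with `stage1_logits`, `stage2_logits`, the (possibly
#'   state-updated) `model`, and `cache` for training.
#' @export
icunet_forward <- function(model, x, training = FALSE) {
  f1 <- stage_forward(model$stage1, x, training = training)
  model$stage1 <- f1$stage
  fused <- fuse_inputs(x, f1$out)
  f2 <- stage_forward(model$stage2, fused, training = training)
  model$stage2 <- f2$stage
  list(stage1_logits = f1$out, stage2_logits = f2$out, model = model,
       cache = list(s1 = f1$cache, s2 = f2$cache,
                    probs1 = fused[, , , 1:4, drop = FALSE]),
       internals = list(stage1 = f1$internals, stage2 = f2$internals,
                        fused_channels = dim(fused)[4]))
}

# Backward through the whole cascade given gradients on both logits
# tensors; the stage-2 input gradient flows through the fused softmax
# back into stage 1.
icunet_backward_ <- function(model, dlogits1, dlogits2, cache) {
  b2 <- stage_backward_(model$stage2, dlogits2, cache$s2)
  dprob <- b2$dx[, , , 1:4, drop = FALSE]
  shp <- dim(dprob)
  P <- matrix(cache$probs1, ncol = 4L)
  dPm <- matrix(dprob, ncol = 4L)
  dl1_fuse <- array(P * (dPm - rowSums(dPm * P)), shp)
  b1 <- stage_backward_(model$stage1, dlogits1 + dl1_fuse, cache$s1)
  list(grads1 = b1$grads, grads2 = b2$grads, dx = b1$dx)
}

#' Structural audit of a built stage
#'
#' Counts the convolution layers by kind and reports the EM-attention
#' placement, for verifying that the refinement stage uses dynamic
#' convolutions for every 3x3x3 convolution while the coarse stage uses
#' none.
#'
#' @param stage a built stage.
#' @return list with counts `n_standard_3x3`, `n_dynamic_3x3`,
#'   `n_pointwise`, and `has_ema`.
#' @export
audit_stage <- function(stage) {
  n_std <- 0L; n_dyn <- 0L; n_pw <- 0L
  note <- function(ly) {
    if (is.null(ly) || is.null(ly$kind)) return()
    if (ly$kind == "dyconv") n_dyn <<- n_dyn + 1L
    else if (ly$kind == "conv" && ly$k == 3L) n_std <<- n_std + 1L
    else if (ly$kind == "conv" && ly$k == 1L) n_pw <<- n_pw + 1L
  }
  bl <- stage$blocks
  for (l in 1:4) { note(bl$enc[[l]]$c1); note(bl$enc[[l]]$c2) }
  note(bl$bott$c1); note(bl$bott$c2)
  for (l in 1:4) { note(bl$dec[[l]]$up); note(bl$dec[[l]]$c1); note(bl$dec[[l]]$c2) }
  note(bl$final)
  list(n_standard_3x3 = n_std, n_dynamic_3x3 = n_dyn, n_pointwise = n_pw,
       has_ema = !is.null(bl$ema))
}

#' Total parameter count of a stage or model
#'
#' @param x a stage or an `icunet_model`.
#' @return integer number of scalar parameters.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "icunet_model")) {
    return(count_parameters(x$stage1) + count_parameters(x$stage2))
  }
  paths <- enumerate_params_(x)
  sum(vapply(paths, function(p) length(get_path_(x, p)), numeric(1)))
}
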