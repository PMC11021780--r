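test_that("stage geometry: width doubling puts 8x base_width channels on the
           fourth lateral at 1/8 resolution", {
  withr::with_seed(51, {
    st <- build_stage(stage_config(in_channels = 4L, base_width = 16L), seed = 2L)
    x <- array(rnorm(32^3 * 4), c(32, 32, 32, 4))
    fw <- stage_forward(st, x)
    expect_identical(fw$internals$lateral4_shape, c(4L, 4L, 4L, 128L))
    expect_identical(dim(fw$out), c(32L, 32L, 32L, 4L))
    # analytic check at the reference input side
    expect_identical(c(128 / 8, 16 * 8), c(16, 128))
  })
})

test_that("indivisible spatial sizes and wrong channel counts are rejected", {
  st <- build_stage(stage_config(in_channels = 4L, base_width = 4L), seed = 3L)
  x <- array(0, c(20, 20, 20, 4))
  expect_error(stage_forward(st, x), "divisible by 16")
  x <- array(0, c(16, 16, 16, 3))
  expect_error(stage_forward(st, x), "channels")
})

test_that("spatial size is preserved across valid input sides", {
  withr::with_seed(52, {
    st <- build_stage(stage_config(in_channels = 4L, base_width = 4L), seed = 4L)
    for (S in c(16L, 32L, 48L)) {
      x <- array(rnorm(S^3 * 4), c(S, S, S, 4L))
      fw <- stage_forward(st, x)
      expect_identical(dim(fw$out), c(S, S, S, 4L))
      expect_identical(fw$internals$lateral4_shape[1:3], rep(S %/% 8L, 3))
    }
  })
})

test_that("structural audit: coarse stage all-standard, refinement stage
           all-dynamic with EM attention", {
  s1 <- build_stage(stage_config(in_channels = 4L, base_width = 4L,
                                 conv_kind = "standard"), seed = 5L)
  s2 <- build_stage(stage_config(in_channels = 8L, base_width = 4L,
                                 conv_kind = "dynamic",
                                 ema_on_fourth_lateral = TRUE,
                                 dyconv_kernels = 2L, ema_bases = 4L), seed = 6L)
  a1 <- audit_stage(s1)
  a2 <- audit_stage(s2)
  expect_identical(a1$n_dynamic_3x3, 0L)
  expect_gt(a1$n_standard_3x3, 0L)
  expect_false(a1$has_ema)
  expect_identical(a2$n_standard_3x3, 0L)
  expect_identical(a2$n_dynamic_3x3, a1$n_standard_3x3)
  expect_true(a2$has_ema)
  # 18 3x3x3 convolutions: 2 per block over 4+1+4 blocks
  expect_identical(a1$n_standard_3x3, 18L)
})

test_that("fused input is stage-1 class probabilities plus the modalities", {
  withr::with_seed(53, {
    x <- array(rnorm(16^3 * 4), c(16, 16, 16, 4))
    logits <- array(rnorm(16^3 * 4), c(16, 16, 16, 4))
    fused <- fuse_inputs(x, logits)
    expect_identical(dim(fused), c(16L, 16L, 16L, 8L))
    psum <- apply(fused[, , , 1:4], 1:3, sum)
    expect_true(all(abs(psum - 1) < 1e-9))
    expect_identical(fused[, , , 5:8], x)
    expect_error(fuse_inputs(x, logits[1:8, , , , drop = FALSE]), "spatial")
  })
})

test_that("the full cascade composes the stage contracts", {
  withr::with_seed(54, {
    model <- build_icunet(base_width = 4L, dyconv_kernels = 2L, ema_bases = 4L,
                          seed = 7L)
    x <- array(rnorm(32^3 * 4), c(32, 32, 32, 4))
    fw <- icunet_forward(model, x)
    expect_identical(dim(fw$stage1_logits), c(32L, 32L, 32L, 4L))
    expect_identical(dim(fw$stage2_logits), c(32L, 32L, 32L, 4L))
    expect_identical(fw$internals$fused_channels, 8L)
    # repeated inference is bit-stable
    fw2 <- icunet_forward(model, x)
    expect_identical(fw$stage2_logits, fw2$stage2_logits)
  })
})

test_that("dynamic kernels multiply stage-2 parameters beyond stage 1", {
  model <- build_icunet(base_width = 4L, dyconv_kernels = 4L, ema_bases = 4L,
                        seed = 8L)
  p1 <- count_parameters(model$stage1)
  p2 <- count_parameters(model$stage2)
  expect_gt(p2, 2 * p1)
})

test_that("the composite loss couples stage-1 parameters end to end", {
  withr::with_seed(55, {
    model <- build_icunet(base_width = 4L, dyconv_kernels = 2L, ema_bases = 4L,
                          seed = 9L)
    x <- array(rnorm(16^3 * 4), c(16, 16, 16, 4))
    cls <- array(sample(0:3, 16^3, TRUE), c(16, 16, 16))
    oh <- onehot(cls)
    fw <- icunet_forward(model, x)
    gr <- icunet:::composite_loss_grads_(fw$stage1_logits, fw$stage2_logits, oh)
    bw <- icunet:::icunet_backward_(model, gr$dlogits1, gr$dlogits2, fw$cache)
    # stage-1 gradients exist and are nonzero even for the CE2/Dice2 terms
    gr2only <- icunet:::composite_loss_grads_(fw$stage1_logits, fw$stage2_logits,
                                              oh, loss_weights(0, 0.5, 1))
    bw2 <- icunet:::icunet_backward_(model, gr2only$dlogits1, gr2only$dlogits2,
                                     fw$cache)
    paths <- icunet:::enumerate_params_(model$stage1)
    gnorm <- sum(vapply(paths, function(p) {
      sum(icunet:::get_path_(bw2$grads1, icunet:::grad_path_(p))^2)
    }, numeric(1)))
    expect_gt(gnorm, 0)
    # gradient shapes line up with parameters everywhere
    for (p in paths) {
      w <- icunet:::get_path_(model$stage1, p)
      g <- icunet:::get_path_(bw$grads1, icunet:::grad_path_(p))
      expect_identical(length(w), length(g))
    }
  })
})

test_that("finite differences confirm the analytic gradient of the
           stage-1 cross-entropy path", {
  withr::with_seed(56, {
    model <- build_icunet(base_width = 2L, dyconv_kernels = 2L, ema_bases = 2L,
                          seed = 10L)
    x <- array(rnorm(16^3 * 4), c(16, 16, 16, 4))
    cls <- array(sample(0:3, 16^3, TRUE), c(16, 16, 16))
    oh <- onehot(cls)
    wts <- loss_weights(0.5, 0, 0)
    fw <- icunet_forward(model, x)
    gr <- icunet:::composite_loss_grads_(fw$stage1_logits, fw$stage2_logits, oh, wts)
    bw <- icunet:::icunet_backward_(model, gr$dlogits1, gr$dlogits2, fw$cache)
    lossfun <- function(m) {
      f <- icunet_forward(m, x)
      composite_loss(f$stage1_logits, f$stage2_logits, oh, wts)$total
    }
    paths <- icunet:::enumerate_params_(model$stage1)
    for (pi_ in c(1, 8, 15)) {
      p <- paths[[pi_]]
      w <- icunet:::get_path_(model$stage1, p)
      g <- icunet:::get_path_(bw$grads1, icunet:::grad_path_(p))
      i <- which.max(abs(g))
      eps <- 1e-5
      wp <- w; wp[i] <- wp[i] + eps
      wm <- w; wm[i] <- wm[i] - eps
      mp <- model; mp$stage1 <- icunet:::set_path_(mp$stage1, p, wp)
      mm <- model; mm$stage1 <- icunet:::set_path_(mm$stage1, p, wm)
      num <- (lossfun(mp) - lossfun(mm)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-3)
    }
  })
})
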