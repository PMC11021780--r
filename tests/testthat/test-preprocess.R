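test_that("z-score normalization matches the hand-computed population form", {
  # nonzero voxels [1,2,3]: mean 2, population sd sqrt(2/3)
  data <- array(0, c(4, 4, 4, 4))
  data[1:3, 1, 1, ] <- c(1, 2, 3)
  st <- new_modality_stack(data)
  out <- zscore_normalize(st)
  expect_equal(out$data[1:3, 1, 1, 1],
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_true(all(out$data[4, , , ] == 0))
})

test_that("normalized nonzero region has mean 0 and population sd 1", {
  case <- tiny_phantom(seed = 21L)
  out <- zscore_normalize(case$stack)
  raw_nz <- case$stack$data != 0
  for (m in 1:4) {
    v <- out$data[, , , m][raw_nz[, , , m]]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
    # voxels that were zero stay exactly zero
    expect_true(all(out$data[, , , m][!raw_nz[, , , m]] == 0))
  }
  # idempotence on an already-standardized stack
  again <- zscore_normalize(out)
  expect_equal(again$data, out$data, tolerance = 1e-6)
})

test_that("degenerate constant channels are zeroed with a warning", {
  data <- array(0, c(4, 4, 4, 4))
  data[, , , 1] <- 5           # constant nonzero: zero spread
  data[1:3, 1, 1, 2:4] <- rnorm(9)
  st <- new_modality_stack(data)
  expect_warning(out <- zscore_normalize(st), "degenerate")
  expect_true(all(out$data[, , , 1] == 0))
})

test_that("label remapping is the bijection 0,1,2,4 <-> 0,1,2,3", {
  lab <- random_label_array()
  cls <- remap_labels(lab)
  expect_identical(sort(unique(as.vector(cls))), c(0L, 1L, 2L, 3L))
  expect_identical(labels_from_classes(cls), lab)
  expect_true(all(cls[lab == 4L] == 3L))
  expect_error(remap_labels(array(3L, c(2, 2, 2))), "invalid values")
  expect_error(labels_from_classes(array(4L, c(2, 2, 2))), "class indices")
})

test_that("one-hot encoding sums to one and inverts through argmax", {
  cls <- array(sample(0:3, 6^3, replace = TRUE), c(6, 6, 6))
  oh <- onehot(cls)
  sums <- apply(oh, 1:3, sum)
  expect_true(all(sums == 1))
  expect_identical(icunet:::channel_argmax_(oh), cls)
  expect_identical(drop(onehot(array(2L, c(1, 1, 1)))), c(0, 0, 1, 0))
  expect_error(onehot(array(4L, c(2, 2, 2))), "out of range")
})

test_that("random crops honour the shape contract and pad small volumes", {
  case <- tiny_phantom(seed = 22L)
  smp <- random_crop(zscore_normalize(case$stack), case$label, 16L)
  expect_identical(dim(smp$inputs), c(16L, 16L, 16L, 4L))
  expect_identical(dim(smp$target_classes), c(16L, 16L, 16L))
  expect_identical(dim(smp$target_onehot), c(16L, 16L, 16L, 4L))
  # crop larger than the volume: zero-padding path
  big <- random_crop(zscore_normalize(case$stack), case$label, 64L)
  expect_identical(dim(big$inputs), c(64L, 64L, 64L, 4L))
  # padding and cropping introduce no label values beyond the originals
  expect_true(all(unique(as.vector(big$target_classes)) %in%
                    remap_labels(case$label$data)))
  # identical RNG state gives the identical window
  s1 <- withr::with_seed(5, random_crop(case$stack, case$label, 16L))
  s2 <- withr::with_seed(5, random_crop(case$stack, case$label, 16L))
  expect_identical(s1$inputs, s2$inputs)
})

test_that("tumor-biased crops hit tumor when forced", {
  case <- tiny_phantom(seed = 23L)
  for (i in 1:5) {
    smp <- random_crop(case$stack, case$label, 16L, tumor_bias = 1)
    expect_gt(sum(smp$target_classes > 0), 0)
  }
})

test_that("augmentation transforms are label-safe", {
  smp <- random_sample(8L)
  # forced flip applied twice is the identity
  f <- function(s) augment(s, flip = c(TRUE, FALSE, FALSE), k_rot = 0L,
                           intensity = c(1, 0))
  expect_identical(f(f(smp)), smp)
  # axial rotation preserves per-class voxel counts
  rot <- augment(smp, flip = c(FALSE, FALSE, FALSE), k_rot = 1L,
                 intensity = c(1, 0))
  expect_identical(table(rot$target_classes), table(smp$target_classes))
  # four quarter turns restore the original
  r4 <- smp
  for (i in 1:4) r4 <- augment(r4, flip = rep(FALSE, 3), k_rot = 1L,
                               intensity = c(1, 0))
  expect_identical(r4, smp)
  # intensity transform is the stated affine map, inputs only
  const <- smp
  const$inputs[] <- 1
  out <- augment(const, flip = rep(FALSE, 3), k_rot = 0L,
                 intensity = c(1.1, 0.05))
  expect_equal(unique(as.vector(out$inputs)), 1.15, tolerance = 1e-12)
  expect_identical(out$target_classes, smp$target_classes)
  # one-hot target stays consistent with the class target
  aug <- augment(smp)
  expect_identical(icunet:::channel_argmax_(aug$target_onehot),
                   aug$target_classes)
})

test_that("geometric augmentation commutes with region composition", {
  for (seed in 1:10) {
    case <- withr::with_seed(seed, tiny_phantom(seed = seed, grid = 16L))
    cls <- remap_labels(case$label$data)
    smp <- list(inputs = array(0, c(dim(cls), 4L)), target_classes = cls,
                target_onehot = onehot(cls))
    flip <- withr::with_seed(seed, runif(3) < 0.5)
    k <- withr::with_seed(seed + 1, sample(0:3, 1))
    aug <- augment(smp, flip = flip, k_rot = k, intensity = c(1, 0))
    lab_aug <- labels_from_classes(aug$target_classes)
    r1 <- compose_regions(lab_aug)
    r0 <- compose_regions(case$label$data)
    # transform each region mask with the same forced draws and compare
    tf <- function(m) {
      s <- list(inputs = array(0, c(dim(m), 4L)),
                target_classes = array(as.integer(m), dim(m)),
                target_onehot = onehot(array(as.integer(m), dim(m)), 2L))
      augment(s, flip = flip, k_rot = k, intensity = c(1, 0))$target_classes == 1L
    }
    expect_identical(r1$wt, tf(r0$wt))
    expect_identical(r1$tc, tf(r0$tc))
    expect_identical(r1$et, tf(r0$et))
  }
})
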