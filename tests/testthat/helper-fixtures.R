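# Shared fixtures, all generated in code.

tiny_phantom <- function(seed = 1L, noise_sd = 10, grid = 32L) {
  generate_phantom(phantom_spec(grid_shape = rep(grid, 3L),
                                radii = c(6, 4, 2), noise_sd = noise_sd,
                                seed = seed))
}

# A random but valid label volume over {0,1,2,4}
random_label_array <- function(shape = c(8, 8, 8)) {
  array(sample(c(0L, 1L, 2L, 4L), prod(shape), replace = TRUE,
               prob = c(0.7, 0.1, 0.1, 0.1)), shape)
}

# A small random training sample with consistent targets
random_sample <- function(s = 8L) {
  cls <- array(sample(0:3, s^3, replace = TRUE), rep(s, 3))
  list(inputs = array(rnorm(s^3 * 4), c(rep(s, 3), 4L)),
       target_classes = cls,
       target_onehot = onehot(cls))
}

# Brute-force M step: per-basis weighted mean with the same epsilon and
# unit-norm maintenance, written as an explicit loop over voxels.
m_step_bruteforce <- function(X, A, epsilon = 1e-6) {
  D <- nrow(X); N <- ncol(X); K <- ncol(A)
  mu <- matrix(0, D, K)
  for (k in seq_len(K)) {
    num <- numeric(D)
    den <- 0
    for (n in seq_len(N)) {
      num <- num + A[n, k] * X[, n]
      den <- den + A[n, k]
    }
    mu[, k] <- num / (den + epsilon)
    nrm <- sqrt(sum(mu[, k]^2))
    if (nrm > 1e-12) mu[, k] <- mu[, k] / nrm
  }
  mu
}

# Brute-force HD95: exhaustive pairwise distances between surface voxels,
# pooled over both directions, same percentile definition.
hd95_bruteforce <- function(pred, gt, spacing = c(1, 1, 1)) {
  surf <- function(mask) {
    d <- dim(mask)
    idx <- which(mask, arr.ind = TRUE)
    keep <- apply(idx, 1, function(v) {
      for (a in 1:3) for (s in c(-1L, 1L)) {
        nb <- v
        nb[a] <- nb[a] + s
        if (nb[a] < 1 || nb[a] > d[a]) return(TRUE)
        if (!mask[nb[1], nb[2], nb[3]]) return(TRUE)
      }
      FALSE
    })
    idx[keep, , drop = FALSE]
  }
  sp <- surf(pred)
  sg <- surf(gt)
  scale_rows <- function(m) sweep(m, 2, spacing, "*")
  a <- scale_rows(sp)
  b <- scale_rows(sg)
  dmat <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  dmat[dmat < 0] <- 0
  dmat <- sqrt(dmat)
  dists <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  as.numeric(quantile(dists, 0.95, names = FALSE))
}
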