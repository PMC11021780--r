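#' Expectation-maximization attention: configuration
#'
#' The EM-attention module summarizes a feature map by a compact set of K
#' basis vectors. The E step computes responsibilities (non-local
#' attention) of every voxel for every basis; the M step re-estimates each
#' basis as the responsibility-weighted mean of the voxel features. After
#' `n_iterations` alternations the feature map is reconstructed as a
#' low-rank combination of the bases, which aggregates long-range context
#' at a cost linear in the number of voxels.
#'
#' @param channels number of feature channels D entering the module.
#' @param n_bases number of bases K (default 64).
#' @param n_iterations EM alternations t (default 3).
#' @param basis_momentum momentum of the persistent global basis update
#'   during training (default 0.9).
#' @param epsilon stabilizer for the M-step denominator.
#' @return an `ema_config` list.
#' @export
ema_config <- function(channels, n_bases = 64L, n_iterations = 3L,
                       basis_momentum = 0.9, epsilon = 1e-6) {
  stopifnot(n_bases >= 1, n_iterations >= 1,
            basis_momentum >= 0, basis_momentum <= 1, epsilon > 0)
  structure(list(channels = as.integer(channels), n_bases = as.integer(n_bases),
                 n_iterations = as.integer(n_iterations),
                 basis_momentum = basis_momentum, epsilon = epsilon),
            class = "ema_config")
}

normalize_columns_ <- function(mu) {
  nrm <- sqrt(colSums(mu^2))
  nrm[nrm < 1e-12] <- 1
  sweep(mu, 2, nrm, "/")
}

softmax_rows_ <- function(z) {
  z <- z - row_max(z)
  e <- exp(z)
  e / rowSums(e)
}

#' EMA E step: voxel-to-basis responsibilities
#'
#' Computes the attention matrix `A` with
#' \eqn{A_{nk} = \mathrm{softmax}_k \langle X_n, \mu_k \rangle}: a softmax
#' over bases of the feature-basis inner products (unit scaling).
#'
#' @param X D x N feature matrix (columns are voxels).
#' @param mu D x K basis matrix (columns are bases).
#' @return N x K attention matrix with rows summing to one.
#' @export
e_step <- function(X, mu) {
  if (!all(is.finite(X)) || !all(is.finite(mu))) stopf_("non-finite inputs to e_step")
  softmax_rows_(crossprod(X, mu))
}

#' EMA M step: responsibility-weighted basis re-estimation
#'
#' \eqn{\mu_k = \sum_n A_{nk} X_n / (\sum_n A_{nk} + \epsilon)}, after
#' which columns are renormalized to unit Euclidean length (basis
#' maintenance). A basis whose total responsibility mass is (numerically)
#' zero falls back to its previous value when one is supplied.
#'
#' @param X D x N feature matrix.
#' @param A N x K attention matrix.
#' @param epsilon denominator stabilizer.
#' @param prev optional D x K previous basis matrix used as fallback for
#'   empty bases.
#' @return D x K basis matrix with unit-norm columns.
#' @export
m_step <- function(X, A, epsilon = 1e-6, prev = NULL) {
  mass <- colSums(A)
  mu <- sweep(X %*% A, 2, mass + epsilon, "/")
  if (!is.null(prev)) {
    empty <- mass < 1e-12
    if (any(empty)) mu[, empty] <- prev[, empty]
  }
  normalize_columns_(mu)
}

#' Run t alternations of the E and M steps
#'
#' @param X D x N feature matrix.
#' @param mu0 D x K initial bases.
#' @param t number of alternations (>= 1).
#' @param epsilon M-step stabilizer.
#' @return list with `mu` (converged bases) and `A` (last responsibilities).
#' @export
em_iterate <- function(X, mu0, t = 3L, epsilon = 1e-6) {
  stopifnot(t >= 1)
  mu <- mu0
  A <- NULL
  for (i in seq_len(t)) {
    A <- e_step(X, mu)
    mu <- m_step(X, A, epsilon, prev = mu)
  }
  list(mu = mu, A = A)
}

#' Low-rank reconstruction from bases and attention
#'
#' \eqn{\tilde X = \mu A^\top}; every column lies in the span of the K
#' bases, so the reconstruction has rank at most K.
#'
#' @param mu D x K basis matrix.
#' @param A N x K attention matrix.
#' @return D x N reconstructed feature matrix.
#' @export
reconstruct <- function(mu, A) {
  mu %*% t(A)
}

#' Momentum update of the persistent global bases
#'
#' `new = momentum * state + (1 - momentum) * converged`, followed by
#' column renormalization to unit length. During training the per-batch
#' converged bases are folded into this running state; at inference the
#' global state seeds the EM iteration.
#'
#' @param state D x K current global bases.
#' @param converged D x K converged bases from the current batch.
#' @param momentum mixing coefficient in [0, 1].
#' @return updated D x K basis matrix with unit-norm columns.
#' @export
update_global_bases <- function(state, converged, momentum = 0.9) {
  normalize_columns_(momentum * state + (1 - momentum) * converged)
}

# --- network layer -----------------------------------------------------------

# Parameters: win/bin and wout/bout are the pointwise (1x1x1) channel
# adapters; mu is the persistent global basis buffer (not Adam-updated).
init_ema_layer_ <- function(channels, n_bases) {
  list(win = matrix(rnorm(channels * channels, sd = sqrt(2 / channels)),
                    channels, channels),
       bin = numeric(channels),
       wout = matrix(rnorm(channels * channels, sd = sqrt(2 / channels)),
                     channels, channels),
       bout = numeric(channels),
       mu = normalize_columns_(matrix(rnorm(channels * n_bases), channels, n_bases)))
}

#' EM-attention forward pass over a feature tensor
#'
#' Pipeline: pointwise convolution in, flatten, `n_iterations` EM
#' alternations seeded by the global bases, low-rank reconstruction,
#' pointwise convolution out, residual addition of the input. The EM
#' iterations themselves are treated as a fixed (non-differentiated)
#' inner solver; gradients flow through the final responsibilities and
#' the two pointwise convolutions (see the package vignette).
#'
#' @param x feature array, dim (D, H, W, C).
#' @param layer an EMA layer parameter list (see [ema_config()] for the
#'   module hyperparameters); created internally by the network builder.
#' @param config an `ema_config`.
#' @param training logical; when `TRUE` the returned layer carries
#'   momentum-updated global bases.
#' @return list with `out` (same shape as `x`), `layer` (possibly updated
#'   state) and `cache` (internal, for the backward pass).
#' @export
ema_forward <- function(x, layer, config, training = FALSE) {
  shp <- dim(x)
  C <- shp[4]
  if (C != config$channels) {
    stopf_("EMA channel mismatch: input has %d channels, config %d", C, config$channels)
  }
  N <- prod(shp[1:3])
  Xm <- matrix(x, ncol = C)                       # N x C voxel-feature view
  Z <- Xm %*% layer$win + matrix(layer$bin, N, C, byrow = TRUE)  # N x C
  fit <- em_iterate(t(Z), layer$mu, config$n_iterations, config$epsilon)
  Xt <- fit$A %*% t(fit$mu)                       # N x C reconstruction
  Y <- Xt %*% layer$wout + matrix(layer$bout, N, C, byrow = TRUE)
  out <- array(Xm + Y, shp)
  if (training) {
    layer$mu <- update_global_bases(layer$mu, fit$mu, config$basis_momentum)
  }
  list(out = out,
       layer = layer,
       cache = list(Xm = Xm, Z = Z, A = fit$A, mu = fit$mu, Xt = Xt, shp = shp))
}

# Backward: residual + pointwise-out are exact; through the EM inner loop we
# differentiate the final E step treating the converged bases as constants.
ema_backward_ <- function(dout, layer, cache) {
  shp <- cache$shp
  C <- shp[4]
  G <- matrix(dout, ncol = C)                     # N x C
  dwout <- crossprod(cache$Xt, G)
  dbout <- colSums(G)
  dXt <- G %*% t(layer$wout)                      # N x C
  dA <- dXt %*% cache$mu                          # N x K
  A <- cache$A
  dlogits <- A * (dA - rowSums(dA * A))           # softmax rows backward
  dZ <- dlogits %*% t(cache$mu)                   # N x C
  dwin <- crossprod(cache$Xm, dZ)
  dbin <- colSums(dZ)
  dXm <- G + dZ %*% t(layer$win)                  # residual + conv-in path
  list(dx = array(dXm, shp),
       grads = list(win = dwin, bin = dbin, wout = dwout, bout = dbout))
}
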