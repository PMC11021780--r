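#' Dynamic 3D convolution: configuration
#'
#' A dynamic convolution keeps K parallel kernels per layer and, for each
#' input sample, aggregates them with softmax attention weights computed
#' from globally pooled features (a squeeze-and-excitation style head:
#' global average pool, a bottleneck affine layer with rectification, an
#' affine layer to K units, softmax with temperature). Because
#' convolution is linear in the kernel, convolving with the aggregated
#' kernel equals the attention-weighted sum of the K individual
#' convolutions; the implementation aggregates first so each sample costs
#' one convolution.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel_size odd cubic kernel side (default 3).
#' @param n_kernels number of parallel kernels K (default 4).
#' @param reduction bottleneck reduction r of the attention head
#'   (default 4).
#' @param temperature softmax temperature for the attention weights
#'   (default 1; annealed from a high value early in training).
#' @return a `dyconv_config` list.
#' @export
dyconv_config <- function(in_channels, out_channels, kernel_size = 3L,
                          n_kernels = 4L, reduction = 4L, temperature = 1) {
  stopifnot(kernel_size %% 2 == 1, n_kernels >= 1, reduction >= 1, temperature > 0)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 n_kernels = as.integer(n_kernels),
                 reduction = as.integer(reduction),
                 temperature = temperature),
            class = "dyconv_config")
}

# Kernel bank: weights as a (k^3 * in) x out x K array matching the
# vol2col patch layout; attention head: two affine maps.
init_dyconv_layer_ <- function(config) {
  cin <- config$in_channels; cout <- config$out_channels
  k3 <- config$kernel_size^3
  K <- config$n_kernels
  hid <- max(1L, cin %/% config$reduction)
  list(W = array(rnorm(k3 * cin * cout * K, sd = sqrt(2 / (k3 * cin))),
                 c(k3 * cin, cout, K)),
       b = matrix(0, cout, K),
       hW1 = matrix(rnorm(cin * hid, sd = sqrt(2 / cin)), cin, hid),
       hb1 = numeric(hid),
       hW2 = matrix(rnorm(hid * K, sd = 1e-2), hid, K),
       hb2 = numeric(K))
}

softmax_vec_ <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Per-sample attention weights over the kernel bank
#'
#' @param x input feature array (D, H, W, in_channels).
#' @param layer dynamic-convolution parameter list (kernel bank plus
#'   attention head), as built by the network constructor.
#' @param config a `dyconv_config`.
#' @return numeric(K) nonnegative weights summing to one.
#' @export
kernel_attention <- function(x, layer, config) {
  shp <- dim(x)
  if (shp[4] != config$in_channels) {
    stopf_("kernel_attention channel mismatch: input %d, config %d",
           shp[4], config$in_channels)
  }
  s <- colMeans(matrix(x, ncol = shp[4]))          # global average pool
  h <- pmax(drop(s %*% layer$hW1) + layer$hb1, 0)  # bottleneck + ReLU
  logits <- drop(h %*% layer$hW2) + layer$hb2
  softmax_vec_(logits / config$temperature)
}

#' Aggregate the kernel bank under attention weights
#'
#' \eqn{\tilde W = \sum_k \pi_k W_k}, \eqn{\tilde b = \sum_k \pi_k b_k}.
#'
#' @param bank list with `W` ((k^3 in) x out x K array) and `b`
#'   (out x K matrix), or a full dynamic-convolution layer.
#' @param pi numeric(K) attention weights.
#' @return list with the aggregated `W` matrix and `b` vector.
#' @export
aggregate_kernels <- function(bank, pi) {
  K <- dim(bank$W)[3]
  stopifnot(length(pi) == K)
  W <- matrix(0, dim(bank$W)[1], dim(bank$W)[2])
  b <- numeric(dim(bank$W)[2])
  for (k in seq_len(K)) {
    W <- W + pi[k] * bank$W[, , k]
    b <- b + pi[k] * bank$b[, k]
  }
  list(W = W, b = b)
}

#' Dynamic convolution forward pass
#'
#' For each sample independently: attention weights from
#' [kernel_attention()], kernel aggregation, then a stride-1 3D
#' convolution with `(kernel_size - 1)/2` zero padding so the spatial
#' shape is preserved.
#'
#' @param x one sample (D, H, W, in) array or a list of such arrays.
#' @param layer dynamic-convolution parameter list.
#' @param config a `dyconv_config`.
#' @return output array (D, H, W, out), or a list of them.
#' @export
dyconv_forward <- function(x, layer, config) {
  if (is.list(x)) return(lapply(x, dyconv_forward, layer = layer, config = config))
  dyconv_fwd_(x, layer, config)$out
}

dyconv_fwd_ <- function(x, layer, config) {
  shp <- dim(x)
  pi <- kernel_attention(x, layer, config)
  agg <- aggregate_kernels(layer, pi)
  y <- conv3d_fwd(x, shp[1], shp[2], shp[3], shp[4], agg$W, agg$b,
                  config$kernel_size)
  dim(y) <- c(shp[1:3], config$out_channels)
  list(out = y,
       cache = list(x = x, pi = pi, Wagg = agg$W, shp = shp))
}

dyconv_bwd_ <- function(dout, layer, config, cache) {
  shp <- cache$shp
  cout <- config$out_channels
  N <- prod(shp[1:3])
  r <- conv3d_bwd(cache$x, dout, shp[1], shp[2], shp[3], shp[4], cache$Wagg,
                  config$kernel_size)
  dWagg <- r$dW
  dbagg <- r$db
  K <- config$n_kernels
  dW <- array(0, dim(layer$W))
  db <- matrix(0, cout, K)
  dpi <- numeric(K)
  for (k in seq_len(K)) {
    dW[, , k] <- cache$pi[k] * dWagg
    db[, k] <- cache$pi[k] * dbagg
    dpi[k] <- sum(dWagg * layer$W[, , k]) + sum(dbagg * layer$b[, k])
  }
  # back through softmax(logits / tau) and the attention head
  pi <- cache$pi
  dlogits <- (pi * (dpi - sum(dpi * pi))) / config$temperature
  s <- colMeans(matrix(cache$x, ncol = shp[4]))
  h_pre <- drop(s %*% layer$hW1) + layer$hb1
  h <- pmax(h_pre, 0)
  dhW2 <- outer(h, dlogits)
  dhb2 <- dlogits
  dh <- drop(layer$hW2 %*% dlogits) * (h_pre > 0)
  dhW1 <- outer(s, dh)
  dhb1 <- dh
  ds <- drop(layer$hW1 %*% dh)
  # input gradient: convolution path + pooled-attention path
  dx <- r$dx
  dim(dx) <- shp
  dx <- dx + rep(ds / N, each = N)
  list(dx = dx,
       grads = list(W = dW, b = db, hW1 = dhW1, hb1 = dhb1,
                    hW2 = dhW2, hb2 = dhb2))
}
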