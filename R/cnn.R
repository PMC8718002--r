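# Multi-input convolutional network for echo-spectrogram classification.
# Architecture: k parallel spectrogram inputs -> shared "preprocessing"
# branch (conv 16 channels, 3x3 stride 1 + max pool 3x3 stride 2, identical
# weights for every input) -> channel concatenation -> conv 32 channels +
# max pool -> three dense layers -> softmax over species.
# Conv/pool forward and backward run in compiled code (src/kernels.cpp);
# dense layers, softmax, loss and the Adam optimiser are plain R.

#' Network specification for the echo classifier
#'
#' @param k number of echo spectrograms presented simultaneously.
#' @param input_shape spectrogram shape `c(n_freq_bins, n_frames)`.
#' @param n_classes number of species.
#' @param conv_channels channels of the shared branch conv and the trunk
#'   conv.
#' @param dense widths of the first two dense layers (the third is the
#'   `n_classes`-way output).
#' @param kernel,pool,pool_stride conv kernel size, pooling kernel size and
#'   pooling stride.
#' @return object of class `echonet_spec`.
#' @export
echonet_spec <- function(k, input_shape, n_classes = 12L,
                         conv_channels = c(16L, 32L),
                         dense = c(256L, 128L),
                         kernel = 3L, pool = 3L, pool_stride = 2L) {
  stopifnot(k >= 1, length(input_shape) == 2, n_classes >= 2)
  out1 <- .conv_pool_shape(input_shape, kernel, pool, pool_stride)
  if (any(out1 < 1)) stopf("input shape %s too small for the branch",
                           paste(input_shape, collapse = "x"))
  out2 <- .conv_pool_shape(out1, kernel, pool, pool_stride)
  if (any(out2 < 1)) stopf("input shape too small for the trunk")
  structure(list(k = as.integer(k), input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 conv_channels = as.integer(conv_channels),
                 dense = as.integer(dense), kernel = as.integer(kernel),
                 pool = as.integer(pool),
                 pool_stride = as.integer(pool_stride),
                 branch_out = out1, trunk_out = out2,
                 flat_dim = prod(out2) * conv_channels[2]),
            class = "echonet_spec")
}

.conv_pool_shape <- function(hw, kernel, pool, stride) {
  conv <- hw - kernel + 1L
  as.integer((conv - pool) %/% stride + 1L)
}

#' Initialise network parameters
#'
#' He-normal initialisation, seeded. The shared-branch parameter count does
#' not depend on `k` (the weights are shared across inputs).
#'
#' @param spec an [echonet_spec()].
#' @param seed integer seed.
#' @return list of parameter arrays (class `echonet_params`).
#' @export
build_echonet <- function(spec, seed = 1L) {
  kh <- spec$kernel
  c1 <- spec$conv_channels[1]; c2 <- spec$conv_channels[2]
  he <- function(dims, fan_in) array(rnorm(prod(dims), sd = sqrt(2 / fan_in)),
                                     dim = dims)
  with_seed(seed, {
    params <- list(
      w1 = he(c(kh, kh, 1L, c1), kh * kh),
      b1 = numeric(c1),
      w2 = he(c(kh, kh, c1 * spec$k, c2), kh * kh * c1 * spec$k),
      b2 = numeric(c2),
      w3 = matrix(rnorm(spec$dense[1] * spec$flat_dim,
                        sd = sqrt(2 / spec$flat_dim)),
                  spec$dense[1], spec$flat_dim),
      b3 = numeric(spec$dense[1]),
      w4 = matrix(rnorm(spec$dense[2] * spec$dense[1],
                        sd = sqrt(2 / spec$dense[1])),
                  spec$dense[2], spec$dense[1]),
      b4 = numeric(spec$dense[2]),
      w5 = matrix(rnorm(spec$n_classes * spec$dense[2],
                        sd = sqrt(2 / spec$dense[2])),
                  spec$n_classes, spec$dense[2]),
      b5 = numeric(spec$n_classes))
    structure(params, class = "echonet_params")
  })
}

# forward pass; x: array (H, W, k, B). Returns probs and (optionally) the
# cache needed for the backward pass.
.echonet_forward <- function(params, spec, x, keep_cache = FALSE) {
  d <- dim(x); B <- d[4]
  kB <- spec$k * B
  x1 <- x; dim(x1) <- c(d[1], d[2], 1L, kB)
  z1 <- .conv2d_fwd(x1, params$w1, params$b1)
  a1 <- pmax(z1, 0); dim(a1) <- dim(z1)
  p1 <- .maxpool_fwd(a1, spec$pool, spec$pool_stride)
  h1 <- p1$y
  d1 <- dim(h1)
  x2 <- h1; dim(x2) <- c(d1[1], d1[2], d1[3] * spec$k, B)  # concat branches
  z2 <- .conv2d_fwd(x2, params$w2, params$b2)
  a2 <- pmax(z2, 0); dim(a2) <- dim(z2)
  p2 <- .maxpool_fwd(a2, spec$pool, spec$pool_stride)
  h2 <- p2$y
  flat <- matrix(h2, nrow = spec$flat_dim, ncol = B)
  z3 <- params$w3 %*% flat + params$b3
  a3 <- pmax(z3, 0)
  z4 <- params$w4 %*% a3 + params$b4
  a4 <- pmax(z4, 0)
  logits <- params$w5 %*% a4 + params$b5
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  probs <- sweep(e, 2, colSums(e), `/`)
  cache <- if (keep_cache)
    list(x1 = x1, z1 = z1, a1 = a1, p1 = p1, x2 = x2, z2 = z2, a2 = a2,
         p2 = p2, flat = flat, a3 = a3, a4 = a4, z3 = z3, z4 = z4) else NULL
  list(probs = probs, cache = cache)
}

# backward pass; y: integer class index per sample (1-based).
.echonet_backward <- function(params, spec, fwd, y) {
  probs <- fwd$probs; cache <- fwd$cache
  B <- ncol(probs)
  dlogits <- probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B
  g <- list()
  g$w5 <- dlogits %*% t(cache$a4); g$b5 <- rowSums(dlogits)
  da4 <- t(params$w5) %*% dlogits
  dz4 <- da4 * (cache$z4 > 0)
  g$w4 <- dz4 %*% t(cache$a3); g$b4 <- rowSums(dz4)
  da3 <- t(params$w4) %*% dz4
  dz3 <- da3 * (cache$z3 > 0)
  g$w3 <- dz3 %*% t(cache$flat); g$b3 <- rowSums(dz3)
  dflat <- t(params$w3) %*% dz3
  dh2 <- array(dflat, dim = dim(cache$p2$y))
  da2 <- .maxpool_bwd(dh2, cache$p2$idx, dim(cache$a2))
  dz2 <- da2 * (cache$z2 > 0); dim(dz2) <- dim(da2)
  bw2 <- .conv2d_bwd(cache$x2, params$w2, dz2)
  g$w2 <- bw2$dw; g$b2 <- bw2$db
  dx2 <- bw2$dx
  dh1 <- dx2
  dim(dh1) <- dim(cache$p1$y)
  da1 <- .maxpool_bwd(dh1, cache$p1$idx, dim(cache$a1))
  dz1 <- da1 * (cache$z1 > 0); dim(dz1) <- dim(da1)
  bw1 <- .conv2d_bwd(cache$x1, params$w1, dz1)
  g$w1 <- bw1$dw; g$b1 <- bw1$db
  g
}

.cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(y, seq_len(ncol(probs)))], 1e-12)))
}

# one Adam step; state holds m/v per parameter plus the step counter
.adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.adam_init <- function(params) {
  zero <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zero, v = zero, t = 0)
}
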