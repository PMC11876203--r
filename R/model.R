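#' Architecture configuration
#'
#' Fixes a reference architecture honoring the method's structural
#' constraints: Encoder 1 halves the input twice (latent map `input_size/4`
#' per side, `latent_channels` deep) and applies residual blocks; Encoder 2
#' compresses the latent map to a `svdd_latent_dim` vector with no output
#' activation and no normalization layers (both a deliberate guard against
#' hypersphere collapse); Decoder 2 and Decoder 1 mirror them with transposed
#' convolutions; the codebook holds `codebook_size` embeddings of dimension
#' `latent_channels`.
#'
#' @param input_size square input side in pixels (divisible by 4).
#' @param latent_channels D, channels of the latent-variable map (reference
#'   value 128).
#' @param codebook_size K, number of embedding vectors (reference value 128;
#'   >= 2).
#' @param svdd_latent_dim length of the Encoder-2 latent vector `z(x)`; must
#'   be well below `(input_size/4)^2 * latent_channels` so the inner
#'   bottleneck discards the redundancy that would let anomalies be
#'   reconstructed. Default 1024 for 256-px inputs, 256 otherwise.
#' @param enc1_width,enc2_width channel widths of the outer/inner conv stages.
#' @param n_res residual blocks in Encoder 1 (mirrored in Decoder 1).
#' @param seed seed for weight initialization.
#' @return an object of class `arch_config`.
#' @export
arch_config <- function(input_size = 64L, latent_channels = 128L,
                        codebook_size = 128L, svdd_latent_dim = NULL,
                        enc1_width = 64L, enc2_width = 64L, n_res = 2L,
                        seed = 1L) {
  if (input_size %% 4 != 0) stop("input_size must be divisible by 4",
                                 call. = FALSE)
  if (codebook_size < 2) stop("codebook_size must be >= 2", call. = FALSE)
  H <- input_size %/% 4L
  if (is.null(svdd_latent_dim))
    svdd_latent_dim <- if (input_size >= 256) 1024L else 256L
  if (svdd_latent_dim >= H * H * latent_channels)
    stop("svdd_latent_dim must be smaller than the latent-variable map",
         call. = FALSE)
  if (input_size %% 16 != 0)
    stop("input_size must be divisible by 16 (two further halvings in Encoder 2)",
         call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 latent_channels = as.integer(latent_channels),
                 codebook_size = as.integer(codebook_size),
                 svdd_latent_dim = as.integer(svdd_latent_dim),
                 enc1_width = as.integer(enc1_width),
                 enc2_width = as.integer(enc2_width),
                 n_res = as.integer(n_res), seed = as.integer(seed)),
            class = "arch_config")
}

model_specs <- function(arch) {
  D <- arch$latent_channels; c1 <- arch$enc1_width; c2 <- arch$enc2_width
  s16 <- arch$input_size %/% 16L
  flat <- s16 * s16 * c2
  list(
    enc1 = c(list(nn_conv(1L, c1), nn_conv(c1, D)),
             rep(list(nn_res(D)), arch$n_res)),
    enc2 = list(nn_conv(D, c2), nn_conv(c2, c2), nn_flatten(),
                nn_linear(flat, arch$svdd_latent_dim, act = "none")),
    dec2 = list(nn_linear(arch$svdd_latent_dim, flat, act = "relu"),
                nn_unflatten(s16, s16, c2), nn_deconv(c2, c2),
                nn_deconv(c2, D, act = "none")),
    dec1 = c(rep(list(nn_res(D)), arch$n_res),
             list(nn_deconv(D, c1), nn_deconv(c1, 1L, act = "sigmoid"))))
}

#' Initialize a VQ-VAE-with-SVDD model
#'
#' Weights are He-initialized and the codebook is uniform in
#' `[-1/K, 1/K]`, all deterministically from `arch$seed`.
#'
#' @param arch an [arch_config()].
#' @return an object of class `vq_svdd_model` (parameters, specs, codebook).
#' @export
vq_svdd_model <- function(arch) {
  specs <- model_specs(arch)
  params <- with_seed(arch$seed, {
    p <- lapply(specs, seq_init)
    K <- arch$codebook_size
    p$codebook <- matrix(runif(K * arch$latent_channels, -1 / K, 1 / K),
                         K, arch$latent_channels)
    p
  })
  structure(list(arch = arch, specs = specs, params = params, sphere = NULL),
            class = "vq_svdd_model")
}

#' Nearest-neighbour codebook quantization
#'
#' Replaces each channel-direction vector of the latent map with its closest
#' codebook embedding (Euclidean distance, ties broken toward the smallest
#' index). The operation is used with a straight-through backward contract
#' during training: gradients w.r.t. the quantized map pass to the
#' pre-quantization map unchanged.
#'
#' @param z_d latent map, array `(H, W, D, N)` (or `(H, W, D)`).
#' @param codebook `K x D` matrix of embeddings.
#' @return list with `z_q` (same shape as `z_d`) and `indices`
#'   (`H x W x N` integer array, values in `1..K`).
#' @export
quantize <- function(z_d, codebook) {
  d <- dim(z_d)
  if (length(d) == 3L) { z_d <- array(z_d, c(d, 1L)); d <- dim(z_d) }
  D <- d[3]
  if (D != ncol(codebook)) stop_dim("latent depth does not match codebook")
  # rows = latent vectors at each (pixel, image)
  Z <- matrix(aperm(z_d, c(1, 2, 4, 3)), ncol = D)
  # squared distances; argmin with "first" realizes the smallest-index tie rule
  d2 <- outer(rowSums(Z^2), rowSums(codebook^2), "+") - 2 * Z %*% t(codebook)
  idx <- max.col(-d2, ties.method = "first")
  zq <- aperm(array(codebook[idx, ], c(d[1], d[2], d[4], D)), c(1, 2, 4, 3))
  list(z_q = zq, indices = array(idx, c(d[1], d[2], d[4])))
}

as_batch <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) array(x, c(dim(x)[1:2], 1L, dim(x)[3]))
  else x
}

#' Forward pass through VQ-VAE with SVDD
#'
#' In `bypass` mode (Step-1 training of the outer autoencoder) the latent map
#' skips Encoder 2 / Decoder 2 entirely: `z_d(x)` is identical to `z_e(x)`
#' and `z` is absent.
#'
#' @param model a `vq_svdd_model`.
#' @param x a single slice matrix, or an `(H, W, 1, N)` batch array.
#' @param bypass logical; skip the inner encoder/decoder.
#' @param keep_cache internal; retain layer caches for backprop.
#' @return a latent bundle: list with `z_e`, `z` (`svdd_latent_dim x N` or
#'   `NULL`), `z_d`, `z_q`, `indices`, `xhat` (and caches when requested).
#' @export
vq_forward <- function(model, x, bypass = FALSE, keep_cache = FALSE) {
  x <- as_batch(x)
  if (dim(x)[1] != model$arch$input_size || dim(x)[2] != model$arch$input_size)
    stop_dim("input size does not match the architecture")
  sp <- model$specs; pa <- model$params
  f1 <- seq_fwd(sp$enc1, pa$enc1, x, keep_cache)
  z_e <- f1$out
  if (bypass) {
    z <- NULL; z_d <- z_e; f2 <- NULL; f3 <- NULL
  } else {
    f2 <- seq_fwd(sp$enc2, pa$enc2, z_e, keep_cache)
    z <- f2$out
    f3 <- seq_fwd(sp$dec2, pa$dec2, z, keep_cache)
    z_d <- f3$out
  }
  q <- quantize(z_d, pa$codebook)
  f4 <- seq_fwd(sp$dec1, pa$dec1, q$z_q, keep_cache)
  bundle <- list(z_e = z_e, z = z, z_d = z_d, z_q = q$z_q,
                 indices = q$indices, xhat = f4$out, bypass = bypass)
  if (keep_cache) bundle$caches <- list(enc1 = f1$caches,
                                        enc2 = if (!bypass) f2$caches,
                                        dec2 = if (!bypass) f3$caches,
                                        dec1 = f4$caches)
  bundle
}

# ---- plain convolutional VAE baseline -------------------------------------

vae_specs <- function(arch) {
  c1 <- arch$enc1_width; c2 <- arch$enc2_width
  s16 <- arch$input_size %/% 16L
  flat <- s16 * s16 * c2
  list(enc = list(nn_conv(1L, c1), nn_conv(c1, c2), nn_conv(c2, c2),
                  nn_conv(c2, c2), nn_flatten()),
       mu = list(nn_linear(flat, arch$svdd_latent_dim)),
       logvar = list(nn_linear(flat, arch$svdd_latent_dim)),
       dec = list(nn_linear(arch$svdd_latent_dim, flat, act = "relu"),
                  nn_unflatten(s16, s16, c2), nn_deconv(c2, c2),
                  nn_deconv(c2, c2), nn_deconv(c2, c1),
                  nn_deconv(c1, 1L, act = "sigmoid")))
}

#' Initialize the plain convolutional VAE baseline
#'
#' The comparison model: a conv encoder to a diagonal-Gaussian latent
#' (`mu`, `logvar`), reparameterized sampling during training, and a mirrored
#' deconv decoder. Its loss shares the proposed model's reconstruction terms
#' (summed squared error plus `1 - MS-SSIM`) with a KL divergence to the
#' standard normal prior in place of quantization and hypersphere terms.
#'
#' @param arch an [arch_config()]; the VAE latent uses `svdd_latent_dim`.
#' @return an object of class `vae_model`.
#' @export
vae_model <- function(arch) {
  specs <- vae_specs(arch)
  params <- with_seed(arch$seed + 1L, lapply(specs, seq_init))
  structure(list(arch = arch, specs = specs, params = params),
            class = "vae_model")
}

#' Forward pass through the VAE baseline
#'
#' @param model a `vae_model`.
#' @param x slice matrix or `(H, W, 1, N)` batch.
#' @param sample logical: reparameterized sampling (training) or the
#'   deterministic posterior mean (evaluation, the default).
#' @param keep_cache internal; retain caches for backprop.
#' @return list with `xhat`, `mu`, `logvar` (and `z`, `eps`, caches).
#' @export
vae_forward <- function(model, x, sample = FALSE, keep_cache = FALSE) {
  x <- as_batch(x)
  sp <- model$specs; pa <- model$params
  fe <- seq_fwd(sp$enc, pa$enc, x, keep_cache)
  fmu <- seq_fwd(sp$mu, pa$mu, fe$out, keep_cache)
  flv <- seq_fwd(sp$logvar, pa$logvar, fe$out, keep_cache)
  mu <- fmu$out; logvar <- flv$out
  eps <- if (sample) matrix(rnorm(length(mu)), nrow(mu), ncol(mu)) else NULL
  z <- if (sample) mu + exp(logvar / 2) * eps else mu
  fd <- seq_fwd(sp$dec, pa$dec, z, keep_cache)
  out <- list(xhat = fd$out, mu = mu, logvar = logvar, z = z, eps = eps)
  if (keep_cache) out$caches <- list(enc = fe$caches, mu = fmu$caches,
                                     logvar = flv$caches, dec = fd$caches)
  out
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' \eqn{KL = -\tfrac12 \sum (1 + \log\sigma^2 - \mu^2 - \sigma^2)}, summed
#' over latent dimensions and averaged over the batch.
#'
#' @param mu,logvar `dim x N` matrices.
#' @return scalar KL value.
#' @export
vae_kl <- function(mu, logvar) {
  mean(colSums(-0.5 * (1 + logvar - mu^2 - exp(logvar))))
}
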