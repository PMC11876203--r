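# Loss functions of the three-step protocol. The public loss_step* functions
# report the breakdown for a single slice and its latent bundle; the training
# engine (train.R) recomputes the same terms batched, with hand-derived
# gradients and the stop-gradient routing:
#   * codebook term  ||sg[z_d] - e||^2  -> gradients reach only the codebook
#   * commitment     lambda ||z_d - sg[e]||^2 -> gradients reach only the
#     encoder side (straight-through through the argmin).

loss_params <- function(params, side) {
  params$M <- effective_M(side, params, warn = FALSE)
  params
}

new_breakdown <- function(terms) {
  terms$total <- sum(unlist(terms))
  structure(terms, class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat("<loss_breakdown>\n")
  for (nm in names(x)) cat(sprintf("  %-17s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

recon_terms <- function(x, xhat, params) {
  list(recon_l2 = sum((x - xhat)^2),
       msssim_term = 1 - ms_ssim(x, xhat, params))
}

vq_terms <- function(z_ref, z_q, lambda) {
  sq <- sum((z_ref - z_q)^2)
  list(codebook_term = sq, commit_term = lambda * sq)
}

#' Step-1 loss: outer VQ autoencoder only
#'
#' `total = ||x - xhat||^2 + (1 - MS_SSIM(x, xhat)) + ||sg[z_e] - e||^2 +
#' lambda ||z_e - sg[e]||^2`, where `e` are the selected codebook embeddings.
#' The bundle must come from a bypass-mode forward (`z_d` identical to `z_e`).
#'
#' @param x input slice matrix.
#' @param bundle latent bundle from [vq_forward()] with `bypass = TRUE`.
#' @param codebook `K x D` codebook matrix (used for validation only; the
#'   selected embeddings are already materialized in `bundle$z_q`).
#' @param lambda commitment coefficient (reference value 0.25).
#' @param params [msssim_params()] for the reconstruction term.
#' @return a `loss_breakdown`.
#' @export
loss_step1 <- function(x, bundle, codebook, lambda = 0.25,
                       params = msssim_params()) {
  if (!isTRUE(bundle$bypass))
    stop("loss_step1 expects a bypass-mode bundle", call. = FALSE)
  x <- as_batch(x)
  params <- loss_params(params, dim(x)[1])
  new_breakdown(c(recon_terms(drop(x), drop(bundle$xhat), params),
                  vq_terms(bundle$z_e, bundle$z_q, lambda)))
}

#' Step-2 loss: full network without the SVDD term
#'
#' Step-1 terms with `z_d` (the Decoder-2 output) replacing `z_e` in the
#' codebook and commitment terms, plus the consistency term
#' `||z_e - z_d||^2` tying the inner autoencoder to the latent map the
#' codebook was trained on.
#'
#' @inheritParams loss_step1
#' @param bundle latent bundle from a full forward pass.
#' @return a `loss_breakdown`.
#' @export
loss_step2 <- function(x, bundle, codebook, lambda = 0.25,
                       params = msssim_params()) {
  if (isTRUE(bundle$bypass))
    stop("loss_step2 expects a full forward bundle", call. = FALSE)
  x <- as_batch(x)
  params <- loss_params(params, dim(x)[1])
  new_breakdown(c(recon_terms(drop(x), drop(bundle$xhat), params),
                  vq_terms(bundle$z_d, bundle$z_q, lambda),
                  list(consistency_term = sum((bundle$z_e - bundle$z_d)^2))))
}

#' Step-3 loss: full network with the SVDD hypersphere term
#'
#' Step-2 terms plus `||z(x) - c||^2`, pulling the Encoder-2 latent toward
#' the hypersphere center. The center is treated as data: no gradient is
#' applied to `c`.
#'
#' @inheritParams loss_step2
#' @param sphere a hypersphere state with element `center`.
#' @return a `loss_breakdown`.
#' @export
loss_step3 <- function(x, bundle, codebook, lambda = 0.25, sphere,
                       params = msssim_params()) {
  if (is.null(sphere) || is.null(sphere$center))
    stop("hypersphere center not initialized", call. = FALSE)
  b2 <- loss_step2(x, bundle, codebook, lambda, params)
  terms <- b2[setdiff(names(b2), "total")]
  terms$svdd_term <- sum((as.numeric(bundle$z) - sphere$center)^2)
  new_breakdown(terms)
}

# ---- batched loss + gradients (training engine) ---------------------------

# Returns mean-over-batch loss breakdown and gradients for every parameter
# group. `step` selects the active terms and the bypass topology.
# `keep_internals` additionally returns the z-level derivative quantities
# (dzq: gradient of the reconstruction terms at the quantized map; dz_ref:
# what the straight-through estimator hands to the encoder side), which the
# gradient-routing audits inspect.
vq_loss_grads <- function(model, x, step, lambda, center = NULL,
                          params = msssim_params(), keep_internals = FALSE) {
  x <- as_batch(x)
  N <- dim(x)[4]
  params <- loss_params(params, dim(x)[1])
  bundle <- vq_forward(model, x, bypass = (step == 1L), keep_cache = TRUE)
  sp <- model$specs; pa <- model$params
  xhat <- bundle$xhat

  recon <- 0; mst <- 0
  dxhat <- array(0, dim(xhat))
  for (i in seq_len(N)) {
    xi <- x[, , 1L, i]; yi <- xhat[, , 1L, i]
    g <- ms_ssim_grad(xi, yi, params)
    recon <- recon + sum((xi - yi)^2)
    mst <- mst + (1 - g$value)
    dxhat[, , 1L, i] <- (2 * (yi - xi) - g$grad) / N
  }
  recon <- recon / N; mst <- mst / N

  g4 <- seq_bwd(sp$dec1, pa$dec1, bundle$caches$dec1, dxhat)
  dzq <- g4$dx

  z_ref <- if (step == 1L) bundle$z_e else bundle$z_d
  diffq <- z_ref - bundle$z_q
  codebook_term <- sum(diffq^2) / N
  commit_term <- lambda * codebook_term

  # codebook gradient: 2 (e_k - z_ref) accumulated over assigned pixels
  D <- dim(z_ref)[3]
  Zmat <- matrix(aperm(z_ref, c(1, 2, 4, 3)), ncol = D)
  idx <- as.integer(bundle$indices)
  contrib <- 2 * (pa$codebook[idx, , drop = FALSE] - Zmat) / N
  dE <- matrix(0, nrow(pa$codebook), D)
  agg <- rowsum(contrib, group = idx)
  dE[as.integer(rownames(agg)), ] <- agg

  # straight-through + commitment into the pre-quantization map
  dz_ref <- dzq + 2 * lambda * diffq / N

  grads <- list(enc1 = NULL, enc2 = NULL, dec2 = NULL, dec1 = g4$grads,
                codebook = dE)
  terms <- list(recon_l2 = recon, msssim_term = mst,
                codebook_term = codebook_term, commit_term = commit_term)

  if (step == 1L) {
    g1 <- seq_bwd(sp$enc1, pa$enc1, bundle$caches$enc1, dz_ref)
    grads$enc1 <- g1$grads
  } else {
    cons <- sum((bundle$z_e - bundle$z_d)^2) / N
    terms$consistency_term <- cons
    dz_d <- dz_ref + 2 * (bundle$z_d - bundle$z_e) / N
    dz_e_extra <- 2 * (bundle$z_e - bundle$z_d) / N
    g3 <- seq_bwd(sp$dec2, pa$dec2, bundle$caches$dec2, dz_d)
    dz <- g3$dx
    if (step == 3L) {
      dz_c <- bundle$z - center
      terms$svdd_term <- sum(dz_c^2) / N
      dz <- dz + 2 * dz_c / N
    }
    g2 <- seq_bwd(sp$enc2, pa$enc2, bundle$caches$enc2, dz)
    g1 <- seq_bwd(sp$enc1, pa$enc1, bundle$caches$enc1, g2$dx + dz_e_extra)
    grads$enc1 <- g1$grads; grads$enc2 <- g2$grads; grads$dec2 <- g3$grads
  }
  out <- list(breakdown = new_breakdown(terms), grads = grads, bundle = bundle)
  if (keep_internals) out$internals <- list(dzq = dzq, dz_ref = dz_ref)
  out
}

# VAE baseline loss + gradients: recon terms as above plus KL to N(0, I).
vae_loss_grads <- function(model, x, params = msssim_params()) {
  x <- as_batch(x)
  N <- dim(x)[4]
  params <- loss_params(params, dim(x)[1])
  fw <- vae_forward(model, x, sample = TRUE, keep_cache = TRUE)
  sp <- model$specs; pa <- model$params
  xhat <- fw$xhat
  recon <- 0; mst <- 0
  dxhat <- array(0, dim(xhat))
  for (i in seq_len(N)) {
    xi <- x[, , 1L, i]; yi <- xhat[, , 1L, i]
    g <- ms_ssim_grad(xi, yi, params)
    recon <- recon + sum((xi - yi)^2)
    mst <- mst + (1 - g$value)
    dxhat[, , 1L, i] <- (2 * (yi - xi) - g$grad) / N
  }
  recon <- recon / N; mst <- mst / N
  kl <- vae_kl(fw$mu, fw$logvar)

  gd <- seq_bwd(sp$dec, pa$dec, fw$caches$dec, dxhat)
  dz <- gd$dx
  dmu <- dz + fw$mu / N
  dlv <- dz * fw$eps * exp(fw$logvar / 2) / 2 -
    0.5 * (1 - exp(fw$logvar)) / N
  gmu <- seq_bwd(sp$mu, pa$mu, fw$caches$mu, dmu)
  glv <- seq_bwd(sp$logvar, pa$logvar, fw$caches$logvar, dlv)
  ge <- seq_bwd(sp$enc, pa$enc, fw$caches$enc, gmu$dx + glv$dx)
  list(breakdown = new_breakdown(list(recon_l2 = recon, msssim_term = mst,
                                      kl_term = kl)),
       grads = list(enc = ge$grads, mu = gmu$grads, logvar = glv$grads,
                    dec = gd$grads))
}
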