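#' Parameters for MS-SSIM and single-scale SSIM
#'
#' Multi-scale structural similarity compares brightness (L), contrast (C)
#' and structure (S) between two images, with C and S evaluated at every
#' dyadic scale `j = 0..M` (each halving is a 2x2 average-pool) and L at the
#' coarsest scale only:
#' \deqn{MS\_SSIM = L^{\alpha} \prod_{j=0}^{M} C_j^{\beta} S_j^{\gamma}.}
#' Per-window statistics are averaged into scalar components before the
#' product is taken.
#'
#' The structure term is available in two forms: `"standard"` uses the
#' covariance-normalized \eqn{S = (2\sigma_{xy}+\delta_3)/(2\sigma_x\sigma_y+\delta_3)}
#' (consistent SSIM dimensions, the default) and `"literal"` uses
#' \eqn{(2\sigma_{xy}+\delta_3)/(\sigma_x+\sigma_y+\delta_3)}.
#'
#' @param delta1,delta2,delta3 stabilization constants (> 0).
#' @param alpha,beta,gamma component exponents.
#' @param M number of halvings; automatically reduced so the coarsest scale
#'   keeps at least 8 px per side (with a warning).
#' @param window `"gaussian"` (default, 11x11, sigma 1.5) or `"uniform"`.
#' @param window_size odd window side length; truncated when wider than the
#'   current scale.
#' @param window_sigma Gaussian window sigma.
#' @param structure_form `"standard"` or `"literal"` (see above).
#' @return an object of class `msssim_params`.
#' @export
msssim_params <- function(delta1 = 1e-4, delta2 = 9e-4, delta3 = 4.5e-4,
                          alpha = 1, beta = 1, gamma = 1, M = 5,
                          window = c("gaussian", "uniform"),
                          window_size = 11L, window_sigma = 1.5,
                          structure_form = c("standard", "literal")) {
  if (any(c(delta1, delta2, delta3) <= 0))
    stop("stabilization constants must be > 0", call. = FALSE)
  if (M < 0) stop("M must be >= 0", call. = FALSE)
  if (window_size %% 2 == 0) stop("window size must be odd", call. = FALSE)
  structure(list(delta1 = delta1, delta2 = delta2, delta3 = delta3,
                 alpha = alpha, beta = beta, gamma = gamma, M = as.integer(M),
                 window = match.arg(window),
                 window_size = as.integer(window_size),
                 window_sigma = window_sigma,
                 structure_form = match.arg(structure_form)),
            class = "msssim_params")
}

window_weights <- function(len, params) {
  if (params$window == "uniform") return(rep(1 / len, len))
  t <- seq_len(len) - (len + 1) / 2
  w <- exp(-t^2 / (2 * params$window_sigma^2))
  w / sum(w)
}

# valid-window band matrix: rows = window positions, cols = pixels
band_matrix <- function(side, w) {
  len <- length(w)
  P <- side - len + 1L
  K <- matrix(0, P, side)
  for (p in seq_len(P)) K[p, p:(p + len - 1L)] <- w
  K
}

scale_band <- function(side, params) {
  len <- min(params$window_size, side)
  if (len %% 2 == 0) len <- len - 1L
  band_matrix(side, window_weights(len, params))
}

# windowed first/second moments of one image pair at one scale
scale_stats <- function(x, y, K) {
  muX <- K %*% x %*% t(K)
  muY <- K %*% y %*% t(K)
  sxx <- pmax(K %*% (x * x) %*% t(K) - muX^2, 0)
  syy <- pmax(K %*% (y * y) %*% t(K) - muY^2, 0)
  sxy <- K %*% (x * y) %*% t(K) - muX * muY
  list(muX = muX, muY = muY, sxx = sxx, syy = syy, sxy = sxy,
       sigX = sqrt(sxx), sigY = sqrt(syy))
}

component_maps <- function(st, params) {
  Lmap <- (2 * st$muX * st$muY + params$delta1) /
    (st$muX^2 + st$muY^2 + params$delta1)
  Cmap <- (2 * st$sigX * st$sigY + params$delta2) /
    (st$sxx + st$syy + params$delta2)
  Smap <- if (params$structure_form == "standard")
    (2 * st$sxy + params$delta3) / (2 * st$sigX * st$sigY + params$delta3)
  else
    (2 * st$sxy + params$delta3) / (st$sigX + st$sigY + params$delta3)
  list(L = Lmap, C = Cmap, S = Smap)
}

#' Windowed SSIM components of an image pair
#'
#' Computes the brightness, contrast and structure comparison terms per
#' window at full resolution and averages each into a scalar.
#'
#' @param x,xhat equal-sized numeric matrices with values in `[0, 1]`.
#' @param params an [msssim_params()].
#' @return named numeric vector `c(L =, C =, S =)`.
#' @export
ssim_components <- function(x, xhat, params = msssim_params()) {
  if (!identical(dim(x), dim(xhat))) stop_dim("image shapes differ")
  K <- scale_band(nrow(x), params)
  cm <- component_maps(scale_stats(x, xhat, K), params)
  c(L = mean(cm$L), C = mean(cm$C), S = mean(cm$S))
}

# 2x2 average pooling (odd trailing row/col dropped)
pool2 <- function(x) {
  H <- 2L * (nrow(x) %/% 2L); W <- 2L * (ncol(x) %/% 2L)
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  p1 <- seq(1L, W, 2L); p2 <- seq(2L, W, 2L)
  (x[o1, p1] + x[o2, p1] + x[o1, p2] + x[o2, p2]) / 4
}

# adjoint of pool2 into an image of size (H, W)
unpool2 <- function(g, H, W) {
  out <- matrix(0, H, W)
  h <- nrow(g); w <- ncol(g)
  idx1 <- seq_len(h) * 2L - 1L; idx2 <- seq_len(w) * 2L - 1L
  out[idx1, idx2] <- g / 4; out[idx1 + 1L, idx2] <- g / 4
  out[idx1, idx2 + 1L] <- g / 4; out[idx1 + 1L, idx2 + 1L] <- g / 4
  out
}

effective_M <- function(side, params, warn = TRUE) {
  M_eff <- max(0L, min(params$M, as.integer(floor(log2(side))) - 3L))
  if (warn && M_eff < params$M)
    warning(sprintf("M reduced from %d to %d for a %d-px image",
                    params$M, M_eff, side), call. = FALSE)
  M_eff
}

#' Multi-scale structural similarity of an image pair
#'
#' @inheritParams ssim_components
#' @return scalar MS-SSIM value (1 for identical images).
#' @export
ms_ssim <- function(x, xhat, params = msssim_params()) {
  if (!identical(dim(x), dim(xhat))) stop_dim("image shapes differ")
  side <- nrow(x)
  if (side < 8) stop_dim("image too small for MS-SSIM (need >= 8 px)")
  M_eff <- effective_M(side, params)
  acc <- 1
  for (j in 0:M_eff) {
    K <- scale_band(nrow(x), params)
    cm <- component_maps(scale_stats(x, xhat, K), params)
    acc <- acc * mean(cm$C)^params$beta * mean(cm$S)^params$gamma
    if (j == M_eff) acc <- acc * mean(cm$L)^params$alpha
    else { x <- pool2(x); xhat <- pool2(xhat) }
  }
  acc
}

# Value and analytic gradient of MS-SSIM w.r.t. xhat for one image pair.
# Requires unit exponents (the training configuration); validated against
# finite differences in the test suite.
ms_ssim_grad <- function(x, xhat, params = msssim_params()) {
  stopifnot(params$alpha == 1, params$beta == 1, params$gamma == 1)
  side <- nrow(x)
  M_eff <- effective_M(side, params, warn = FALSE)
  n_sc <- M_eff + 1L
  xs <- vector("list", n_sc); ys <- vector("list", n_sc)
  xs[[1]] <- x; ys[[1]] <- xhat
  for (j in seq_len(M_eff)) {
    xs[[j + 1]] <- pool2(xs[[j]]); ys[[j + 1]] <- pool2(ys[[j]])
  }
  cb <- numeric(n_sc); sb <- numeric(n_sc); Lbar <- NA_real_
  dC <- vector("list", n_sc); dS <- vector("list", n_sc); dL <- NULL
  for (j in seq_len(n_sc)) {
    xj <- xs[[j]]; yj <- ys[[j]]
    K <- scale_band(nrow(xj), params)
    st <- scale_stats(xj, yj, K)
    cm <- component_maps(st, params)
    P <- length(cm$C)
    cb[j] <- mean(cm$C); sb[j] <- mean(cm$S)
    adj <- function(G) t(K) %*% G %*% K
    sigY_s <- pmax(st$sigY, 1e-12)
    # contrast: depends on y only through sigma_y
    DnC <- st$sxx + st$syy + params$delta2
    NnC <- 2 * st$sigX * st$sigY + params$delta2
    G1 <- ((2 * st$sigX * DnC - NnC * 2 * st$sigY) / DnC^2) / sigY_s
    dC[[j]] <- (yj * adj(G1) - adj(G1 * st$muY)) / P
    # structure: depends on sigma_xy and sigma_y
    NnS <- 2 * st$sxy + params$delta3
    if (params$structure_form == "standard") {
      DnS <- 2 * st$sigX * st$sigY + params$delta3
      A <- 2 / DnS
      B <- (-NnS * 2 * st$sigX / DnS^2) / sigY_s
    } else {
      DnS <- st$sigX + st$sigY + params$delta3
      A <- 2 / DnS
      B <- (-NnS / DnS^2) / sigY_s
    }
    dS[[j]] <- (xj * adj(A) - adj(A * st$muX) +
                  yj * adj(B) - adj(B * st$muY)) / P
    if (j == n_sc) {
      DnL <- st$muX^2 + st$muY^2 + params$delta1
      NnL <- 2 * st$muX * st$muY + params$delta1
      Lbar <- mean(cm$L)
      dL <- adj((2 * st$muX * DnL - NnL * 2 * st$muY) / DnL^2) / P
    }
  }
  value <- Lbar * prod(cb * sb)
  cs <- cb * sb
  # leave-one-out product coefficients (avoids dividing by near-zero terms)
  loo <- vapply(seq_len(n_sc), function(j) prod(cs[-j]), 0)
  g <- Lbar * loo[n_sc] * (sb[n_sc] * dC[[n_sc]] + cb[n_sc] * dS[[n_sc]]) +
    prod(cs) * dL
  if (n_sc > 1L) {
    for (j in seq(n_sc - 1L, 1L)) {
      g <- unpool2(g, nrow(ys[[j]]), ncol(ys[[j]])) +
        Lbar * loo[j] * (sb[j] * dC[[j]] + cb[j] * dS[[j]])
    }
  }
  list(value = value, grad = g)
}

#' Reconstruction fidelity metrics
#'
#' RMSE, PSNR (for images with dynamic range 1) and single-scale SSIM
#' (mean of the windowed L*C*S product map, standard structure form).
#'
#' @inheritParams ssim_components
#' @return list with elements `rmse`, `psnr` (dB; `Inf` for identical
#'   images) and `ssim`.
#' @export
fidelity <- function(x, xhat, params = msssim_params()) {
  if (!identical(dim(x), dim(xhat))) stop_dim("image shapes differ")
  rmse <- sqrt(mean((x - xhat)^2))
  psnr <- if (rmse == 0) Inf else 20 * log10(1 / rmse)
  K <- scale_band(nrow(x), params)
  cm <- component_maps(scale_stats(x, xhat, K), params)
  list(rmse = rmse, psnr = psnr, ssim = mean(cm$L * cm$C * cm$S))
}
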