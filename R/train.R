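#' Training configuration for the three-step protocol
#'
#' Reference hyperparameters: batch size 64, Adam with learning rate 1e-4,
#' up to 200 epochs per step, commitment coefficient `lambda = 0.25`.
#' Scaled-down benchmarks typically reduce epochs and raise the learning
#' rate (see the package vignette).
#'
#' @param batch_size slices per minibatch (>= 1).
#' @param learning_rate Adam step size.
#' @param epochs integer vector of length 3: epochs for Steps 1-3 (a single
#'   value is recycled).
#' @param lambda commitment coefficient (> 0).
#' @param seed master seed for initialization, shuffling and sampling.
#' @param center_refresh `"epoch_latents"` (update the hypersphere center
#'   from the latents collected during the epoch, the default) or
#'   `"full_pass"` (an extra full forward pass per epoch).
#' @param codebook_init `"encoder_sample"` (default) seeds the codebook with
#'   latent vectors drawn from the initial encoder on training slices, so
#'   quantization starts in the occupied region of latent space;
#'   `"uniform"` keeps the model's uniform `[-1/K, 1/K]` initialization.
#' @param pretrained_lr_factor learning-rate multiplier applied in Steps 2
#'   and 3 to the module groups pretrained in Step 1 (Encoder 1, Decoder 1,
#'   codebook), while the freshly added Encoder 2 / Decoder 2 train at the
#'   full rate. 1 trains all groups uniformly; smaller values protect the
#'   learned reconstruction while the inner autoencoder catches up, which
#'   prevents a collapse of all latents onto a single point when the epoch
#'   budget is small.
#' @param lr_decay `"none"` (constant rate, the default) or `"cosine"`
#'   (cosine annealing of the learning rate over each step's epochs).
#' @param msssim [msssim_params()] used inside every loss.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 1e-4,
                         epochs = c(200L, 200L, 200L), lambda = 0.25,
                         seed = 1L,
                         center_refresh = c("epoch_latents", "full_pass"),
                         codebook_init = c("encoder_sample", "uniform"),
                         pretrained_lr_factor = 1,
                         lr_decay = c("none", "cosine"),
                         msssim = msssim_params()) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  epochs <- as.integer(rep(epochs, length.out = 3L))
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = epochs,
                 lambda = lambda, seed = as.integer(seed),
                 center_refresh = match.arg(center_refresh),
                 codebook_init = match.arg(codebook_init),
                 pretrained_lr_factor = pretrained_lr_factor,
                 lr_decay = match.arg(lr_decay),
                 msssim = msssim),
            class = "train_config")
}

# stack all slices of a volume list into an (H, W, 1, N) tensor + index table
slices_tensor <- function(volumes) {
  mats <- unlist(lapply(volumes, `[[`, "slices"), recursive = FALSE)
  H <- nrow(mats[[1]])
  x <- array(unlist(mats), c(H, ncol(mats[[1]]), 1L, length(mats)))
  info <- do.call(rbind, lapply(volumes, function(v)
    data.frame(case_id = v$case_id, slice_index = seq_along(v$slices),
               flag = v$anomaly_slice_flags, label = v$label)))
  list(x = x, info = info)
}

# Encoder-2 latents for a batch tensor, in evaluation mode
encode_z <- function(model, x) {
  x <- as_batch(x)
  f1 <- seq_fwd(model$specs$enc1, model$params$enc1, x, keep_cache = FALSE)
  seq_fwd(model$specs$enc2, model$params$enc2, f1$out,
          keep_cache = FALSE)$out
}

#' Initialize the hypersphere center
#'
#' The center `c` is the arithmetic mean of the Encoder-2 latent vectors
#' `z(x)` over all training slices of the Step-2-trained network.
#'
#' @param model a `vq_svdd_model` (after Step-2 training).
#' @param volumes list of training `exam_volume`s (or an `(H,W,1,N)` tensor).
#' @param batch_size forward-pass batch size.
#' @return hypersphere state: list with `center` and `n` (slices averaged).
#' @export
initialize_center <- function(model, volumes, batch_size = 64L) {
  if (is.list(volumes) && !is.array(volumes) && length(volumes) == 0L)
    stop("cannot initialize the center from an empty set", call. = FALSE)
  x <- if (is.list(volumes) && !is.array(volumes)) slices_tensor(volumes)$x
       else as_batch(volumes)
  n <- dim(x)[4]
  if (n == 0L) stop("cannot initialize the center from an empty set",
                    call. = FALSE)
  acc <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    z <- encode_z(model, x[, , , b, drop = FALSE])
    acc <- acc + rowSums(z)
  }
  structure(list(center = acc / n, n = n), class = "hypersphere_state")
}

#' Update the hypersphere center from an epoch's latents
#'
#' End-of-epoch replacement: the new center is the mean of the latent
#' vectors collected over the epoch (not a running average across epochs).
#' An empty latent set leaves the center unchanged with a warning.
#'
#' @param sphere a hypersphere state.
#' @param epoch_latents `svdd_latent_dim x n` matrix of latents.
#' @return the updated hypersphere state.
#' @export
update_center <- function(sphere, epoch_latents) {
  if (is.null(epoch_latents) || length(epoch_latents) == 0L ||
      NCOL(epoch_latents) == 0L) {
    warning("no latents collected this epoch; center unchanged")
    return(sphere)
  }
  sphere$center <- rowMeans(as.matrix(epoch_latents))
  sphere$n <- NCOL(epoch_latents)
  sphere
}

adam_update_groups <- function(params, grads, states, groups, lrs) {
  for (g in groups) {
    r <- adam_step(params[[g]], grads[[g]], states[[g]], lrs[[g]])
    params[[g]] <- r$params; states[[g]] <- r$state
  }
  list(params = params, states = states)
}

#' Train VQ-VAE with SVDD (three-step protocol)
#'
#' Step 1 trains the outer autoencoder (Encoder 1, codebook, Decoder 1) in
#' bypass mode; Step 2 trains the full network without the SVDD term,
#' after which the hypersphere center is initialized as the mean latent;
#' Step 3 trains the full loss, refreshing the center every epoch. All
#' steps see only normal volumes; an abnormal volume in the training set is
#' a configuration error, since the method is one-class.
#'
#' @param volumes list of normal `exam_volume`s.
#' @param arch an [arch_config()].
#' @param cfg a [train_config()].
#' @return an object of class `vq_svdd_fit`: the trained `model`, the
#'   hypersphere `sphere`, a per-epoch `history` data frame and the configs.
#' @export
train_vq_svdd <- function(volumes, arch, cfg = train_config()) {
  labs <- vapply(volumes, `[[`, "", "label")
  if (any(labs != "normal"))
    stop("training set must contain only normal volumes", call. = FALSE)
  st <- slices_tensor(volumes)
  x_all <- st$x
  n <- dim(x_all)[4]
  arch$seed <- cfg$seed
  model <- vq_svdd_model(arch)
  if (cfg$codebook_init == "encoder_sample" && n > 0L) {
    sub <- seq_len(min(64L, n))
    z_e <- seq_fwd(model$specs$enc1, model$params$enc1,
                   x_all[, , , sub, drop = FALSE], keep_cache = FALSE)$out
    Z <- matrix(aperm(z_e, c(1, 2, 4, 3)), ncol = dim(z_e)[3])
    K <- arch$codebook_size
    model$params$codebook <- with_seed(mix_seed(cfg$seed, 0L, 17L), {
      pick <- sample.int(nrow(Z), K, replace = nrow(Z) < K)
      Z[pick, , drop = FALSE] +
        matrix(rnorm(K * ncol(Z), 0, 0.01), K, ncol(Z))
    })
  }
  history <- list()
  sphere <- NULL

  run_step <- function(step, groups) {
    states <- lapply(model$params[groups], adam_init)
    names(states) <- groups
    lrs <- stats::setNames(rep(cfg$learning_rate, length(groups)), groups)
    if (step > 1L) {
      pre <- intersect(groups, c("enc1", "dec1", "codebook"))
      lrs[pre] <- cfg$learning_rate * cfg$pretrained_lr_factor
    }
    for (epoch in seq_len(cfg$epochs[step])) {
      decay <- if (cfg$lr_decay == "cosine")
        0.5 * (1 + cos(pi * (epoch - 1) / max(1L, cfg$epochs[step]))) else 1
      lrs_e <- lrs * decay
      ord <- with_seed(mix_seed(cfg$seed, epoch, salt = step), sample.int(n))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      sums <- NULL; nb <- 0L
      epoch_z <- NULL
      for (b in batches) {
        r <- vq_loss_grads(model, x_all[, , , b, drop = FALSE], step,
                           cfg$lambda,
                           center = if (step == 3L) sphere$center,
                           params = cfg$msssim)
        upd <- adam_update_groups(model$params, r$grads, states, groups, lrs_e)
        model$params <<- upd$params; states <- upd$states
        t <- unlist(r$breakdown)
        sums <- if (is.null(sums)) t else sums + t
        nb <- nb + 1L
        if (step == 3L) epoch_z <- cbind(epoch_z, r$bundle$z)
      }
      center_updated <- FALSE
      radius <- NA_real_
      if (step == 3L) {
        sphere <<- if (cfg$center_refresh == "full_pass")
          initialize_center(model, x_all, cfg$batch_size)
        else update_center(sphere, epoch_z)
        center_updated <- TRUE
        # hypersphere radius diagnostic: mean squared distance of the
        # training-slice latents from the current center
        acc <- 0
        for (bb in split(seq_len(n), ceiling(seq_len(n) / 64))) {
          zb <- encode_z(model, x_all[, , , bb, drop = FALSE])
          acc <- acc + sum(colSums((zb - sphere$center)^2))
        }
        radius <- acc / n
      }
      row <- as.list(sums / nb)
      history[[length(history) + 1L]] <<- c(list(step = step, epoch = epoch,
                                                 center_updated = center_updated,
                                                 svdd_radius = radius),
                                            row)
    }
  }

  run_step(1L, c("enc1", "dec1", "codebook"))
  run_step(2L, c("enc1", "enc2", "dec2", "dec1", "codebook"))
  if (n > 0L) sphere <- initialize_center(model, x_all, cfg$batch_size)
  run_step(3L, c("enc1", "enc2", "dec2", "dec1", "codebook"))

  cols <- c("step", "epoch", "center_updated", "svdd_radius", "recon_l2",
            "msssim_term", "codebook_term", "commit_term", "consistency_term",
            "svdd_term", "total")
  hist_df <- if (length(history))
    do.call(rbind, lapply(history, function(r) {
      r <- c(r, stats::setNames(as.list(rep(NA_real_, sum(!cols %in% names(r)))),
                                cols[!cols %in% names(r)]))
      as.data.frame(r[cols], check.names = FALSE)
    }))
  else data.frame()
  structure(list(model = model, sphere = sphere, history = hist_df,
                 arch = arch, cfg = cfg),
            class = "vq_svdd_fit")
}

#' Train the plain VAE baseline
#'
#' Single-phase training with the same per-slice reconstruction terms and a
#' KL term; by convention the epoch budget equals the sum of the three
#' step budgets of the proposed model, so comparisons share compute.
#'
#' @param volumes list of normal `exam_volume`s.
#' @param arch an [arch_config()].
#' @param cfg a [train_config()]; `sum(cfg$epochs)` epochs are run.
#' @return an object of class `vae_fit` with `model` and `history`.
#' @export
train_vae <- function(volumes, arch, cfg = train_config()) {
  labs <- vapply(volumes, `[[`, "", "label")
  if (any(labs != "normal"))
    stop("training set must contain only normal volumes", call. = FALSE)
  st <- slices_tensor(volumes)
  x_all <- st$x
  n <- dim(x_all)[4]
  arch$seed <- cfg$seed
  model <- vae_model(arch)
  state <- adam_init(model$params)
  history <- list()
  for (epoch in seq_len(sum(cfg$epochs))) {
    seed_e <- mix_seed(cfg$seed, epoch, salt = 9L)
    hist_row <- with_seed(seed_e, {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      sums <- NULL; nb <- 0L
      for (b in batches) {
        r <- vae_loss_grads(model, x_all[, , , b, drop = FALSE], cfg$msssim)
        u <- adam_step(model$params, r$grads, state, cfg$learning_rate)
        model$params <- u$params; state <- u$state
        t <- unlist(r$breakdown)
        sums <- if (is.null(sums)) t else sums + t
        nb <- nb + 1L
      }
      as.list(sums / nb)
    })
    history[[epoch]] <- c(list(epoch = epoch), hist_row)
  }
  structure(list(model = model,
                 history = do.call(rbind, lapply(history, as.data.frame)),
                 arch = arch, cfg = cfg),
            class = "vae_fit")
}
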