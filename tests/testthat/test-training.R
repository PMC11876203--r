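# Build a latent bundle by hand so the loss identities can be checked in
# isolation from the network.
fake_bundle <- function(x, z_e, z_q, z_d = NULL, z = NULL, bypass = TRUE) {
  list(z_e = z_e, z = z, z_d = if (is.null(z_d)) z_e else z_d, z_q = z_q,
       indices = NULL, xhat = vqsvdd:::as_batch(x), bypass = bypass)
}

test_that("step-1 loss vanishes at a perfect fixed point and sums its terms", {
  set.seed(1)
  x <- matrix(runif(16 * 16), 16)
  z <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  b <- fake_bundle(x, z_e = z, z_q = z)
  l0 <- loss_step1(x, b, codebook = NULL, lambda = 0.25,
                   params = msssim_params(M = 1, window_size = 5))
  expect_equal(l0$total, 0, tolerance = 1e-12)
  # commitment is lambda times the codebook distance; total is the exact sum
  zq <- z + 0.1
  b2 <- fake_bundle(x, z_e = z, z_q = zq)
  l <- loss_step1(x, b2, NULL, lambda = 0.25,
                  params = msssim_params(M = 1, window_size = 5))
  expect_equal(l$commit_term, 0.25 * l$codebook_term)
  expect_equal(l$codebook_term, 0.01 * length(z), tolerance = 1e-12)
  expect_equal(l$total, l$recon_l2 + l$msssim_term + l$codebook_term +
                 l$commit_term)
  expect_true(all(unlist(l) >= 0))
})

test_that("step-2 adds the consistency term and reduces to step 1 when z_d = z_e", {
  set.seed(2)
  x <- matrix(runif(16 * 16), 16)
  z <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  zq <- z + 0.05
  p <- msssim_params(M = 1, window_size = 5)
  b1 <- fake_bundle(x, z_e = z, z_q = zq, bypass = TRUE)
  b2 <- fake_bundle(x, z_e = z, z_d = z, z_q = zq, bypass = FALSE)
  l1 <- loss_step1(x, b1, NULL, 0.25, p)
  l2 <- loss_step2(x, b2, NULL, 0.25, p)
  expect_equal(l2$consistency_term, 0)
  expect_equal(l2$total, l1$total)
  # maps differing by 0.1 in each of n elements -> 0.01 n
  b3 <- fake_bundle(x, z_e = z, z_d = z + 0.1, z_q = zq, bypass = FALSE)
  l3 <- loss_step2(x, b3, NULL, 0.25, p)
  expect_equal(l3$consistency_term, 0.01 * length(z), tolerance = 1e-12)
  expect_error(loss_step2(x, b1, NULL, 0.25, p), "full forward")
  expect_error(loss_step1(x, b2, NULL, 0.25, p), "bypass")
})

test_that("step-3 adds the hypersphere distance", {
  set.seed(3)
  x <- matrix(runif(16 * 16), 16)
  z_map <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  p <- msssim_params(M = 1, window_size = 5)
  cvec <- c(1, -1)
  b <- fake_bundle(x, z_e = z_map, z_d = z_map, z_q = z_map + 0.05,
                   z = matrix(cvec), bypass = FALSE)
  l2 <- loss_step2(x, b, NULL, 0.25, p)
  l3 <- loss_step3(x, b, NULL, 0.25, sphere = list(center = cvec), p)
  expect_equal(l3$svdd_term, 0)
  expect_equal(l3$total, l2$total)
  b$z <- matrix(cvec + c(0.3, 0.4))
  l3b <- loss_step3(x, b, NULL, 0.25, sphere = list(center = cvec), p)
  expect_equal(l3b$svdd_term, 0.25)
  expect_error(loss_step3(x, b, NULL, 0.25, sphere = NULL, p),
               "not initialized")
})

test_that("center updates replace rather than average across epochs", {
  sph <- list(center = c(0, 0))
  # mean of {(0,0), (2,2)} is (1,1)
  s1 <- update_center(sph, cbind(c(0, 0), c(2, 2)))
  expect_equal(s1$center, c(1, 1))
  # single latent: the center equals it
  expect_equal(update_center(sph, cbind(c(3, -1)))$center, c(3, -1))
  # epoch 2 overrides epoch 1 entirely
  s2 <- update_center(s1, cbind(c(10, 10), c(12, 12)))
  expect_equal(s2$center, c(11, 11))
  expect_warning(s3 <- update_center(s2, NULL), "no latents")
  expect_equal(s3$center, s2$center)
  # streaming-sum oracle over many latents
  set.seed(8)
  Z <- matrix(rnorm(16 * 1000), 16, 1000)
  acc <- numeric(16)
  for (i in seq_len(1000)) acc <- acc + Z[, i]
  expect_equal(update_center(sph, Z)$center, acc / 1000, tolerance = 1e-6)
})

test_that("initialize_center averages Encoder-2 latents over all slices", {
  arch <- tiny_arch()
  m <- vq_svdd_model(arch)
  vols <- tiny_volumes(2)
  sph <- initialize_center(m, vols, batch_size = 3)
  st <- vqsvdd:::slices_tensor(vols)
  z <- vqsvdd:::encode_z(m, st$x)
  expect_equal(sph$center, rowMeans(z), tolerance = 1e-10)
  expect_equal(sph$n, dim(st$x)[4])
  expect_error(initialize_center(m, list()), "empty")
})

test_that("zero-epoch training returns the seeded initialization", {
  arch <- tiny_arch()
  vols <- tiny_volumes(2)
  cfg <- train_config(batch_size = 4, epochs = c(0L, 0L, 0L), seed = 5L,
                      codebook_init = "uniform",
                      msssim = msssim_params(M = 1, window_size = 5))
  fit <- train_vq_svdd(vols, arch, cfg)
  arch5 <- arch; arch5$seed <- 5L
  expect_identical(fit$model$params, vq_svdd_model(arch5)$params)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training is deterministic, one-class, and logs center updates", {
  arch <- tiny_arch()
  vols <- tiny_volumes(2)
  cfg <- tiny_cfg(seed = 2L)
  f1 <- train_vq_svdd(vols, arch, cfg)
  f2 <- train_vq_svdd(vols, arch, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$sphere$center, f2$sphere$center)
  # one center update per step-3 epoch, none elsewhere
  h <- f1$history
  expect_true(all(h$center_updated[h$step == 3]))
  expect_false(any(h$center_updated[h$step != 3]))
  expect_equal(sum(h$step == 3), cfg$epochs[3])
  # loss terms logged nonnegative and summing to the total
  act <- h[h$step == 3, c("recon_l2", "msssim_term", "codebook_term",
                          "commit_term", "consistency_term", "svdd_term")]
  expect_true(all(act >= 0))
  expect_equal(unname(rowSums(act)), h$total[h$step == 3], tolerance = 1e-9)
  # abnormal volumes are rejected: the method is one-class
  bad <- vols
  bad[[1]] <- inject_anomaly(bad[[1]], anomaly_spec("nodule", 3, 0.4, 1), 1)
  expect_error(train_vq_svdd(bad, arch, cfg), "only normal")
  expect_error(train_vae(bad, arch, cfg), "only normal")
})

test_that("the VAE baseline trains for the combined epoch budget", {
  fit <- train_vae(tiny_volumes(2), tiny_arch(), tiny_cfg(seed = 1L))
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(fit$history$kl_term >= 0))
})
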