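# Shared fixtures for the test suite.
#
# The scaled-down benchmark: 64-px phantoms, 20 normal training cases of
# 8-12 slices, reduced channel widths, 10 epochs per training step. Trained
# fits are cached per seed so the training-dynamics and separation tests
# share the same models.

bench_arch <- function() {
  arch_config(input_size = 64, latent_channels = 32, codebook_size = 64,
              svdd_latent_dim = 64, enc1_width = 16, enc2_width = 32)
}

bench_cfg <- function(seed) {
  train_config(batch_size = 1, learning_rate = 2e-3,
               epochs = c(10L, 10L, 10L), seed = seed,
               pretrained_lr_factor = 0.1, lr_decay = "cosine",
               msssim = msssim_params(M = 3))
}

bench_anomaly_specs <- function() {
  list(anomaly_spec("nodule", radius_px = 7, intensity_delta = 0.4,
                    n_slices_affected = 4),
       anomaly_spec("void", radius_px = 8, intensity_delta = -0.15,
                    n_slices_affected = 4))
}

bench_train_volumes <- function(seed) {
  pc <- phantom_config(image_size = 64, seed = 100 + seed)
  lapply(0:19, function(i) generate_normal_volume(pc, i))
}

bench_test_volumes <- function(seed) {
  pc <- phantom_config(image_size = 64, seed = 500 + seed)
  generate_dataset(pc, n_normal = 12, n_abnormal = 12, bench_anomaly_specs())
}

.bench_cache <- new.env(parent = emptyenv())

bench_fit <- function(seed) {
  key <- paste0("vq", seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- train_vq_svdd(bench_train_volumes(seed),
                                         bench_arch(), bench_cfg(seed))
  .bench_cache[[key]]
}

bench_vae_fit <- function(seed) {
  key <- paste0("vae", seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- train_vae(bench_train_volumes(seed),
                                     bench_arch(), bench_cfg(seed))
  .bench_cache[[key]]
}

# tiny architecture for fast unit tests of the network machinery
tiny_arch <- function(seed = 1L) {
  arch_config(input_size = 32, latent_channels = 4, codebook_size = 8,
              svdd_latent_dim = 8, enc1_width = 4, enc2_width = 4,
              n_res = 1L, seed = seed)
}

tiny_cfg <- function(seed = 1L, epochs = c(1L, 1L, 1L)) {
  train_config(batch_size = 4, learning_rate = 1e-3, epochs = epochs,
               seed = seed, msssim = msssim_params(M = 1, window_size = 5))
}

tiny_volumes <- function(n = 2L, seed = 7L) {
  pc <- phantom_config(image_size = 32, slices_min = 3, slices_max = 4,
                       vessel_count = 3, seed = seed)
  lapply(seq_len(n) - 1L, function(i) generate_normal_volume(pc, i))
}
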