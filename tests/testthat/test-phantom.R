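test_that("volume generation is deterministic in (seed, case_index)", {
  cfg <- phantom_config(seed = 11)
  expect_identical(generate_normal_volume(cfg, 0),
                   generate_normal_volume(cfg, 0))
  expect_identical(generate_normal_volume(cfg, 3),
                   generate_normal_volume(cfg, 3))
  # different cases differ while sharing layout statistics
  v0 <- generate_normal_volume(cfg, 0)
  v1 <- generate_normal_volume(cfg, 1)
  expect_gt(sum((v0$slices[[1]] - v1$slices[[1]])^2), 0)
})

test_that("all pixels stay in [0, 1] after noise", {
  cfg <- phantom_config(seed = 5, noise_sd = 0.1)
  v <- generate_normal_volume(cfg, 2)
  rng <- range(unlist(v$slices))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
})

test_that("lung fields are darker than the body wall", {
  cfg <- phantom_config(seed = 2)  # defaults: lung 0.2, body 0.6
  v <- generate_normal_volume(cfg, 0)
  for (k in c(1L, length(v$slices) %/% 2L)) {
    lung <- v$layout$lung[[k]]
    wall <- v$layout$body[[k]] & !lung
    expect_lt(mean(v$slices[[k]][lung]), mean(v$slices[[k]][wall]))
  }
})

test_that("anomaly injection sets flags, masks and label consistently", {
  cfg <- phantom_config(seed = 3)
  v <- generate_normal_volume(cfg, 0)
  for (kind in c("nodule", "consolidation", "void")) {
    delta <- if (kind == "void") -0.15 else 0.4
    sp <- anomaly_spec(kind, radius_px = 5, intensity_delta = delta,
                       n_slices_affected = 3)
    a <- inject_anomaly(v, sp, seed = 21)
    expect_equal(a$label, "abnormal")
    expect_equal(sum(a$anomaly_slice_flags), 3L)
    # flags true exactly where masks are nonzero
    nz <- vapply(a$anomaly_masks, function(m) any(m > 0), TRUE)
    expect_identical(nz, a$anomaly_slice_flags)
    # flagged slices are contiguous
    w <- which(a$anomaly_slice_flags)
    expect_identical(w, seq(min(w), max(w)))
  }
})

test_that("nodules brighten and voids darken the masked region", {
  cfg <- phantom_config(seed = 9)
  v <- generate_normal_volume(cfg, 1)
  nod <- inject_anomaly(v, anomaly_spec("nodule", 5, 0.4, 2), seed = 4)
  k <- which(nod$anomaly_slice_flags)[1]
  m <- nod$anomaly_masks[[k]] > 0
  expect_gt(mean(nod$slices[[k]][m]), mean(v$slices[[k]][m]))

  vd <- inject_anomaly(v, anomaly_spec("void", 5, -0.15, 2), seed = 4)
  k <- which(vd$anomaly_slice_flags)[1]
  m <- vd$anomaly_masks[[k]] > 0
  expect_lt(mean(vd$slices[[k]][m]), mean(v$slices[[k]][m]))
})

test_that("injection rejects invalid inputs and impossible placements", {
  cfg <- phantom_config(seed = 3)
  v <- generate_normal_volume(cfg, 0)
  a <- inject_anomaly(v, anomaly_spec("nodule", 4, 0.3, 1), seed = 1)
  expect_error(inject_anomaly(a, anomaly_spec("nodule", 4, 0.3, 1), seed = 1),
               "normal source")
  expect_error(inject_anomaly(v, anomaly_spec("nodule", 40, 0.3, 1), seed = 1),
               "fit inside")
  expect_error(anomaly_spec("void", 5, +0.2, 1), "negative")
  expect_error(phantom_config(image_size = 16), "image_size")
  expect_error(phantom_config(body_intensity = 1.4), "intensities")
})

test_that("generate_dataset honors counts, cycling and determinism", {
  cfg <- phantom_config(seed = 13)
  specs <- list(anomaly_spec("nodule", 5, 0.4, 2),
                anomaly_spec("void", 5, -0.15, 2))
  d1 <- generate_dataset(cfg, 6, 3, specs)
  expect_length(d1, 9L)
  labs <- vapply(d1, `[[`, "", "label")
  expect_equal(sum(labs == "abnormal"), 3L)
  # kinds cycled from the spec list
  expect_match(d1[[7]]$case_id, "nodule")
  expect_match(d1[[8]]$case_id, "void")
  expect_match(d1[[9]]$case_id, "nodule")
  expect_identical(generate_dataset(cfg, 6, 3, specs), d1)
  expect_length(generate_dataset(cfg, 0, 0), 0L)
  expect_error(generate_dataset(cfg, 2, 1), "anomaly_specs")
})
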