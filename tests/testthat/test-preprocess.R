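test_that("volume write/load round-trips within 16-bit quantization", {
  cfg <- phantom_config(image_size = 32, slices_min = 3, slices_max = 3,
                        vessel_count = 3, seed = 1)
  v <- inject_anomaly(generate_normal_volume(cfg, 0),
                      anomaly_spec("nodule", 3, 0.4, 2), seed = 2)
  dir <- withr::local_tempdir()
  write_volume(v, dir)
  r <- load_volume(dir)
  expect_equal(r$label, "abnormal")
  expect_identical(r$anomaly_slice_flags, v$anomaly_slice_flags)
  err <- max(mapply(function(a, b) max(abs(a - b)), r$slices, v$slices))
  expect_lte(err, 1 / 65535 + 1e-12)
  k <- which(v$anomaly_slice_flags)[1]
  expect_identical(r$anomaly_masks[[k]], v$anomaly_masks[[k]])
})

test_that("slices load in lexical filename order; empty dirs error", {
  dir <- withr::local_tempdir()
  for (i in 0:9)
    png::writePNG(matrix(i / 10, 8, 8), file.path(dir, sprintf("%03d.png", i)))
  v <- load_volume(dir)
  expect_length(v$slices, 10L)
  expect_equal(vapply(v$slices, function(s) s[1, 1], 0), (0:9) / 10,
               tolerance = 1 / 254)
  empty <- withr::local_tempdir()
  expect_error(load_volume(empty), "no slice images")
  # mixed sizes are a format error
  bad <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 8, 8), file.path(bad, "a.png"))
  png::writePNG(matrix(0.5, 9, 9), file.path(bad, "b.png"))
  expect_error(load_volume(bad), "mixed")
})

test_that("bicubic resize matches a direct Keys-kernel transcription", {
  # independent oracle: per-output-pixel double loop over the 4x4 support
  keys <- function(t, a = -0.5) {
    t <- abs(t)
    ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
           ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
  }
  oracle <- function(img, target) {
    s <- nrow(img)
    out <- matrix(0, target, target)
    for (i in seq_len(target)) for (j in seq_len(target)) {
      x <- (i - 0.5) * s / target + 0.5
      y <- (j - 0.5) * s / target + 0.5
      acc <- 0
      for (di in -1:2) for (dj in -1:2) {
        ti <- floor(x) + di; tj <- floor(y) + dj
        w <- keys(x - ti) * keys(y - tj)
        acc <- acc + w * img[min(max(ti, 1), s), min(max(tj, 1), s)]
      }
      out[i, j] <- acc
    }
    out
  }
  set.seed(31)
  img <- matrix(runif(144), 12, 12)
  expect_equal(resize_bicubic(img, 7), oracle(img, 7), tolerance = 1e-12)
  # downsampling halves the side; identity and constants are preserved
  expect_equal(dim(resize_bicubic(matrix(runif(64^2), 64), 32)), c(32L, 32L))
  expect_identical(resize_bicubic(img, 12), img)
  expect_equal(resize_bicubic(matrix(0.37, 10, 10), 5),
               matrix(0.37, 5, 5), tolerance = 1e-6)
  expect_message(resize_bicubic(img, 24), "upsampling")
})

test_that("min-max scaling is per-volume with the stated endpoint mapping", {
  sl <- list(matrix(c(-1000, 400, -300, 0), 2, 2), matrix(-200, 2, 2))
  v <- structure(list(case_id = "t", slices = sl, label = "normal",
                      anomaly_masks = list(matrix(0L, 2, 2), matrix(0L, 2, 2)),
                      anomaly_slice_flags = c(FALSE, FALSE), layout = NULL),
                 class = "exam_volume")
  r <- minmax_scale(v)
  expect_equal(r$slices[[1]][1, 1], 0)
  expect_equal(r$slices[[1]][2, 1], 1)
  expect_equal(r$slices[[1]][1, 2], (-300 + 1000) / 1400)  # 0.5
  # idempotent on a volume already spanning [0, 1]
  expect_equal(minmax_scale(r)$slices, r$slices)
  v$slices <- list(matrix(7, 2, 2))
  v$anomaly_masks <- v$anomaly_masks[1]; v$anomaly_slice_flags <- FALSE
  expect_warning(rc <- minmax_scale(v), "constant")
  expect_equal(rc$slices[[1]], matrix(0, 2, 2))
})

test_that("sixfold split partitions normals and isolates abnormals", {
  ids <- sprintf("n%02d", 1:12)
  ab <- c("a1", "a2")
  folds <- sixfold_split(ids, ab, seed = 42)
  expect_length(folds, 6L)
  tests <- lapply(folds, `[[`, "test_case_ids")
  expect_true(all(lengths(tests) == 2L))
  # test subsets are pairwise disjoint and cover all normals
  expect_setequal(unlist(tests), ids)
  expect_equal(anyDuplicated(unlist(tests)), 0L)
  for (f in folds) {
    expect_setequal(c(f$train_case_ids, f$validation_case_ids,
                      f$test_case_ids), ids)
    expect_length(f$train_case_ids, 8L)
    expect_equal(anyDuplicated(c(f$train_case_ids, f$validation_case_ids,
                                 f$test_case_ids)), 0L)
    # abnormal ids attach to every test set, never to training/validation
    expect_identical(f$abnormal_case_ids, ab)
    expect_length(intersect(ab, c(f$train_case_ids, f$validation_case_ids)), 0L)
  }
  # validation rotates: fold k validates subset (k+1) mod 6
  expect_identical(folds[[1]]$validation_case_ids, folds[[2]]$test_case_ids)
  expect_error(sixfold_split(ids[1:5], ab, 1), "at least 6")
})

test_that("a 1200-case split yields six subsets of 200", {
  folds <- sixfold_split(sprintf("c%04d", 1:1200), character(), seed = 7)
  expect_true(all(vapply(folds, function(f) length(f$test_case_ids), 0L) == 200L))
  expect_true(all(vapply(folds, function(f) length(f$train_case_ids), 0L) == 800L))
})

test_that("fold assignments survive JSON serialization", {
  folds <- sixfold_split(sprintf("n%02d", 1:13), "abn", seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_folds(folds, path)
  r <- read_folds(path)
  expect_equal(lapply(r, unclass), lapply(folds, unclass))
  # subset sizes differ by at most one when n is not divisible by 6
  sizes <- vapply(folds, function(f) length(f$test_case_ids), 0L)
  expect_lte(diff(range(sizes)), 1L)
})
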