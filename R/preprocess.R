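#' Write an examinee volume to a per-case directory
#'
#' Slices are stored as 16-bit grayscale TIFF files (`slice_000.tiff`, ...)
#' so the round-trip quantization error is at most 1/65535 per pixel, with a
#' JSON sidecar (`volume.json`) holding the case id, label and per-slice
#' abnormality flags; anomaly masks, when present, are stored as
#' `mask_###.tiff`.
#'
#' @param volume an `exam_volume` with pixels in `[0, 1]`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_volume <- function(volume, dir) {
  stopifnot(inherits(volume, "exam_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(volume$slices))
    tiff::writeTIFF(volume$slices[[k]],
                    file.path(dir, sprintf("slice_%03d.tiff", k - 1L)),
                    bits.per.sample = 16L)
  if (any(volume$anomaly_slice_flags))
    for (k in which(volume$anomaly_slice_flags))
      tiff::writeTIFF(volume$anomaly_masks[[k]] * 1.0,
                      file.path(dir, sprintf("mask_%03d.tiff", k - 1L)),
                      bits.per.sample = 16L)
  meta <- list(case_id = volume$case_id, label = volume$label,
               anomaly_slice_flags = volume$anomaly_slice_flags)
  jsonlite::write_json(meta, file.path(dir, "volume.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop_dim("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]   # take first channel
  img
}

#' Load an examinee volume from a directory of slice images
#'
#' Reads all PNG/TIFF files in lexical filename order; raw intensities are
#' preserved as floating values. A `volume.json` sidecar (as written by
#' [write_volume()]) restores the label, flags and masks; without one the
#' volume is labelled `"normal"` with empty masks.
#'
#' @param path directory containing slice images.
#' @return an `exam_volume`.
#' @export
load_volume <- function(path) {
  if (!dir.exists(path)) stop_dim("no such directory: ", path)
  files <- sort(list.files(path, pattern = "(?i)^slice.*\\.(png|tiff?)$",
                           full.names = TRUE))
  if (length(files) == 0L)
    files <- sort(list.files(path, pattern = "(?i)\\.(png|tiff?)$",
                             full.names = TRUE))
  files <- files[!grepl("^mask", basename(files))]
  if (length(files) == 0L)
    stop_dim("no slice images found in ", path)
  slices <- lapply(files, read_gray_image)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_dim("mixed slice sizes in ", path)
  n <- length(slices)
  s <- dims[1, 1]
  masks <- lapply(slices, function(x) matrix(0L, nrow(x), ncol(x)))
  flags <- rep(FALSE, n)
  label <- "normal"
  case_id <- basename(path)
  meta_path <- file.path(path, "volume.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    label <- meta$label
    case_id <- meta$case_id
    flags <- as.logical(meta$anomaly_slice_flags)[seq_len(n)]
    for (k in which(flags)) {
      mf <- file.path(path, sprintf("mask_%03d.tiff", k - 1L))
      if (file.exists(mf))
        masks[[k]] <- matrix(as.integer(read_gray_image(mf) > 0.5), s, s)
    }
  }
  new_exam_volume(case_id, slices, label, masks, flags, layout = NULL)
}

# Keys cubic convolution kernel, a = -0.5 (the common bicubic default)
keys_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# target x source interpolation matrix for one axis (edge-replicated)
bicubic_matrix <- function(src, target) {
  A <- matrix(0, target, src)
  for (i in seq_len(target)) {
    x <- (i - 0.5) * src / target + 0.5       # continuous source coordinate
    base <- floor(x)
    taps <- (base - 1):(base + 2)
    w <- keys_kernel(x - taps)
    taps <- pmin(pmax(taps, 1), src)          # replicate edges
    for (k in seq_along(taps)) A[i, taps[k]] <- A[i, taps[k]] + w[k]
  }
  A
}

#' Bicubic resize of a square slice image
#'
#' Separable cubic convolution with the Keys `a = -0.5` kernel and
#' edge replication; exact identity when `target_size` equals the input size.
#'
#' @param image square numeric matrix.
#' @param target_size output pixels per side.
#' @return `target_size x target_size` matrix.
#' @export
resize_bicubic <- function(image, target_size) {
  if (nrow(image) != ncol(image)) stop_dim("resize_bicubic expects a square image")
  s <- nrow(image)
  if (target_size == s) return(image)
  if (target_size > s)
    message("resize_bicubic: upsampling from ", s, " to ", target_size)
  A <- bicubic_matrix(s, target_size)
  A %*% image %*% t(A)
}

#' Min-max scale a volume into [0, 1]
#'
#' The minimum and maximum are taken over the whole case volume (all slices),
#' not per slice, so one examinee's tissue maps to consistent gray levels.
#' A constant volume maps to all zeros with a warning.
#'
#' @param volume an `exam_volume` (any real-valued intensities).
#' @return the volume with slices rescaled into `[0, 1]`.
#' @export
minmax_scale <- function(volume) {
  stopifnot(inherits(volume, "exam_volume"))
  if (length(volume$slices) == 0L) stop_dim("empty volume")
  lo <- min(vapply(volume$slices, min, 0))
  hi <- max(vapply(volume$slices, max, 0))
  if (hi == lo) {
    warning("constant volume: min-max scaling maps all pixels to 0")
    volume$slices <- lapply(volume$slices, function(x) x * 0)
  } else {
    volume$slices <- lapply(volume$slices, function(x) (x - lo) / (hi - lo))
  }
  volume
}

#' Sixfold cross-validation split over normal cases
#'
#' Normal cases are shuffled and divided into six near-equal subsets (sizes
#' differing by at most one). Fold `k` tests on subset `k`, validates on
#' subset `(k + 1) mod 6`, and trains on the remaining four; every abnormal
#' case is attached to every fold's test set and never appears in training or
#' validation.
#'
#' @param normal_case_ids,abnormal_case_ids character/integer id vectors.
#' @param seed integer seed for the shuffle.
#' @return list of 6 `fold_assignment` objects with elements `fold_id`
#'   (0-based), `train_case_ids`, `validation_case_ids`, `test_case_ids`
#'   (normal test subset) and `abnormal_case_ids`.
#' @export
sixfold_split <- function(normal_case_ids, abnormal_case_ids = character(),
                          seed = 1L) {
  n <- length(normal_case_ids)
  if (n < 6) stop("need at least 6 normal cases for a sixfold split",
                  call. = FALSE)
  ids <- with_seed(seed, sample(normal_case_ids))
  sizes <- rep(n %/% 6L, 6L)
  if (n %% 6L > 0) sizes[seq_len(n %% 6L)] <- sizes[seq_len(n %% 6L)] + 1L
  subset_of <- rep(seq_len(6L), times = sizes)
  subsets <- split(ids, subset_of)
  lapply(0:5, function(k) {
    test_s <- k + 1L
    val_s <- (k + 1L) %% 6L + 1L
    train_s <- setdiff(seq_len(6L), c(test_s, val_s))
    structure(list(fold_id = k,
                   train_case_ids = unname(unlist(subsets[train_s])),
                   validation_case_ids = subsets[[val_s]],
                   test_case_ids = subsets[[test_s]],
                   abnormal_case_ids = abnormal_case_ids),
              class = "fold_assignment")
  })
}

#' Serialize fold assignments to JSON
#' @param folds result of [sixfold_split()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_folds <- function(folds, path) {
  jsonlite::write_json(lapply(folds, unclass), path, auto_unbox = FALSE)
  invisible(path)
}

#' Read fold assignments from JSON
#' @param path file written by [write_folds()].
#' @return list of `fold_assignment` objects.
#' @export
read_folds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(f) {
    structure(list(fold_id = as.integer(f$fold_id[[1]]),
                   train_case_ids = unlist(f$train_case_ids),
                   validation_case_ids = unlist(f$validation_case_ids),
                   test_case_ids = unlist(f$test_case_ids),
                   abnormal_case_ids = unlist(f$abnormal_case_ids)),
              class = "fold_assignment")
  })
}
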