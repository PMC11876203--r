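#' Configuration for the synthetic chest-phantom generator
#'
#' The generator emulates the structural statistics the anomaly-detection
#' method relies on: every examinee shares the same gross anatomy (elliptical
#' body wall enclosing two darker lung fields) while fine bright structures
#' (vessel-like curvilinear segments and dots) vary from slice to slice and
#' from case to case.
#'
#' @param image_size pixels per side of each square slice (>= 32). Default 64,
#'   the scaled-down benchmark size; use 256 for full-scale runs.
#' @param slices_min,slices_max inclusive range for the number of slices per
#'   case (clinical chest series run 72-124 slices; the default 8-12 keeps
#'   desk-scale benchmarks fast).
#' @param body_intensity,lung_intensity,vessel_intensity mean grayscale levels
#'   in `[0, 1]` of the body wall, lung fields and vessel structures.
#' @param vessel_count number of vessel-like structures drawn per slice.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (clamped back into `[0, 1]`).
#' @param seed integer seed; together with a case index it fully determines a
#'   volume, so datasets are reproducible and order-independent.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64, slices_min = 8, slices_max = 12,
                           body_intensity = 0.6, lung_intensity = 0.2,
                           vessel_intensity = 0.5, vessel_count = 5,
                           noise_sd = 0.02, seed = 1L) {
  if (image_size < 32) stop("image_size must be >= 32", call. = FALSE)
  if (slices_min < 1 || slices_max < slices_min)
    stop("invalid slices_per_case range", call. = FALSE)
  ints <- c(body_intensity, lung_intensity, vessel_intensity)
  if (any(ints < 0 | ints > 1))
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 slices_min = as.integer(slices_min),
                 slices_max = as.integer(slices_max),
                 body_intensity = body_intensity,
                 lung_intensity = lung_intensity,
                 vessel_intensity = vessel_intensity,
                 vessel_count = as.integer(vessel_count),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Specification of an injected lung anomaly
#'
#' Three kinds mirror the gross appearance of intrapulmonary disease:
#' `"nodule"` (compact bright blob, e.g. a tumour), `"consolidation"`
#' (larger diffuse brightening with an irregular margin, e.g. pneumonia) and
#' `"void"` (structure-free dark patch, e.g. emphysematous destruction, which
#' must darken: `intensity_delta < 0`).
#'
#' @param kind one of `"nodule"`, `"consolidation"`, `"void"`.
#' @param radius_px anomaly radius in pixels (>= 1).
#' @param intensity_delta signed grayscale shift applied inside the lesion.
#' @param n_slices_affected number of contiguous slices carrying the lesion.
#' @return an object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(kind = c("nodule", "consolidation", "void"),
                         radius_px = 6, intensity_delta = 0.4,
                         n_slices_affected = 3) {
  kind <- match.arg(kind)
  if (radius_px < 1) stop("radius_px must be >= 1", call. = FALSE)
  if (n_slices_affected < 1)
    stop("n_slices_affected must be >= 1", call. = FALSE)
  if (kind == "void" && intensity_delta >= 0)
    stop("void anomalies must have negative intensity_delta", call. = FALSE)
  structure(list(kind = kind, radius_px = radius_px,
                 intensity_delta = intensity_delta,
                 n_slices_affected = as.integer(n_slices_affected)),
            class = "anomaly_spec")
}

new_exam_volume <- function(case_id, slices, label, anomaly_masks,
                            flags, layout) {
  structure(list(case_id = case_id, slices = slices, label = label,
                 anomaly_masks = anomaly_masks,
                 anomaly_slice_flags = flags, layout = layout),
            class = "exam_volume")
}

#' @export
print.exam_volume <- function(x, ...) {
  cat(sprintf("<exam_volume %s: %d slices of %dx%d, label=%s, %d flagged>\n",
              x$case_id, length(x$slices), nrow(x$slices[[1]]),
              ncol(x$slices[[1]]), x$label, sum(x$anomaly_slice_flags)))
  invisible(x)
}

# elliptical mask on an s x s grid; cx, cy, a, b in pixel units
ellipse_mask <- function(s, cx, cy, a, b) {
  xs <- matrix(seq_len(s), s, s)             # row coordinate
  ys <- matrix(seq_len(s), s, s, byrow = TRUE)
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

# splat a small gaussian bump of given amplitude centred at (ci, cj)
splat_blob <- function(img, ci, cj, amp, sigma) {
  s <- nrow(img)
  r <- max(1L, ceiling(2.5 * sigma))
  i <- max(1L, ci - r):min(s, ci + r)
  j <- max(1L, cj - r):min(s, cj + r)
  d2 <- outer((i - ci)^2, (j - cj)^2, "+")
  img[i, j] <- img[i, j] + amp * exp(-d2 / (2 * sigma^2))
  img
}

# Case-level geometry shared by all slices of one examinee, including the
# vascular tree: each lung gets a hilum (medial anchor) and a fan of
# case-seeded branch angles/curvatures/reaches. Vessels are therefore
# consistent anatomy that varies smoothly from slice to slice - the
# statistical regularity a one-class reconstruction model relies on -
# rather than per-slice noise.
phantom_layout <- function(config) {
  s <- config$image_size
  jit <- function(x, f) x * (1 + runif(1, -f, f))
  cx <- s / 2 + runif(1, -0.02, 0.02) * s
  cy <- s / 2 + runif(1, -0.02, 0.02) * s
  nv <- config$vessel_count
  # Even angular fan with jitter, and fixed (permuted) reach/width ladders:
  # cases differ in vessel arrangement but carry a comparable vascular load,
  # like real parenchyma. Fully random fans make some cases much harder to
  # reconstruct than others, which no one-class model should have to absorb.
  vessels <- lapply(c(-1, 1), function(side) {
    base <- seq(0, 2 * pi, length.out = nv + 1L)[seq_len(nv)]
    list(side = side,
         angles = base + runif(nv, -0.15, 0.15),
         curv = runif(nv, -0.08, 0.08),
         reach = sample(seq(0.4, 0.95, length.out = nv)),
         width = sample(seq(1.1, 1.6, length.out = nv)))
  })
  list(s = s, cx = cx, cy = cy,
       body_a = jit(0.40 * s, 0.015), body_b = jit(0.46 * s, 0.015),
       lung_a = jit(0.22 * s, 0.03), lung_b = jit(0.14 * s, 0.03),
       lung_off = jit(0.19 * s, 0.02), vessels = vessels)
}

# slice-position modulation of lung size: lungs taper towards apex/base
lung_scale <- function(t) 0.55 + 0.45 * sqrt(pmax(0, 1 - (2 * t - 1)^2))

phantom_slice_masks <- function(lay, t) {
  f <- lung_scale(t)
  body <- ellipse_mask(lay$s, lay$cx, lay$cy, lay$body_a, lay$body_b)
  lungL <- ellipse_mask(lay$s, lay$cx, lay$cy - lay$lung_off,
                        f * lay$lung_a, f * lay$lung_b)
  lungR <- ellipse_mask(lay$s, lay$cx, lay$cy + lay$lung_off,
                        f * lay$lung_a, f * lay$lung_b)
  list(body = body, lung = (lungL | lungR) & body)
}

# Render the case's vascular tree on one slice. Branches radiate from the
# hilum along case-fixed angles; their reach scales with the slice's lung
# size, and a small per-slice angular wobble keeps slices from being
# identical without making the pattern unpredictable.
draw_vessels <- function(img, lung, lay, t, config, scale = 1) {
  amp <- config$vessel_intensity - config$lung_intensity
  f <- lung_scale(t)
  step <- 0.8 * scale
  for (vt in lay$vessels) {
    hil_i <- lay$cx
    hil_j <- lay$cy + vt$side * lay$lung_off * 0.45
    for (v in seq_along(vt$angles)) {
      ang <- vt$angles[v] + runif(1, -0.05, 0.05)
      # branch length scales with the lung's elliptical radius along the
      # branch direction, so every case carries a comparable vascular load
      r_theta <- 1 / sqrt((cos(ang) / lay$lung_a)^2 + (sin(ang) / lay$lung_b)^2)
      reach_px <- vt$reach[v] * f * r_theta * 1.6
      steps <- max(3L, ceiling(reach_px / step))
      ci <- hil_i; cj <- hil_j
      for (k in seq_len(steps)) {
        ci <- ci + step * cos(ang); cj <- cj + step * sin(ang)
        ang <- ang + vt$curv[v] / steps
        ii <- round(ci); jj <- round(cj)
        if (ii < 1 || ii > lay$s || jj < 1 || jj > lay$s) break
        if (lung[ii, jj]) {
          sig <- vt$width[v] * (1 - 0.4 * k / steps)   # taper outward
          img <- splat_blob(img, ii, jj, amp, sigma = sig * scale)
        }
      }
    }
  }
  img
}

#' Generate one normal synthetic examinee volume
#'
#' Deterministic in `(config$seed, case_index)`: the same pair always yields a
#' bit-identical volume, independent of calls made before or after.
#'
#' @param config a [phantom_config()].
#' @param case_index nonnegative integer identifying the case.
#' @return an `exam_volume` with `label = "normal"`, empty anomaly masks, and
#'   a `layout` element holding the generator's own body/lung masks per slice.
#' @export
generate_normal_volume <- function(config, case_index = 0L) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(mix_seed(config$seed, case_index), {
    rng <- config$slices_min:config$slices_max
    n <- if (length(rng) == 1L) rng else sample(rng, 1L)
    lay <- phantom_layout(config)
    slices <- vector("list", n)
    lungs <- vector("list", n)
    bodies <- vector("list", n)
    # slices are rendered at 2x resolution and average-pooled down, giving
    # the softened edges of resampled CT rather than razor-sharp masks
    lay2 <- lay
    for (f in c("s", "cx", "cy", "body_a", "body_b", "lung_a", "lung_b",
                "lung_off"))
      lay2[[f]] <- lay[[f]] * 2
    amp <- config$vessel_intensity - config$lung_intensity
    for (k in seq_len(n)) {
      t <- (k - 0.5) / n
      m <- phantom_slice_masks(lay, t)
      m2 <- phantom_slice_masks(lay2, t)
      base2 <- matrix(0, 2L * config$image_size, 2L * config$image_size)
      base2[m2$body] <- config$body_intensity
      base2[m2$lung] <- config$lung_intensity
      ves2 <- draw_vessels(base2 * 0, m2$lung, lay2, t, config, scale = 2)
      ves <- pool2(ves2)
      # normalize the slice's vascular energy to a target proportional to
      # lung area: every examinee carries the same vascular load per unit
      # lung, as in real parenchyma; arrangements still differ per case
      e <- sum(ves[m$lung]^2)
      target <- 0.5 * amp^2 * sum(m$lung)
      if (e > 0) ves <- ves * min(1.6, max(0.6, sqrt(target / e)))
      img <- pool2(base2) + ves +
        matrix(rnorm(config$image_size^2, 0, config$noise_sd),
               config$image_size, config$image_size)
      slices[[k]] <- clamp01(img)
      lungs[[k]] <- m$lung
      bodies[[k]] <- m$body
    }
    empty <- lapply(slices, function(x) matrix(0L, nrow(x), ncol(x)))
    new_exam_volume(sprintf("case_%04d", case_index), slices, "normal",
                    empty, rep(FALSE, n),
                    layout = list(lung = lungs, body = bodies))
  })
}

# Lesion footprint and intensity profile; mask is the lesion core (d <= r).
# Nodules are spiculated and internally textured, consolidations irregular
# and streaky: localized high-frequency structure absent from normal
# anatomy, which a model trained on normals cannot restore. Voids are
# handled separately (flat replacement in inject_anomaly).
lesion_region <- function(s, ci, cj, r, kind) {
  xs <- matrix(seq_len(s), s, s)
  ys <- matrix(seq_len(s), s, s, byrow = TRUE)
  th <- atan2(ys - cj, xs - ci)
  d <- sqrt((xs - ci)^2 + (ys - cj)^2)
  if (kind == "consolidation") {        # irregular margin
    r_eff <- r * (1 + 0.25 * sin(3 * th + runif(1, 0, 2 * pi)) +
                    0.15 * sin(5 * th + runif(1, 0, 2 * pi)))
  } else r_eff <- r
  mask <- d <= r_eff
  prof <- switch(kind,
    nodule = {
      core <- pmax(0, 1 - (d / r)^2)
      spang <- runif(7L, 0, 2 * pi)
      spic <- 0
      for (a in spang) {                 # spicule rays beyond the core
        ang_d <- abs(((th - a + pi) %% (2 * pi)) - pi)
        spic <- spic + exp(-(ang_d / 0.12)^2) *
          exp(-((d - r) / (0.6 * r))^2) * (d > 0.6 * r) * (d < 1.9 * r)
      }
      tex <- matrix(runif(s * s, 0.55, 1.45), s, s)   # internal texture
      p <- pmin(core * tex + 0.8 * pmin(spic, 1), 1.2)
      mask <- mask | (p > 0.12)
      p
    },
    consolidation = {
      streak <- 0.6 + 0.4 * sin(2 * pi * d / max(2, r / 1.5)) *
        matrix(runif(s * s, 0.3, 1), s, s)
      mask * pmax(0.35, 1 - 0.3 * (d / pmax(r_eff, 1))^2) * streak
    },
    void = mask * 1)
  list(mask = mask, profile = prof * if (kind == "nodule") 1 else mask)
}

#' Inject a localized anomaly into a normal volume
#'
#' Places the lesion at a random position that fits entirely inside a lung
#' field, on `spec$n_slices_affected` contiguous slices (radius tapered
#' towards the first/last affected slice). Nodules and consolidations add
#' `intensity_delta`; voids additionally flatten local structure, emulating
#' the structureless black regions of destroyed parenchyma.
#'
#' @param volume a normal `exam_volume` from [generate_normal_volume()].
#' @param spec an [anomaly_spec()].
#' @param seed integer seed controlling placement.
#' @return a new `exam_volume` with `label = "abnormal"`, per-slice masks and
#'   flags set on exactly the affected slices.
#' @export
inject_anomaly <- function(volume, spec, seed = 1L) {
  stopifnot(inherits(volume, "exam_volume"), inherits(spec, "anomaly_spec"))
  if (volume$label != "normal")
    stop("inject_anomaly expects a normal source volume", call. = FALSE)
  n <- length(volume$slices)
  k <- min(spec$n_slices_affected, n)
  if (spec$n_slices_affected > n)
    stop("n_slices_affected exceeds the number of slices", call. = FALSE)
  with_seed(seed, {
    r <- spec$radius_px
    s <- nrow(volume$slices[[1]])
    ok <- NULL; first <- NA_integer_
    # sample a contiguous slice window, then a centre whose full lesion disc
    # fits inside that window's central lung field; retry other windows if
    # the lung there is too small (apex/base slices)
    for (wtry in seq_len(10L)) {
      first <- sample.int(n - k + 1L, 1L)
      mid <- first + (k - 1L) %/% 2L
      lung <- volume$layout$lung[[mid]]
      cand <- which(lung, arr.ind = TRUE)
      if (nrow(cand) == 0L) next
      for (try in seq_len(200L)) {
        p <- cand[sample.int(nrow(cand), 1L), ]
        if (p[1] - r < 1 || p[1] + r > s || p[2] - r < 1 || p[2] + r > s) next
        ii <- (p[1] - r):(p[1] + r)
        jj <- (p[2] - r):(p[2] + r)
        disc <- outer((ii - p[1])^2, (jj - p[2])^2, "+") <= r^2
        if (all(lung[ii, jj][disc])) { ok <- p; break }
      }
      if (!is.null(ok)) break
    }
    if (is.null(ok))
      stop("anomaly does not fit inside the lung field", call. = FALSE)
    out <- volume
    out$label <- "abnormal"
    taper <- if (k == 1L) 1 else 0.7 + 0.3 *
      (1 - abs(seq_len(k) - (k + 1) / 2) / ((k + 1) / 2))
    for (z in seq_len(k)) {
      sl <- first + z - 1L
      reg <- lesion_region(s, ok[1], ok[2], max(1, r * taper[z]), spec$kind)
      img <- out$slices[[sl]]
      if (spec$kind == "void") {
        # structure-free: replace content with a flat dark level
        base <- mean(img[reg$mask])
        img[reg$mask] <- clamp01(base + spec$intensity_delta +
                                   rnorm(sum(reg$mask), 0, 0.004))
      } else {
        img <- clamp01(img + spec$intensity_delta * reg$profile)
      }
      out$slices[[sl]] <- img
      out$anomaly_masks[[sl]] <- matrix(as.integer(reg$mask), s, s)
      out$anomaly_slice_flags[sl] <- TRUE
    }
    out
  })
}

#' Generate a labelled synthetic dataset
#'
#' Normal cases use indices `0 .. n_normal-1`; abnormal cases are fresh normal
#' volumes (indices `n_normal ..`) with anomalies injected, cycling through
#' `anomaly_specs`. Fully determined by `config$seed`.
#'
#' @param config a [phantom_config()].
#' @param n_normal,n_abnormal case counts (>= 0).
#' @param anomaly_specs list of [anomaly_spec()] objects; required when
#'   `n_abnormal > 0`.
#' @return list of `exam_volume` objects, normals first.
#' @export
generate_dataset <- function(config, n_normal, n_abnormal,
                             anomaly_specs = list()) {
  stopifnot(n_normal >= 0, n_abnormal >= 0)
  if (n_abnormal > 0 && length(anomaly_specs) == 0L)
    stop("anomaly_specs must be nonempty when n_abnormal > 0", call. = FALSE)
  vols <- vector("list", n_normal + n_abnormal)
  for (i in seq_len(n_normal))
    vols[[i]] <- generate_normal_volume(config, i - 1L)
  for (i in seq_len(n_abnormal)) {
    idx <- n_normal + i - 1L
    base <- generate_normal_volume(config, idx)
    spec <- anomaly_specs[[(i - 1L) %% length(anomaly_specs) + 1L]]
    v <- inject_anomaly(base, spec, seed = mix_seed(config$seed, idx, 1L))
    v$case_id <- sprintf("case_%04d_%s", idx, spec$kind)
    vols[[n_normal + i]] <- v
  }
  vols
}
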