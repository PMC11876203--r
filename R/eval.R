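#' Per-slice anomaly score
#'
#' `S(x) = ||x - xhat||^2 + ||z(x) - c||^2`: squared reconstruction error
#' plus squared distance of the Encoder-2 latent from the hypersphere
#' center, summed with unit weights. `svdd_weight` is exposed because the
#' relative weighting of the two terms is a natural tuning knob (default 1).
#'
#' @param x,xhat input and reconstructed slice matrices.
#' @param z latent vector of the slice.
#' @param center hypersphere center vector.
#' @param svdd_weight weight on the hypersphere-distance term.
#' @return list with `recon_term`, `svdd_term`, `total`.
#' @export
anomaly_score <- function(x, xhat, z, center, svdd_weight = 1) {
  if (!identical(dim(x), dim(xhat))) stop_dim("image shapes differ")
  if (length(z) != length(center)) stop_dim("latent/center lengths differ")
  recon <- sum((x - xhat)^2)
  svdd <- svdd_weight * sum((as.numeric(z) - as.numeric(center))^2)
  list(recon_term = recon, svdd_term = svdd, total = recon + svdd)
}

#' Representative score of an examinee
#'
#' The maximum slice-level anomaly score within one examinee's volume.
#'
#' @param scores numeric vector of per-slice total scores (nonempty).
#' @return scalar maximum.
#' @export
representative_score <- function(scores) {
  if (length(scores) == 0L) stop("empty score list", call. = FALSE)
  max(scores)
}

#' Score all slices of a set of volumes with a trained model
#'
#' @param fit a `vq_svdd_fit` from [train_vq_svdd()].
#' @param volumes list of `exam_volume`s.
#' @param batch_size forward-pass batch size.
#' @param svdd_weight weight on the hypersphere term (see [anomaly_score()]).
#' @return data frame with columns `case_id`, `slice_index`, `label`,
#'   `flag`, `recon_term`, `svdd_term`, `total`.
#' @export
score_volumes <- function(fit, volumes, batch_size = 64L, svdd_weight = 1) {
  stopifnot(inherits(fit, "vq_svdd_fit"))
  st <- slices_tensor(volumes)
  n <- dim(st$x)[4]
  recon <- numeric(n); svdd <- numeric(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    bundle <- vq_forward(fit$model, st$x[, , , b, drop = FALSE])
    dx <- (st$x[, , , b, drop = FALSE] - bundle$xhat)^2
    recon[b] <- apply(dx, 4, sum)
    svdd[b] <- svdd_weight * colSums((bundle$z - fit$sphere$center)^2)
  }
  cbind(st$info, recon_term = recon, svdd_term = svdd, total = recon + svdd)
}

#' Score volumes with the VAE baseline
#'
#' The baseline has no hypersphere; its slice score is the squared
#' reconstruction error (posterior-mean reconstruction, no sampling).
#'
#' @param fit a `vae_fit` from [train_vae()].
#' @inheritParams score_volumes
#' @return data frame as in [score_volumes()] (with `svdd_term = 0`).
#' @export
score_volumes_vae <- function(fit, volumes, batch_size = 64L) {
  stopifnot(inherits(fit, "vae_fit"))
  st <- slices_tensor(volumes)
  n <- dim(st$x)[4]
  recon <- numeric(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- vae_forward(fit$model, st$x[, , , b, drop = FALSE], sample = FALSE)
    dx <- (st$x[, , , b, drop = FALSE] - fw$xhat)^2
    recon[b] <- apply(dx, 4, sum)
  }
  cbind(st$info, recon_term = recon, svdd_term = 0, total = recon)
}

#' Per-examinee representative scores
#'
#' @param slice_scores data frame from [score_volumes()].
#' @return data frame with one row per case: `case_id`, `label`, `score`.
#' @export
representative_scores <- function(slice_scores) {
  agg <- aggregate(total ~ case_id + label, data = slice_scores, FUN = max)
  data.frame(case_id = agg$case_id, label = agg$label, score = agg$total)
}

#' ROC curve and AUC for representative scores
#'
#' AUC by the trapezoidal rule over the empirical ROC (equivalently the
#' Mann-Whitney statistic with half credit for ties); abnormal is the
#' positive class and higher scores mean more abnormal.
#'
#' @param scores numeric vector of per-case scores.
#' @param labels logical (or `"normal"`/`"abnormal"`) per-case labels.
#' @return list with `auc` and `curve` (data frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "abnormal"
  if (length(unique(pos)) < 2L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- pROC::roc(response = pos, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  list(auc = as.numeric(pROC::auc(r)), curve = curve)
}

#' Youden-index threshold and operating point
#'
#' Scans the midpoints between consecutive distinct sorted scores (plus one
#' cut above the maximum, i.e. "call everything normal") and returns the
#' threshold maximizing `J = sensitivity + specificity - 1`. A case is
#' called abnormal when its score is strictly greater than the threshold.
#' Ties in J are broken toward higher specificity (fewer false alarms among
#' the many normals in a screening population).
#'
#' @inheritParams roc_auc
#' @return list with `threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `youden`.
#' @export
youden_threshold <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "abnormal"
  if (length(unique(pos)) < 2L)
    stop("threshold undefined: both classes must be present", call. = FALSE)
  s <- sort(unique(scores))
  cand <- c((head(s, -1) + tail(s, -1)) / 2, max(s) + 1)
  best <- NULL
  for (th in cand) {
    pred <- scores > th
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    J <- sens + spec - 1
    if (is.null(best) || J > best$youden + 1e-12 ||
        (abs(J - best$youden) <= 1e-12 && spec > best$specificity)) {
      best <- list(threshold = th, sensitivity = sens, specificity = spec,
                   accuracy = mean(pred == pos), youden = J)
    }
  }
  best
}

#' Reconstruction-fidelity comparison between normal and abnormal slices
#'
#' The normal group pools all slices of normal cases; the abnormal group
#' pools only the flagged (lesion-carrying) slices of abnormal cases.
#' Unflagged slices of abnormal cases belong to neither group.
#'
#' @param volumes list of `exam_volume`s with slice flags.
#' @param reconstruct either a fitted model (`vq_svdd_fit`/`vae_fit`) or a
#'   function mapping a slice matrix to its reconstruction.
#' @return list with `per_slice` (data frame of per-slice metrics and group)
#'   and `summary` (mean and SD of rmse/psnr/ssim per group).
#' @export
fidelity_comparison <- function(volumes, reconstruct) {
  fn <- reconstruct_fn(reconstruct)
  rows <- list()
  for (v in volumes) {
    for (k in seq_along(v$slices)) {
      group <- if (v$label == "normal") "normal"
               else if (v$anomaly_slice_flags[k]) "abnormal" else NA
      if (is.na(group)) next
      x <- v$slices[[k]]
      f <- fidelity(x, fn(x))
      rows[[length(rows) + 1L]] <- data.frame(case_id = v$case_id,
                                              slice_index = k, group = group,
                                              rmse = f$rmse, psnr = f$psnr,
                                              ssim = f$ssim)
    }
  }
  per_slice <- do.call(rbind, rows)
  if (!any(per_slice$group == "abnormal"))
    warning("no abnormal slices: abnormal group is empty")
  summ <- do.call(rbind, lapply(split(per_slice, per_slice$group), function(d)
    data.frame(group = d$group[1], n_slices = nrow(d),
               rmse_mean = mean(d$rmse), rmse_sd = sd(d$rmse),
               psnr_mean = mean(d$psnr[is.finite(d$psnr)]),
               psnr_sd = sd(d$psnr[is.finite(d$psnr)]),
               ssim_mean = mean(d$ssim), ssim_sd = sd(d$ssim))))
  rownames(summ) <- NULL
  list(per_slice = per_slice, summary = summ)
}

reconstruct_fn <- function(reconstruct) {
  if (is.function(reconstruct)) return(reconstruct)
  if (inherits(reconstruct, "vq_svdd_fit"))
    return(function(x) drop(vq_forward(reconstruct$model, x)$xhat))
  if (inherits(reconstruct, "vae_fit"))
    return(function(x) drop(vae_forward(reconstruct$model, x)$xhat))
  stop("reconstruct must be a fitted model or a function", call. = FALSE)
}

#' Evaluate one fold: representative-score metrics for a test set
#'
#' Scores the test volumes, takes per-case representative scores, and
#' reports AUC plus the in-sample Youden operating point (the threshold is
#' fit on the same test scores it classifies, mirroring screening-study
#' practice; interpret accuracy/sensitivity/specificity accordingly).
#'
#' @param fit a `vq_svdd_fit` or `vae_fit`.
#' @param volumes test `exam_volume`s (both classes present).
#' @param svdd_weight weight on the hypersphere term (proposed model only).
#' @return one-row data frame: `accuracy`, `sensitivity`, `specificity`,
#'   `auc`, `threshold`.
#' @export
evaluate_fold <- function(fit, volumes, svdd_weight = 1) {
  sc <- if (inherits(fit, "vae_fit")) score_volumes_vae(fit, volumes)
        else score_volumes(fit, volumes, svdd_weight = svdd_weight)
  rep <- representative_scores(sc)
  roc <- roc_auc(rep$score, rep$label)
  yj <- youden_threshold(rep$score, rep$label)
  data.frame(accuracy = yj$accuracy, sensitivity = yj$sensitivity,
             specificity = yj$specificity, auc = roc$auc,
             threshold = yj$threshold)
}

#' Cross-validation report with paired tests
#'
#' Aggregates per-fold metrics of the proposed model and a comparator:
#' across-fold mean and SD per metric, and a two-sided paired t-test
#' (`df = folds - 1`) on the per-fold metric pairs.
#'
#' @param metrics_proposed,metrics_comparator data frames with one row per
#'   fold and identical metric columns (e.g. from [evaluate_fold()]).
#' @param metrics which columns to aggregate and test.
#' @return an `eval_report`: list with `summary` (per model/metric mean, sd)
#'   and `paired_tests` (metric, t, df, p_value, mean_difference).
#' @export
evaluate_cv <- function(metrics_proposed, metrics_comparator,
                        metrics = c("accuracy", "sensitivity",
                                    "specificity", "auc")) {
  if (nrow(metrics_proposed) != nrow(metrics_comparator))
    stop("fold-count mismatch between models", call. = FALSE)
  summ <- do.call(rbind, lapply(metrics, function(m)
    data.frame(metric = m,
               proposed_mean = mean(metrics_proposed[[m]]),
               proposed_sd = sd(metrics_proposed[[m]]),
               comparator_mean = mean(metrics_comparator[[m]]),
               comparator_sd = sd(metrics_comparator[[m]]))))
  tests <- do.call(rbind, lapply(metrics, function(m) {
    d <- metrics_proposed[[m]] - metrics_comparator[[m]]
    if (all(d == 0)) {
      data.frame(metric = m, t = 0, df = length(d) - 1L, p_value = 1,
                 mean_difference = 0)
    } else {
      tt <- t.test(metrics_proposed[[m]], metrics_comparator[[m]],
                   paired = TRUE)
      data.frame(metric = m, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 mean_difference = unname(tt$estimate))
    }
  }))
  structure(list(summary = summ, paired_tests = tests), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\nPer-model summary:\n")
  print(x$summary, row.names = FALSE)
  cat("Paired t-tests (proposed vs comparator):\n")
  print(x$paired_tests, row.names = FALSE)
  invisible(x)
}
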