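test_that("anomaly score decomposes into its two terms", {
  x <- matrix(runif(16), 4)
  s0 <- anomaly_score(x, x, c(1, 2), c(1, 2))
  expect_equal(s0$total, 0)
  s <- anomaly_score(x, x + 0.25, c(0, 0), c(0.5, sqrt(0.5)))
  expect_equal(s$recon_term, 16 * 0.0625)
  expect_equal(s$svdd_term, 0.75)
  expect_equal(s$total, s$recon_term + s$svdd_term)
  # increasing any pixel's |x - xhat| strictly increases the score
  xh <- x; xh[2, 2] <- xh[2, 2] + 0.3
  expect_gt(anomaly_score(x, xh, c(1), c(1))$total,
            anomaly_score(x, x, c(1), c(1))$total)
  expect_error(anomaly_score(x, matrix(0, 2, 2), 1, 1), "shapes")
  expect_error(anomaly_score(x, x, c(1, 2), 1), "lengths")
})

test_that("the representative score is the order-invariant slice maximum", {
  expect_equal(representative_score(c(0.1, 0.9, 0.4)), 0.9)
  expect_equal(representative_score(0.7), 0.7)
  set.seed(1)
  v <- runif(20)
  expect_equal(representative_score(sample(v)), representative_score(v))
  expect_error(representative_score(numeric(0)), "empty")
})

test_that("AUC matches the pairwise-concordance oracle and is rank-invariant", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.9), c(FALSE, FALSE, TRUE))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.2, 0.1), c(FALSE, FALSE, TRUE))$auc, 0)
  mw_oracle <- function(scores, pos) {
    ps <- scores[pos]; ns <- scores[!pos]
    conc <- 0
    for (a in ps) for (b in ns)
      conc <- conc + (a > b) + 0.5 * (a == b)
    conc / (length(ps) * length(ns))
  }
  for (s in 1:5) {
    set.seed(s)
    scores <- round(runif(20), 1)          # rounding forces ties
    pos <- runif(20) > 0.5
    if (length(unique(pos)) < 2) next
    r <- roc_auc(scores, pos)
    expect_equal(r$auc, mw_oracle(scores, pos), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(roc_auc(exp(3 * scores), pos)$auc, r$auc, tolerance = 1e-12)
    expect_true(all(diff(r$curve$fpr) >= 0))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("Youden threshold matches an exhaustive scan and its own operating point", {
  y <- youden_threshold(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_gt(y$threshold, 2); expect_lt(y$threshold, 3)
  expect_equal(y$accuracy, 1)
  expect_equal(y$youden, 1)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  scan_oracle <- function(scores, pos) {
    cand <- sort(unique(scores))
    cand <- c((head(cand, -1) + tail(cand, -1)) / 2, max(cand) + 1)
    max(sapply(cand, function(th) {
      mean(scores[pos] > th) + mean(scores[!pos] <= th) - 1
    }))
  }
  for (s in 1:5) {
    set.seed(10 + s)
    scores <- rnorm(30) + ifelse(runif(30) > 0.5, 0.8, 0)
    pos <- c(rep(TRUE, 15), rep(FALSE, 15))
    yt <- youden_threshold(scores, pos)
    expect_equal(yt$youden, scan_oracle(scores, pos), tolerance = 1e-12)
    # the returned threshold reproduces the returned operating point exactly
    pred <- scores > yt$threshold
    expect_equal(sum(pred & pos) / sum(pos), yt$sensitivity)
    expect_equal(sum(!pred & !pos) / sum(!pos), yt$specificity)
    expect_equal(mean(pred == pos), yt$accuracy)
  }
})

test_that("fidelity comparison groups slices by the flag rule", {
  cfg <- phantom_config(image_size = 32, slices_min = 10, slices_max = 10,
                        vessel_count = 3, seed = 6)
  vn <- generate_normal_volume(cfg, 0)
  va <- inject_anomaly(generate_normal_volume(cfg, 1),
                       anomaly_spec("nodule", 4, 0.4, 3), seed = 2)
  fc <- fidelity_comparison(list(vn, va), function(x) x)   # identity model
  expect_equal(sum(fc$per_slice$group == "abnormal"), 3L)
  expect_equal(sum(fc$per_slice$group == "normal"), 10L)   # all normal slices
  expect_true(all(fc$per_slice$rmse == 0))
  expect_true(all(fc$per_slice$ssim == 1))
  expect_warning(fidelity_comparison(list(vn), function(x) x), "empty")
})

test_that("cross-validation report aggregates folds with paired t-tests", {
  m <- data.frame(accuracy = c(0.7, 0.72, 0.69, 0.71, 0.7, 0.73),
                  sensitivity = 0.6, specificity = 0.8,
                  auc = c(0.75, 0.77, 0.74, 0.76, 0.75, 0.78))
  same <- evaluate_cv(m, m)
  expect_true(all(same$paired_tests$t == 0))
  expect_true(all(same$paired_tests$p_value == 1))
  expect_true(all(same$paired_tests$df == 5))
  # hand-computed 3-pair toy: differences (1, 2, 3) -> t = 2 sqrt(3)
  a <- data.frame(accuracy = c(2, 4, 6), sensitivity = 1, specificity = 1,
                  auc = 0.5)
  b <- data.frame(accuracy = c(1, 2, 3), sensitivity = 1, specificity = 1,
                  auc = 0.5)
  r <- evaluate_cv(a, b, metrics = "accuracy")
  expect_equal(r$paired_tests$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r$paired_tests$p_value, 2 * pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-9)
  expect_equal(r$summary$proposed_mean, 4)
  expect_error(evaluate_cv(m, m[1:3, ]), "mismatch")
})
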