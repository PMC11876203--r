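# Independent brute-force oracles used by the unit and acceptance tests.
# Each is a direct transcription of the defining formula, kept free of any
# code path it is used to check.

# multi-scale similarity: per-window moments by explicit loops, components
# averaged per scale, luminance at the coarsest scale only
naive_ms_ssim <- function(x, y, M, win_len, d1 = 1e-4, d2 = 9e-4,
                          d3 = 4.5e-4) {
  pool <- function(m) {
    h <- nrow(m) %/% 2L; w <- ncol(m) %/% 2L
    out <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w))
      out[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    out
  }
  acc <- 1
  for (j in 0:M) {
    s <- nrow(x); P <- s - win_len + 1L
    L <- C <- S <- 0
    for (p in seq_len(P)) for (q in seq_len(P)) {
      wx <- x[p:(p + win_len - 1L), q:(q + win_len - 1L)]
      wy <- y[p:(p + win_len - 1L), q:(q + win_len - 1L)]
      mx <- mean(wx); my <- mean(wy)
      vx <- mean(wx^2) - mx^2; vy <- mean(wy^2) - my^2
      cxy <- mean(wx * wy) - mx * my
      sx <- sqrt(max(vx, 0)); sy <- sqrt(max(vy, 0))
      L <- L + (2 * mx * my + d1) / (mx^2 + my^2 + d1)
      C <- C + (2 * sx * sy + d2) / (vx + vy + d2)
      S <- S + (2 * cxy + d3) / (2 * sx * sy + d3)
    }
    acc <- acc * (C / P^2) * (S / P^2)
    if (j == M) acc <- acc * (L / P^2)
    x <- pool(x); y <- pool(y)
  }
  acc
}

# Mann-Whitney pairwise concordance with half credit for ties
mw_auc_oracle <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  conc <- 0
  for (a in ps) for (b in ns) conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(ps) * length(ns))
}

# exhaustive Youden scan over midpoints of consecutive distinct scores
youden_scan_oracle <- function(scores, pos) {
  cand <- sort(unique(scores))
  cand <- c((head(cand, -1) + tail(cand, -1)) / 2, max(cand) + 1)
  max(sapply(cand, function(th) {
    mean(scores[pos] > th) + mean(scores[!pos] <= th) - 1
  }))
}

# nearest codebook row by explicit per-row distance
nn_quantize_oracle <- function(v, E) {
  d <- apply(E, 1, function(e) sum((v - e)^2))
  which.min(d)
}
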