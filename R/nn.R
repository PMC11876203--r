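# Minimal CNN machinery: 4D tensors are R arrays (H, W, C, N). Convolutions
# are im2col + BLAS matmul; transposed convolutions reuse the same machinery
# with the roles of forward and backward-data swapped. Everything here has a
# hand-derived backward pass; gradient-routing tests audit them by finite
# differences.

act_fwd <- function(x, act) {
  switch(act, none = x, relu = pmax(x, 0), sigmoid = 1 / (1 + exp(-x)))
}

# dy * act'(pre); `post` is the activation output (used for sigmoid)
act_bwd <- function(dy, pre, post, act) {
  switch(act, none = dy, relu = dy * (pre > 0), sigmoid = dy * post * (1 - post))
}

conv_out_side <- function(s, k, stride, pad) (s + 2 * pad - k) %/% stride + 1L

conv_fwd_raw <- function(x, W, b, stride, pad) {
  d <- dim(x); kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[4]
  Ho <- conv_out_side(d[1], kh, stride, pad)
  Wo <- conv_out_side(d[2], kw, stride, pad)
  cols <- im2col_cpp(x, kh, kw, stride, pad)
  Wmat <- matrix(W, ncol = cout)
  ymat <- crossprod(Wmat, cols) + b
  y <- aperm(array(ymat, c(cout, Ho, Wo, d[4])), c(2, 3, 1, 4))
  list(y = y, cols = cols, xdim = d)
}

conv_bwd_raw <- function(dy, cache, W, stride, pad) {
  d <- cache$xdim; kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[4]
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = cout)
  dW <- array(cache$cols %*% t(dym), dim = dim(W))
  db <- rowSums(dym)
  Wmat <- matrix(W, ncol = cout)
  dx <- col2im_cpp(Wmat %*% dym, d[1], d[2], d[3], d[4], kh, kw, stride, pad)
  list(dx = dx, dW = dW, db = db)
}

# transposed convolution: weight array (kh, kw, Cout, Cin)
deconv_fwd_raw <- function(x, W, b, stride, pad) {
  d <- dim(x); kh <- dim(W)[1]; kw <- dim(W)[2]
  cout <- dim(W)[3]; cin <- dim(W)[4]
  Ho <- (d[1] - 1L) * stride - 2L * pad + kh
  Wo <- (d[2] - 1L) * stride - 2L * pad + kw
  xmat <- matrix(aperm(x, c(3, 1, 2, 4)), nrow = cin)
  Wmat <- matrix(W, ncol = cin)
  y <- col2im_cpp(Wmat %*% xmat, Ho, Wo, cout, d[4], kh, kw, stride, pad)
  bb <- array(rep(b, each = Ho * Wo), c(Ho, Wo, cout))
  list(y = y + as.vector(bb), xmat = xmat, xdim = d, odim = c(Ho, Wo, cout, d[4]))
}

deconv_bwd_raw <- function(dy, cache, W, stride, pad) {
  kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[3]; cin <- dim(W)[4]
  d <- cache$xdim
  dcols <- im2col_cpp(dy, kh, kw, stride, pad)
  Wmat <- matrix(W, ncol = cin)
  dxmat <- crossprod(Wmat, dcols)
  dx <- aperm(array(dxmat, c(cin, d[1], d[2], d[4])), c(2, 3, 1, 4))
  dW <- array(dcols %*% t(cache$xmat), dim = dim(W))
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = cout)
  list(dx = dx, dW = dW, db = rowSums(dym))
}

# ---- layer specs ----------------------------------------------------------

nn_conv <- function(cin, cout, k = 4L, stride = 2L, pad = 1L, act = "relu")
  list(type = "conv", cin = cin, cout = cout, k = k, stride = stride,
       pad = pad, act = act)
nn_deconv <- function(cin, cout, k = 4L, stride = 2L, pad = 1L, act = "relu")
  list(type = "deconv", cin = cin, cout = cout, k = k, stride = stride,
       pad = pad, act = act)
nn_res <- function(ch) list(type = "res", ch = ch)
nn_flatten <- function() list(type = "flatten")
nn_unflatten <- function(H, W, C) list(type = "unflatten", H = H, W = W, C = C)
nn_linear <- function(din, dout, act = "none")
  list(type = "linear", din = din, dout = dout, act = act)

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

layer_init <- function(sp) {
  switch(sp$type,
    conv = list(W = he_init(c(sp$k, sp$k, sp$cin, sp$cout), sp$k^2 * sp$cin),
                b = numeric(sp$cout)),
    deconv = list(W = he_init(c(sp$k, sp$k, sp$cout, sp$cin), sp$k^2 * sp$cin),
                  b = numeric(sp$cout)),
    res = list(c1 = list(W = he_init(c(3, 3, sp$ch, sp$ch), 9 * sp$ch),
                         b = numeric(sp$ch)),
               c2 = list(W = he_init(c(3, 3, sp$ch, sp$ch), 9 * sp$ch),
                         b = numeric(sp$ch))),
    linear = list(W = he_init(c(sp$dout, sp$din), sp$din),
                  b = numeric(sp$dout)),
    flatten = list(),
    unflatten = list())
}

layer_fwd <- function(sp, par, x) {
  switch(sp$type,
    conv = {
      r <- conv_fwd_raw(x, par$W, par$b, sp$stride, sp$pad)
      y <- act_fwd(r$y, sp$act)
      list(y = y, cache = list(r = r, pre = r$y, post = y))
    },
    deconv = {
      r <- deconv_fwd_raw(x, par$W, par$b, sp$stride, sp$pad)
      y <- act_fwd(r$y, sp$act)
      list(y = y, cache = list(r = r, pre = r$y, post = y))
    },
    res = {
      h1 <- pmax(x, 0)
      r1 <- conv_fwd_raw(h1, par$c1$W, par$c1$b, 1L, 1L)
      h2 <- pmax(r1$y, 0)
      r2 <- conv_fwd_raw(h2, par$c2$W, par$c2$b, 1L, 1L)
      list(y = x + r2$y, cache = list(x = x, r1 = r1, r2 = r2, h2pre = r1$y))
    },
    flatten = list(y = matrix(x, ncol = dim(x)[4]), cache = list(d = dim(x))),
    unflatten = list(y = array(x, c(sp$H, sp$W, sp$C, ncol(x))), cache = NULL),
    linear = {
      pre <- par$W %*% x + par$b
      y <- act_fwd(pre, sp$act)
      list(y = y, cache = list(x = x, pre = pre, post = y))
    })
}

layer_bwd <- function(sp, par, cache, dy) {
  switch(sp$type,
    conv = {
      dpre <- act_bwd(dy, cache$pre, cache$post, sp$act)
      g <- conv_bwd_raw(dpre, cache$r, par$W, sp$stride, sp$pad)
      list(dx = g$dx, grad = list(W = g$dW, b = g$db))
    },
    deconv = {
      dpre <- act_bwd(dy, cache$pre, cache$post, sp$act)
      g <- deconv_bwd_raw(dpre, cache$r, par$W, sp$stride, sp$pad)
      list(dx = g$dx, grad = list(W = g$dW, b = g$db))
    },
    res = {
      g2 <- conv_bwd_raw(dy, cache$r2, par$c2$W, 1L, 1L)
      dh2 <- g2$dx * (cache$h2pre > 0)
      g1 <- conv_bwd_raw(dh2, cache$r1, par$c1$W, 1L, 1L)
      dx <- dy + g1$dx * (cache$x > 0)
      list(dx = dx, grad = list(c1 = list(W = g1$dW, b = g1$db),
                                c2 = list(W = g2$dW, b = g2$db)))
    },
    flatten = list(dx = array(dy, cache$d), grad = list()),
    unflatten = list(dx = matrix(dy, ncol = dim(dy)[4]), grad = list()),
    linear = {
      dpre <- act_bwd(dy, cache$pre, cache$post, sp$act)
      list(dx = crossprod(par$W, dpre),
           grad = list(W = tcrossprod(dpre, cache$x), b = rowSums(dpre)))
    })
}

seq_init <- function(specs) lapply(specs, layer_init)

seq_fwd <- function(specs, params, x, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(specs)) else NULL
  for (i in seq_along(specs)) {
    r <- layer_fwd(specs[[i]], params[[i]], x)
    x <- r$y
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

seq_bwd <- function(specs, params, caches, dy) {
  grads <- vector("list", length(specs))
  for (i in rev(seq_along(specs))) {
    r <- layer_bwd(specs[[i]], params[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[[i]] <- r$grad
  }
  list(dx = dy, grads = grads)
}

# ---- parameter-tree utilities and Adam ------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros <- function(a) {
  if (is.list(a)) lapply(a, tree_zeros) else a * 0
}

adam_init <- function(params) list(m = tree_zeros(params),
                                   v = tree_zeros(params), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - u, params, upd)
  list(params = params, state = state)
}
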