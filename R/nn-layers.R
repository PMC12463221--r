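# Internal neural-network primitives.
#
# All internal activations are stored as dense arrays with layout
# [H, W, B, C] (height, width, batch, channel).  Channel-last makes every
# channel mixing a single matrix multiply on the (H*W*B) x C flattening,
# which is where almost all of the arithmetic lives.  Convolutions are
# evaluated as k*k shifted GEMMs, transposed convolutions as 4 scatter
# GEMMs; no im2col buffer is ever materialised.
#
# Every *_fwd returns list(y, cache); the matching *_bwd consumes the
# cache and the upstream gradient and returns gradients with respect to
# input and parameters.  Gradients are validated against central finite
# differences in the test suite.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# ---- small helpers ---------------------------------------------------------

fg_zeros <- function(...) array(0, dim = c(...))

# broadcast a per-channel vector over [H,W,B,C]
bc_channel <- function(v, d) rep(v, each = prod(d[1:3]))

# convert [C,H,W] (public layout) -> [H,W,1,C] (internal) and back
chw_to_hwbc <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(2L, 3L, 1L))
  dim(y) <- c(d[2], d[3], 1L, d[1])
  y
}

hwbc_to_chw <- function(x) {
  d <- dim(x)
  stopifnot(d[3] == 1L)
  dim(x) <- c(d[1], d[2], d[4])
  aperm(x, c(3L, 1L, 2L))
}

# [B,C,H,W] -> [H,W,B,C]
bchw_to_hwbc <- function(x) aperm(x, c(3L, 4L, 1L, 2L))
hwbc_to_bchw <- function(x) aperm(x, c(3L, 4L, 1L, 2L))

fg_pad2 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- fg_zeros(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4])
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

# ---- parameter initialisation ----------------------------------------------

# Conv kernels: He normal, sd = sqrt(2 / fan_in); fully connected layers
# (stored as 1x1 convs): Xavier uniform.  `scheme` is recorded so that
# init_weights() can re-draw with the right law.
init_conv <- function(k, c_in, c_out, scheme = c("he", "xavier"), bias = TRUE) {
  scheme <- match.arg(scheme)
  p <- list(
    w = array(0, dim = c(k, k, c_in, c_out)),
    b = if (bias) numeric(c_out) else NULL
  )
  attr(p, "scheme") <- scheme
  attr(p, "fans") <- c(k * k * c_in, k * k * c_out)
  class(p) <- "fg_conv_params"
  draw_conv(p)
}

draw_conv <- function(p) {
  fans <- attr(p, "fans")
  if (attr(p, "scheme") == "he") {
    p$w[] <- stats::rnorm(length(p$w), sd = sqrt(2 / fans[1]))
  } else {
    a <- sqrt(6 / (fans[1] + fans[2]))
    p$w[] <- stats::runif(length(p$w), -a, a)
  }
  if (!is.null(p$b)) p$b[] <- 0
  p
}

init_bn <- function(c_out) {
  p <- list(
    gamma = rep(1, c_out), beta = numeric(c_out),
    run_mean = numeric(c_out), run_var = rep(1, c_out)
  )
  class(p) <- "fg_bn_params"
  p
}

# ---- convolution ------------------------------------------------------------

# Convolution via im2col: one GEMM on the (n x k^2*C_in) patch matrix.
# A 1x1 stride-1 convolution short-circuits to a plain matrix multiply
# (this is the hot path of the ST-MLP / attention projections).
nn_conv_fwd <- function(x, p, stride = 1L, pad = NULL) {
  d <- dim(x)
  k <- dim(p$w)[1]
  c_in <- dim(p$w)[3]; c_out <- dim(p$w)[4]
  if (d[4] != c_in)
    stop(sprintf("conv: input has %d channels, block expects %d", d[4], c_in))
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  n_in <- prod(d[1:3])
  if (k == 1L && stride == 1L) {
    s <- x; dim(s) <- c(n_in, c_in)
    wm <- p$w; dim(wm) <- c(c_in, c_out)
    out <- s %*% wm
    if (!is.null(p$b)) out <- out + rep(p$b, each = n_in)
    dim(out) <- c(d[1], d[2], d[3], c_out)
    return(list(y = out, cache = list(cols = s, p = p, k1 = TRUE,
                                      in_dim = d, out_dim = dim(out))))
  }
  xp <- fg_pad2(x, pad)
  dp <- dim(xp)
  ho <- (dp[1] - k) %/% stride + 1L
  wo <- (dp[2] - k) %/% stride + 1L
  n <- ho * wo * d[3]
  cols <- matrix(0, n, k * k * c_in)
  blk <- 0L
  for (di in seq_len(k)) {
    ri <- di + stride * (seq_len(ho) - 1L)
    for (dj in seq_len(k)) {
      rj <- dj + stride * (seq_len(wo) - 1L)
      s <- xp[ri, rj, , , drop = FALSE]
      cols[, blk + seq_len(c_in)] <- s
      blk <- blk + c_in
    }
  }
  # rows of wm follow the same (di, dj) block order with channel fastest
  wm <- aperm(p$w, c(3L, 2L, 1L, 4L))
  dim(wm) <- c(k * k * c_in, c_out)
  out <- cols %*% wm
  if (!is.null(p$b)) out <- out + rep(p$b, each = n)
  dim(out) <- c(ho, wo, d[3], c_out)
  list(y = out, cache = list(cols = cols, p = p, stride = stride, pad = pad,
                             k1 = FALSE, in_dim = d, out_dim = dim(out)))
}

nn_conv_bwd <- function(dy, cache) {
  p <- cache$p
  k <- dim(p$w)[1]; c_in <- dim(p$w)[3]; c_out <- dim(p$w)[4]
  od <- cache$out_dim
  n <- od[1] * od[2] * od[3]
  g <- dy; dim(g) <- c(n, c_out)
  db <- if (is.null(p$b)) NULL else colSums(g)
  if (cache$k1) {
    wm <- p$w; dim(wm) <- c(c_in, c_out)
    dw <- crossprod(cache$cols, g)
    dim(dw) <- dim(p$w)
    dx <- g %*% t(wm)
    dim(dx) <- cache$in_dim
    return(list(dx = dx, dp = list(w = dw, b = db)))
  }
  stride <- cache$stride; pad <- cache$pad
  dwm <- crossprod(cache$cols, g)        # (k^2*c_in) x c_out
  dim(dwm) <- c(c_in, k, k, c_out)       # channel fastest, then dj, di
  dw <- aperm(dwm, c(3L, 2L, 1L, 4L))
  wm <- aperm(p$w, c(3L, 2L, 1L, 4L))
  dim(wm) <- c(k * k * c_in, c_out)
  gw <- g %*% t(wm)                      # n x (k^2*c_in)
  d <- cache$in_dim
  gxp <- fg_zeros(d[1] + 2L * pad, d[2] + 2L * pad, d[3], c_in)
  blk <- 0L
  for (di in seq_len(k)) {
    ri <- di + stride * (seq_len(od[1]) - 1L)
    for (dj in seq_len(k)) {
      rj <- dj + stride * (seq_len(od[2]) - 1L)
      gi <- gw[, blk + seq_len(c_in)]
      dim(gi) <- c(od[1], od[2], od[3], c_in)
      gxp[ri, rj, , ] <- gxp[ri, rj, , , drop = FALSE] + gi
      blk <- blk + c_in
    }
  }
  dx <- gxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, dp = list(w = dw, b = db))
}

# ---- transposed convolution (2x2 kernel, stride 2) --------------------------

nn_tconv_fwd <- function(x, p) {
  d <- dim(x)
  c_in <- dim(p$w)[3]; c_out <- dim(p$w)[4]
  if (d[4] != c_in)
    stop(sprintf("tconv: input has %d channels, block expects %d", d[4], c_in))
  n <- d[1] * d[2] * d[3]
  xm <- x; dim(xm) <- c(n, c_in)
  y <- fg_zeros(2L * d[1], 2L * d[2], d[3], c_out)
  for (di in 1:2) {
    ri <- 2L * seq_len(d[1]) - 2L + di
    for (dj in 1:2) {
      rj <- 2L * seq_len(d[2]) - 2L + dj
      o <- xm %*% matrix(p$w[di, dj, , ], c_in, c_out)
      dim(o) <- c(d[1], d[2], d[3], c_out)
      y[ri, rj, , ] <- o
    }
  }
  y <- y + bc_channel(p$b, dim(y))
  list(y = y, cache = list(x = x, p = p))
}

nn_tconv_bwd <- function(dy, cache) {
  x <- cache$x; p <- cache$p
  d <- dim(x)
  c_in <- dim(p$w)[3]; c_out <- dim(p$w)[4]
  n <- d[1] * d[2] * d[3]
  xm <- x; dim(xm) <- c(n, c_in)
  dw <- array(0, dim = dim(p$w))
  dxm <- matrix(0, n, c_in)
  for (di in 1:2) {
    ri <- 2L * seq_len(d[1]) - 2L + di
    for (dj in 1:2) {
      rj <- 2L * seq_len(d[2]) - 2L + dj
      g <- dy[ri, rj, , , drop = FALSE]
      dim(g) <- c(n, c_out)
      dw[di, dj, , ] <- crossprod(xm, g)
      dxm <- dxm + g %*% t(matrix(p$w[di, dj, , ], c_in, c_out))
    }
  }
  gd <- dim(dy)
  gm <- dy; dim(gm) <- c(prod(gd[1:3]), c_out)
  db <- colSums(gm)
  dim(dxm) <- d
  list(dx = dxm, dp = list(w = dw, b = db))
}

# ---- batch normalisation ----------------------------------------------------

# Train mode uses biased batch statistics over (H, W, B); running stats are
# EMA-updated with unbiased variance.  Eval mode normalises with running
# statistics.  The running-stat update is returned in the cache (the caller
# decides whether to commit it, so pure forward passes stay side-effect free).
nn_bn_fwd <- function(x, p, train = FALSE) {
  d <- dim(x)
  n <- prod(d[1:3])
  xm <- x; dim(xm) <- c(n, d[4])
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + .bn_eps)
    xhat <- xc * rep(inv, each = n)
    run_mean <- (1 - .bn_momentum) * p$run_mean + .bn_momentum * mu
    vu <- if (n > 1) v * n / (n - 1) else v
    run_var <- (1 - .bn_momentum) * p$run_var + .bn_momentum * vu
  } else {
    inv <- 1 / sqrt(p$run_var + .bn_eps)
    xhat <- (xm - rep(p$run_mean, each = n)) * rep(inv, each = n)
    run_mean <- p$run_mean; run_var <- p$run_var
  }
  y <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
  dim(y) <- d
  list(y = y,
       cache = list(xhat = xhat, inv = inv, p = p, d = d, n = n, train = train),
       run_mean = run_mean, run_var = run_var)
}

nn_bn_bwd <- function(dy, cache) {
  d <- cache$d; n <- cache$n
  g <- dy; dim(g) <- c(n, d[4])
  dgamma <- colSums(g * cache$xhat)
  dbeta <- colSums(g)
  dxhat <- g * rep(cache$p$gamma, each = n)
  if (cache$train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dxm <- (dxhat - rep(s1 / n, each = n) -
              cache$xhat * rep(s2 / n, each = n)) * rep(cache$inv, each = n)
  } else {
    dxm <- dxhat * rep(cache$inv, each = n)
  }
  dim(dxm) <- d
  list(dx = dxm, dp = list(gamma = dgamma, beta = dbeta,
                           run_mean = NULL, run_var = NULL))
}

# ---- pointwise nonlinearities ----------------------------------------------

nn_relu_fwd <- function(x) {
  y <- x * (x > 0)
  list(y = y, cache = x > 0)
}
nn_relu_bwd <- function(dy, cache) dy * cache

fg_sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- pooling ----------------------------------------------------------------

# global (spatial) average/max pooling: [H,W,B,C] -> B x C matrices
nn_gap_fwd <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  y <- matrix(colMeans(xm), d[3], d[4])
  list(y = y, cache = d)
}
nn_gap_bwd <- function(dy, d) {
  g <- rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2])
  dim(g) <- d
  g
}

nn_gmp_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- x; dim(xm) <- c(hw, d[3] * d[4])
  idx <- max.col(t(xm), ties.method = "first")
  y <- matrix(xm[(seq_along(idx) - 1L) * hw + idx], d[3], d[4])
  list(y = y, cache = list(idx = idx, d = d))
}
nn_gmp_bwd <- function(dy, cache) {
  d <- cache$d; hw <- d[1] * d[2]
  g <- numeric(prod(d))
  g[(seq_along(cache$idx) - 1L) * hw + cache$idx] <- as.vector(dy)
  dim(g) <- d
  g
}

# channel-wise average/max pooling: [H,W,B,C] -> [H,W,B,1]
nn_cap_fwd <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
  y <- rowMeans(xm)
  dim(y) <- c(d[1], d[2], d[3], 1L)
  list(y = y, cache = d)
}
nn_cap_bwd <- function(dy, d) {
  g <- rep(as.vector(dy) / d[4], d[4])
  dim(g) <- d
  g
}

nn_cmp_fwd <- function(x) {
  d <- dim(x)
  n <- prod(d[1:3])
  xm <- x; dim(xm) <- c(n, d[4])
  j <- max.col(xm, ties.method = "first")
  y <- xm[cbind(seq_len(n), j)]
  dim(y) <- c(d[1], d[2], d[3], 1L)
  list(y = y, cache = list(j = j, d = d))
}
nn_cmp_bwd <- function(dy, cache) {
  d <- cache$d; n <- prod(d[1:3])
  g <- matrix(0, n, d[4])
  g[cbind(seq_len(n), cache$j)] <- as.vector(dy)
  dim(g) <- d
  g
}

# ---- channel concat / split -------------------------------------------------

nn_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- fg_zeros(da[1], da[2], da[3], da[4] + db[4])
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  y
}

nn_split <- function(g, c_a) {
  d <- dim(g)
  list(a = g[, , , seq_len(c_a), drop = FALSE],
       b = g[, , , c_a + seq_len(d[4] - c_a), drop = FALSE])
}
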