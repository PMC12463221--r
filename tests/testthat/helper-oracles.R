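# Straight-line scalar re-implementations of every block's defining
# arithmetic, written with plain loops and independent of the package's
# vectorised code paths.  All oracles operate on [C, H, W] arrays.

o_sigmoid <- function(x) 1 / (1 + exp(-x))

# 2-D convolution, nested loops; w: [k,k,cin,cout], b: length cout
oracle_conv <- function(x, w, b, stride = 1L, pad = 1L) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  k <- dim(w)[1]; cout <- dim(w)[4]
  ho <- (H + 2 * pad - k) %/% stride + 1L
  wo <- (W + 2 * pad - k) %/% stride + 1L
  out <- array(0, c(cout, ho, wo))
  for (co in seq_len(cout)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- b[co]
    for (ci in seq_len(C)) for (di in seq_len(k)) for (dj in seq_len(k)) {
      si <- (i - 1L) * stride + di - pad
      sj <- (j - 1L) * stride + dj - pad
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        acc <- acc + x[ci, si, sj] * w[di, dj, ci, co]
    }
    out[co, i, j] <- acc
  }
  out
}

# batch norm in eval mode (running statistics), scalar loop
oracle_bn_eval <- function(x, gamma, beta, rm, rv, eps = 1e-5) {
  out <- x
  for (c in seq_len(dim(x)[1]))
    out[c, , ] <- gamma[c] * (x[c, , ] - rm[c]) / sqrt(rv[c] + eps) + beta[c]
  out
}

oracle_relu <- function(x) {
  x[x < 0] <- 0
  x
}

# full conv block: conv -> BN(eval) -> ReLU
oracle_conv_block <- function(x, block, stride) {
  p <- block$params
  y <- oracle_conv(x, p$conv$w, p$conv$b, stride = stride, pad = 1L)
  y <- oracle_bn_eval(y, p$bn$gamma, p$bn$beta, p$bn$run_mean, p$bn$run_var)
  oracle_relu(y)
}

# token shift, scalar loop over every target position
oracle_shift <- function(x, axis, groups, offsets) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  out <- array(0, dim(x))
  for (g in seq_along(groups)) {
    o <- offsets[g]
    for (ch in groups[[g]]) for (i in seq_len(H)) for (j in seq_len(W)) {
      if (axis == "height") {
        si <- i - o
        if (si >= 1 && si <= H) out[ch, i, j] <- x[ch, si, j]
      } else {
        sj <- j - o
        if (sj >= 1 && sj <= W) out[ch, i, j] <- x[ch, i, sj]
      }
    }
  }
  out
}

# position-wise two-layer channel MLP: FC(C->hid) -> ReLU -> FC(hid->C)
oracle_channel_mlp <- function(v, w1, b1, w2, b2) {
  hid <- length(b1)
  h <- numeric(hid)
  for (k in seq_len(hid)) h[k] <- max(0, sum(v * w1[, k]) + b1[k])
  out <- numeric(length(b2))
  for (c in seq_along(b2)) out[c] <- sum(h * w2[, c]) + b2[c]
  out
}

oracle_stmlp <- function(x, block) {
  p <- block$params; cfg <- block$config
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  groups <- focusgate:::shift_groups(C, cfg$spec_h$n_groups)
  sh <- oracle_shift(x, "height", groups, cfg$spec_h$offsets)
  sw <- oracle_shift(x, "width", groups, cfg$spec_w$offsets)
  out <- array(0, dim(x))
  w <- function(q) matrix(q$w, dim(q$w)[3], dim(q$w)[4])
  for (i in seq_len(H)) for (j in seq_len(W)) {
    mh <- oracle_channel_mlp(sh[, i, j], w(p$fc1h), p$fc1h$b,
                             w(p$fc2h), p$fc2h$b)
    mw <- oracle_channel_mlp(sw[, i, j], w(p$fc1w), p$fc1w$b,
                             w(p$fc2w), p$fc2w$b)
    out[, i, j] <- mh + mw + x[, i, j]
  }
  out
}

oracle_channel_attention <- function(x, block) {
  p <- block$params
  C <- dim(x)[1]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(x[c, , ])
    mx[c] <- max(x[c, , ])
  }
  w <- function(q) matrix(q$w, dim(q$w)[3], dim(q$w)[4])
  fa <- oracle_channel_mlp(avg, w(p$ca_fc1), p$ca_fc1$b,
                           w(p$ca_fc2), p$ca_fc2$b)
  fm <- oracle_channel_mlp(mx, w(p$ca_fc1), p$ca_fc1$b,
                           w(p$ca_fc2), p$ca_fc2$b)
  o_sigmoid(fa + fm)
}

oracle_spatial_attention <- function(x, block) {
  p <- block$params
  H <- dim(x)[2]; W <- dim(x)[3]
  pooled <- array(0, c(2, H, W))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    pooled[1, i, j] <- mean(x[, i, j])
    pooled[2, i, j] <- max(x[, i, j])
  }
  logits <- oracle_conv(pooled, p$sa_conv$w, p$sa_conv$b,
                        stride = 1L, pad = 3L)
  o_sigmoid(logits[1, , ])
}

oracle_cbam <- function(x, block) {
  mc <- oracle_channel_attention(x, block)
  f1 <- x
  for (c in seq_len(dim(x)[1])) f1[c, , ] <- x[c, , ] * mc[c]
  ms <- oracle_spatial_attention(f1, block)
  f2 <- f1
  for (c in seq_len(dim(x)[1])) f2[c, , ] <- f1[c, , ] * ms
  f2
}

oracle_attention_gate <- function(x, g, block) {
  p <- block$params
  H <- dim(x)[2]; W <- dim(x)[3]
  w <- function(q) matrix(q$w, dim(q$w)[3], dim(q$w)[4])
  psi <- array(0, c(1, H, W))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ax <- as.vector(t(w(p$phi_x)) %*% x[, i, j]) + p$phi_x$b
    ag <- as.vector(t(w(p$phi_g)) %*% g[, i, j]) + p$phi_g$b
    s <- pmax(ax + ag, 0)
    psi[1, i, j] <- sum(s * w(p$psi)[, 1]) + p$psi$b
  }
  psi <- oracle_bn_eval(psi, p$bn$gamma, p$bn$beta, p$bn$run_mean,
                        p$bn$run_var)
  alpha <- o_sigmoid(psi[1, , ])
  out <- x
  for (c in seq_len(dim(x)[1])) out[c, , ] <- x[c, , ] * alpha
  out
}

# random small feature map
rand_fm <- function(C, H, W) array(stats::rnorm(C * H * W), c(C, H, W))

# random preprocessed pair for trainer-level tests
rand_pair <- function(size = 32L, seed = 1L) {
  set.seed(seed)
  list(x = array(stats::rnorm(3 * size * size), c(3, size, size)),
       y = matrix((stats::runif(size * size) > 0.5) * 1, size, size),
       id = paste0("r", seed))
}
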