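#' @title Learned building blocks
#' @description
#' The four learned blocks of the network — convolutional block, Shifted
#' Token MLP (ST-MLP), Convolutional Block Attention Module (CBAM) and
#' Attention Gate (AG) — exposed as standalone, individually testable
#' operations on feature maps.
#'
#' A *feature map* is a plain numeric array indexed `[channel, height,
#' width]`. Blocks are created with [new_block()] and applied with
#' [conv_block()], [stmlp_block()], [cbam()], [attention_gate()] and
#' friends. All operations run in evaluation mode by default (batch norm
#' uses its running statistics), which at identity initialisation makes a
#' batch-norm layer numerically transparent up to the stabilising epsilon.
#' @name blocks
NULL

as_feature_map <- function(x) {
  if (is.matrix(x)) dim(x) <- c(1L, dim(x))
  stopifnot(is.numeric(x), length(dim(x)) == 3L, all(is.finite(x)))
  x
}

# ---- token shifting ---------------------------------------------------------

#' Shift specification for the ST-MLP token shift
#'
#' Channels are partitioned into `n_groups` contiguous, near-equal groups
#' (remainder channels go to the last group); group `k` is translated by
#' `offsets[k]` pixels along `axis`, vacated positions are zero-filled and
#' nothing wraps around.
#'
#' @param axis `"height"` or `"width"`.
#' @param n_groups number of contiguous channel groups.
#' @param offsets integer displacements in pixels, one per group. The
#'   default `-2:2` follows the shifted-MLP convention of symmetric
#'   single-step shifts around an unshifted centre group.
#' @return an object of class `shift_spec`.
#' @export
shift_spec <- function(axis = c("height", "width"), n_groups = 5L,
                       offsets = -2:2) {
  axis <- match.arg(axis)
  n_groups <- as.integer(n_groups)
  offsets <- as.integer(offsets)
  stopifnot(n_groups >= 1L, length(offsets) == n_groups)
  structure(list(axis = axis, n_groups = n_groups, offsets = offsets),
            class = "shift_spec")
}

# contiguous near-equal channel partition; remainder -> last group
shift_groups <- function(n_channels, n_groups) {
  base <- n_channels %/% n_groups
  sizes <- rep(base, n_groups)
  sizes[n_groups] <- sizes[n_groups] + n_channels %% n_groups
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_len(n_groups), function(g) {
    if (sizes[g] == 0L) integer(0) else starts[g]:ends[g]
  })
}

# internal: x is [H,W,B,C]
nn_shift_fwd <- function(x, spec) {
  d <- dim(x)
  ext <- if (spec$axis == "height") d[1] else d[2]
  if (any(abs(spec$offsets) >= ext))
    stop("shift offset magnitude must be smaller than the spatial extent")
  groups <- shift_groups(d[4], spec$n_groups)
  y <- array(0, d)
  for (g in seq_along(groups)) {
    ch <- groups[[g]]
    if (length(ch) == 0L) next
    o <- spec$offsets[g]
    if (o == 0L) {
      y[, , , ch] <- x[, , , ch, drop = FALSE]
    } else if (spec$axis == "height") {
      if (o > 0L) y[(o + 1L):d[1], , , ch] <- x[1:(d[1] - o), , , ch, drop = FALSE]
      else        y[1:(d[1] + o), , , ch] <- x[(1L - o):d[1], , , ch, drop = FALSE]
    } else {
      if (o > 0L) y[, (o + 1L):d[2], , ch] <- x[, 1:(d[2] - o), , ch, drop = FALSE]
      else        y[, 1:(d[2] + o), , ch] <- x[, (1L - o):d[2], , ch, drop = FALSE]
    }
  }
  y
}

nn_shift_bwd <- function(dy, spec) {
  neg <- spec
  neg$offsets <- -spec$offsets
  nn_shift_fwd(dy, neg)
}

#' Shift channel groups of a feature map along one spatial axis
#'
#' @param input feature map array `[channels, height, width]`.
#' @param spec a [shift_spec()].
#' @return array of the same shape with channel groups translated and
#'   vacated positions zero-filled.
#' @examples
#' x <- array(1:18, c(2, 3, 3))
#' s <- shift_spec("height", 1, offsets = 1L)
#' shift_tokens(x, s)[1, , 1]  # (a, b, c) -> (0, a, b)
#' @export
shift_tokens <- function(input, spec) {
  input <- as_feature_map(input)
  stopifnot(inherits(spec, "shift_spec"))
  hwbc_to_chw(nn_shift_fwd(chw_to_hwbc(input), spec))
}

# ---- block constructors -----------------------------------------------------

#' Create a learned block
#'
#' Constructs one of the network's four learned blocks with freshly
#' initialised parameters (He for convolutions, Xavier for the MLP /
#' channel-attention projections, identity for batch norm).
#'
#' @param kind one of `"conv"`, `"stmlp"`, `"cbam"`, `"ag"`.
#' @param in_channels,out_channels,downsample conv block: channel
#'   configuration and whether the 3x3 convolution uses stride 2.
#' @param channels ST-MLP / CBAM: the number of input channels.
#' @param hidden_ratio ST-MLP: hidden width multiplier (hidden = ratio * C).
#' @param n_groups,offsets ST-MLP: token-shift grouping (see [shift_spec()]).
#' @param reduction CBAM: channel-attention bottleneck ratio `r`
#'   (bottleneck width `max(1, C %/% r)`).
#' @param x_channels,g_channels AG: channels of the skip feature `x` and
#'   gating signal `g`; the intermediate width is `max(1, x_channels %/% 2)`.
#' @param seed optional integer seed for reproducible initialisation.
#' @return an object of class `fg_block` with fields `block_kind`,
#'   `params`, `config` and `parameter_count`.
#' @export
new_block <- function(kind = c("conv", "stmlp", "cbam", "ag"),
                      in_channels = NULL, out_channels = NULL,
                      downsample = FALSE,
                      channels = NULL, hidden_ratio = 4L,
                      n_groups = 5L, offsets = -2:2,
                      reduction = 16L,
                      x_channels = NULL, g_channels = NULL,
                      seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  cfg <- switch(kind,
    conv = {
      stopifnot(!is.null(in_channels), !is.null(out_channels))
      list(in_channels = as.integer(in_channels),
           out_channels = as.integer(out_channels),
           downsample = isTRUE(downsample))
    },
    stmlp = {
      stopifnot(!is.null(channels))
      list(channels = as.integer(channels),
           hidden = as.integer(hidden_ratio) * as.integer(channels),
           spec_h = shift_spec("height", n_groups, offsets),
           spec_w = shift_spec("width", n_groups, offsets))
    },
    cbam = {
      stopifnot(!is.null(channels))
      list(channels = as.integer(channels),
           bottleneck = max(1L, as.integer(channels) %/% as.integer(reduction)))
    },
    ag = {
      stopifnot(!is.null(x_channels), !is.null(g_channels))
      list(x_channels = as.integer(x_channels),
           g_channels = as.integer(g_channels),
           int_channels = max(1L, as.integer(x_channels) %/% 2L))
    })
  params <- switch(kind,
    conv = list(conv = init_conv(3L, cfg$in_channels, cfg$out_channels, "he"),
                bn = init_bn(cfg$out_channels)),
    stmlp = list(
      fc1h = init_conv(1L, cfg$channels, cfg$hidden, "xavier"),
      fc2h = init_conv(1L, cfg$hidden, cfg$channels, "xavier"),
      fc1w = init_conv(1L, cfg$channels, cfg$hidden, "xavier"),
      fc2w = init_conv(1L, cfg$hidden, cfg$channels, "xavier")),
    cbam = list(
      ca_fc1 = init_conv(1L, cfg$channels, cfg$bottleneck, "xavier"),
      ca_fc2 = init_conv(1L, cfg$bottleneck, cfg$channels, "xavier"),
      sa_conv = init_conv(7L, 2L, 1L, "he")),
    ag = list(
      phi_x = init_conv(1L, cfg$x_channels, cfg$int_channels, "he"),
      phi_g = init_conv(1L, cfg$g_channels, cfg$int_channels, "he"),
      psi = init_conv(1L, cfg$int_channels, 1L, "he"),
      bn = init_bn(1L)))
  structure(list(block_kind = kind, params = params, config = cfg,
                 parameter_count = fg_count_params(params)),
            class = "fg_block")
}

#' @export
print.fg_block <- function(x, ...) {
  cat(sprintf("<fg_block %s> %d parameters\n", x$block_kind,
              x$parameter_count))
  invisible(x)
}

#' Number of trainable parameters of a block
#' @param block an `fg_block`.
#' @return integer count of trainable scalars (batch-norm running
#'   statistics excluded).
#' @export
block_parameter_count <- function(block) {
  stopifnot(inherits(block, "fg_block"))
  fg_count_params(block$params)
}

# ---- conv block -------------------------------------------------------------

# internal batched forward: Conv3x3 -> BN -> ReLU
cb_fwd <- function(x, p, cfg, train = FALSE) {
  stride <- if (cfg$downsample) 2L else 1L
  cv <- nn_conv_fwd(x, p$conv, stride = stride, pad = 1L)
  bn <- nn_bn_fwd(cv$y, p$bn, train = train)
  p$bn$run_mean <- bn$run_mean; p$bn$run_var <- bn$run_var
  rl <- nn_relu_fwd(bn$y)
  list(y = rl$y, p = p,
       cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache))
}

cb_bwd <- function(dy, cache) {
  d1 <- nn_relu_bwd(dy, cache$relu)
  b <- nn_bn_bwd(d1, cache$bn)
  c <- nn_conv_bwd(b$dx, cache$conv)
  list(dx = c$dx, dp = list(conv = c$dp, bn = b$dp))
}

#' Apply a convolutional block (3x3 conv + batch norm + ReLU)
#'
#' @param input feature map `[channels, height, width]`.
#' @param block an `fg_block` of kind `"conv"`.
#' @param train logical; use batch statistics (`TRUE`) or running
#'   statistics (`FALSE`, default) in the batch-norm layer.
#' @return feature map with `out_channels` channels; spatial dimensions
#'   are halved (stride-2, padding 1) when the block downsamples.
#' @export
conv_block <- function(input, block, train = FALSE) {
  stopifnot(inherits(block, "fg_block"), block$block_kind == "conv")
  input <- as_feature_map(input)
  if (dim(input)[1] != block$config$in_channels)
    stop(sprintf("conv_block: input has %d channels, block expects %d",
                 dim(input)[1], block$config$in_channels))
  out <- cb_fwd(chw_to_hwbc(input), block$params, block$config, train = train)
  hwbc_to_chw(out$y)
}

# ---- ST-MLP -----------------------------------------------------------------

# two-layer channel MLP as 1x1 projections: FC(C -> hC) -> ReLU -> FC(hC -> C)
stmlp_branch_fwd <- function(x, fc1, fc2, spec) {
  s <- nn_shift_fwd(x, spec)
  a1 <- nn_conv_fwd(s, fc1)
  r1 <- nn_relu_fwd(a1$y)
  a2 <- nn_conv_fwd(r1$y, fc2)
  list(y = a2$y, cache = list(a1 = a1$cache, r1 = r1$cache, a2 = a2$cache,
                              spec = spec))
}

stmlp_branch_bwd <- function(dy, cache) {
  b2 <- nn_conv_bwd(dy, cache$a2)
  dr <- nn_relu_bwd(b2$dx, cache$r1)
  b1 <- nn_conv_bwd(dr, cache$a1)
  list(dx = nn_shift_bwd(b1$dx, cache$spec), d_fc1 = b1$dp, d_fc2 = b2$dp)
}

# clamp shift offsets to the available extent (sign-preserving); only
# relevant for deep stages of very small inputs, where a +/-2 pixel shift
# would exceed the feature map
clamp_spec <- function(spec, extent) {
  spec$offsets <- pmin(pmax(spec$offsets, -(extent - 1L)), extent - 1L)
  spec
}

stmlp_fwd <- function(x, p, cfg) {
  d <- dim(x)
  spec_h <- clamp_spec(cfg$spec_h, d[1])
  spec_w <- clamp_spec(cfg$spec_w, d[2])
  h <- stmlp_branch_fwd(x, p$fc1h, p$fc2h, spec_h)
  w <- stmlp_branch_fwd(x, p$fc1w, p$fc2w, spec_w)
  list(y = h$y + w$y + x, cache = list(h = h$cache, w = w$cache))
}

stmlp_bwd <- function(dy, cache) {
  h <- stmlp_branch_bwd(dy, cache$h)
  w <- stmlp_branch_bwd(dy, cache$w)
  list(dx = dy + h$dx + w$dx,
       dp = list(fc1h = h$d_fc1, fc2h = h$d_fc2,
                 fc1w = w$d_fc1, fc2w = w$d_fc2))
}

#' Apply a Shifted Token MLP block
#'
#' Computes `MLP_h(Shift_h(z)) + MLP_w(Shift_w(z)) + z`, where each MLP is
#' a position-shared two-layer perceptron over channels (1x1 projections
#' `C -> hidden_ratio*C -> C` with a ReLU in between) and the shifts
#' translate contiguous channel groups along height and width.
#'
#' @inheritParams conv_block
#' @param block an `fg_block` of kind `"stmlp"`.
#' @return feature map of the same shape as `input`.
#' @export
stmlp_block <- function(input, block) {
  stopifnot(inherits(block, "fg_block"), block$block_kind == "stmlp")
  input <- as_feature_map(input)
  if (dim(input)[1] != block$config$channels)
    stop("stmlp_block: channel mismatch")
  hwbc_to_chw(stmlp_fwd(chw_to_hwbc(input), block$params, block$config)$y)
}

# ---- CBAM -------------------------------------------------------------------

# shared channel MLP applied to a pooled B x C matrix (as [1,1,B,C])
cbam_mlp_fwd <- function(v, p) {
  a1 <- nn_conv_fwd(v, p$ca_fc1)
  r1 <- nn_relu_fwd(a1$y)
  a2 <- nn_conv_fwd(r1$y, p$ca_fc2)
  list(y = a2$y, cache = list(a1 = a1$cache, r1 = r1$cache, a2 = a2$cache))
}

cbam_mlp_bwd <- function(dy, cache) {
  b2 <- nn_conv_bwd(dy, cache$a2)
  dr <- nn_relu_bwd(b2$dx, cache$r1)
  b1 <- nn_conv_bwd(dr, cache$a1)
  list(dv = b1$dx, d_fc1 = b1$dp, d_fc2 = b2$dp)
}

ca_fwd <- function(x, p) {
  d <- dim(x)
  ap <- nn_gap_fwd(x); mp <- nn_gmp_fwd(x)
  va <- ap$y; dim(va) <- c(1L, 1L, d[3], d[4])
  vm <- mp$y; dim(vm) <- c(1L, 1L, d[3], d[4])
  fa <- cbam_mlp_fwd(va, p)
  fm <- cbam_mlp_fwd(vm, p)
  mc <- fg_sigmoid(fa$y + fm$y)  # [1,1,B,C]
  list(mc = mc, cache = list(ap = ap$cache, mp = mp$cache,
                             fa = fa$cache, fm = fm$cache, mc = mc, d = d))
}

ca_bwd <- function(dmc, cache) {
  dlog <- dmc * cache$mc * (1 - cache$mc)
  ba <- cbam_mlp_bwd(dlog, cache$fa)
  bm <- cbam_mlp_bwd(dlog, cache$fm)
  da <- ba$dv; dim(da) <- c(cache$d[3], cache$d[4])
  dm <- bm$dv; dim(dm) <- c(cache$d[3], cache$d[4])
  dx <- nn_gap_bwd(da, cache$ap) + nn_gmp_bwd(dm, cache$mp)
  list(dx = dx,
       d_fc1 = fg_tree_add(ba$d_fc1, bm$d_fc1),
       d_fc2 = fg_tree_add(ba$d_fc2, bm$d_fc2))
}

sa_fwd <- function(x, p) {
  ca <- nn_cap_fwd(x); cm <- nn_cmp_fwd(x)
  cat2 <- nn_concat(ca$y, cm$y)
  cv <- nn_conv_fwd(cat2, p$sa_conv, pad = 3L)
  ms <- fg_sigmoid(cv$y)  # [H,W,B,1]
  list(ms = ms, cache = list(cap = ca$cache, cmp = cm$cache,
                             conv = cv$cache, ms = ms))
}

sa_bwd <- function(dms, cache) {
  dlog <- dms * cache$ms * (1 - cache$ms)
  cb <- nn_conv_bwd(dlog, cache$conv)
  sp <- nn_split(cb$dx, 1L)
  dx <- nn_cap_bwd(sp$a, cache$cap) + nn_cmp_bwd(sp$b, cache$cmp)
  list(dx = dx, d_conv = cb$dp)
}

cbam_fwd <- function(x, p) {
  d <- dim(x)
  hw <- d[1] * d[2]
  ca <- ca_fwd(x, p)
  f1 <- x * rep(as.vector(ca$mc), each = hw)
  sa <- sa_fwd(f1, p)
  f2 <- f1 * as.vector(sa$ms)
  list(y = f2, cache = list(ca = ca$cache, sa = sa$cache, x = x, f1 = f1,
                            mc = ca$mc, ms = sa$ms, d = d))
}

cbam_bwd <- function(dy, cache) {
  d <- cache$d; hw <- d[1] * d[2]; n <- prod(d[1:3])
  # through F2 = F1 * ms
  t1 <- dy * cache$f1
  dim(t1) <- c(n, d[4])
  dms <- rowSums(t1); dim(dms) <- c(d[1], d[2], d[3], 1L)
  df1 <- dy * as.vector(cache$ms)
  sab <- sa_bwd(dms, cache$sa)
  df1 <- df1 + sab$dx
  # through F1 = x * mc
  t2 <- df1 * cache$x
  dim(t2) <- c(hw, d[3] * d[4])
  dmc <- colSums(t2); dim(dmc) <- c(1L, 1L, d[3], d[4])
  dx <- df1 * rep(as.vector(cache$mc), each = hw)
  cab <- ca_bwd(dmc, cache$ca)
  dx <- dx + cab$dx
  list(dx = dx, dp = list(ca_fc1 = cab$d_fc1, ca_fc2 = cab$d_fc2,
                          sa_conv = sab$d_conv))
}

#' Channel attention weights of a CBAM block
#'
#' `sigma(MLP(avgpool(F)) + MLP(maxpool(F)))` with a shared two-layer
#' bottleneck MLP; one weight per channel, each strictly in (0, 1).
#'
#' @inheritParams conv_block
#' @param block an `fg_block` of kind `"cbam"`.
#' @return numeric vector of length `channels`.
#' @export
channel_attention <- function(input, block) {
  stopifnot(inherits(block, "fg_block"), block$block_kind == "cbam")
  input <- as_feature_map(input)
  if (dim(input)[1] != block$config$channels)
    stop("channel_attention: channel mismatch")
  as.vector(ca_fwd(chw_to_hwbc(input), block$params)$mc)
}

#' Spatial attention map of a CBAM block
#'
#' `sigma(Conv7x7([avgpool_c(F); maxpool_c(F)]))` (padding 3): one weight
#' per pixel, each strictly in (0, 1).
#'
#' @inheritParams channel_attention
#' @return numeric matrix `[height, width]`.
#' @export
spatial_attention <- function(input, block) {
  stopifnot(inherits(block, "fg_block"), block$block_kind == "cbam")
  input <- as_feature_map(input)
  ms <- sa_fwd(chw_to_hwbc(input), block$params)$ms
  matrix(ms, dim(input)[2], dim(input)[3])
}

#' Apply a full CBAM block
#'
#' Sequential attention: the channel-refined map `F * M_c(F)` is computed
#' first and the spatial attention is evaluated on that refined map, i.e.
#' `F' = (F * M_c(F)) * M_s(F * M_c(F))`.
#'
#' @inheritParams channel_attention
#' @return feature map of the same shape as `input`.
#' @export
cbam <- function(input, block) {
  stopifnot(inherits(block, "fg_block"), block$block_kind == "cbam")
  input <- as_feature_map(input)
  if (dim(input)[1] != block$config$channels)
    stop("cbam: channel mismatch")
  hwbc_to_chw(cbam_fwd(chw_to_hwbc(input), block$params)$y)
}

# ---- Attention Gate ---------------------------------------------------------

ag_fwd <- function(x, g, p, train = FALSE) {
  dx_ <- dim(x); dg <- dim(g)
  if (dx_[1] != dg[1] || dx_[2] != dg[2])
    stop("attention_gate: x and g must share spatial dimensions")
  ax <- nn_conv_fwd(x, p$phi_x)
  ag_ <- nn_conv_fwd(g, p$phi_g)
  rl <- nn_relu_fwd(ax$y + ag_$y)
  ps <- nn_conv_fwd(rl$y, p$psi)
  bn <- nn_bn_fwd(ps$y, p$bn, train = train)
  p$bn$run_mean <- bn$run_mean; p$bn$run_var <- bn$run_var
  alpha <- fg_sigmoid(bn$y)  # [H,W,B,1]
  y <- x * as.vector(alpha)
  list(y = y, alpha = alpha, p = p,
       cache = list(ax = ax$cache, ag = ag_$cache, relu = rl$cache,
                    psi = ps$cache, bn = bn$cache, alpha = alpha, x = x,
                    d = dx_))
}

ag_bwd <- function(dy, cache) {
  d <- cache$d; n <- prod(d[1:3])
  t1 <- dy * cache$x
  dim(t1) <- c(n, d[4])
  dalpha <- rowSums(t1); dim(dalpha) <- c(d[1], d[2], d[3], 1L)
  dxm <- dy * as.vector(cache$alpha)
  dbn <- dalpha * cache$alpha * (1 - cache$alpha)
  b <- nn_bn_bwd(dbn, cache$bn)
  ps <- nn_conv_bwd(b$dx, cache$psi)
  dr <- nn_relu_bwd(ps$dx, cache$relu)
  bx <- nn_conv_bwd(dr, cache$ax)
  bg <- nn_conv_bwd(dr, cache$ag)
  list(dx = dxm + bx$dx, dg = bg$dx,
       dp = list(phi_x = bx$dp, phi_g = bg$dp, psi = ps$dp, bn = b$dp))
}

#' Apply an attention gate to a skip feature
#'
#' Computes `alpha = sigma(psi(ReLU(phi_x(x) + phi_g(g))))` — with `phi_x`
#' and `phi_g` 1x1 convolutions to `max(1, C_x/2)` intermediate channels
#' and `psi` a 1x1 convolution followed by batch norm to a single channel —
#' and returns `alpha * x` (the coefficient map broadcast over channels).
#' `x` and `g` must share spatial dimensions; no implicit resampling is
#' performed.
#'
#' @param x encoder (skip) feature map `[x_channels, H, W]`.
#' @param g decoder gating signal `[g_channels, H, W]`.
#' @param block an `fg_block` of kind `"ag"`.
#' @param train logical; batch-norm mode as in [conv_block()].
#' @param return_alpha if `TRUE`, return a list with the gated output and
#'   the gate coefficients `alpha` (`[1, H, W]`, values strictly in (0,1)).
#' @return feature map shaped like `x`, or a list `(output, alpha)`.
#' @export
attention_gate <- function(x, g, block, train = FALSE, return_alpha = FALSE) {
  stopifnot(inherits(block, "fg_block"), block$block_kind == "ag")
  x <- as_feature_map(x); g <- as_feature_map(g)
  if (dim(x)[1] != block$config$x_channels ||
      dim(g)[1] != block$config$g_channels)
    stop("attention_gate: channel mismatch")
  out <- ag_fwd(chw_to_hwbc(x), chw_to_hwbc(g), block$params, train = train)
  y <- hwbc_to_chw(out$y)
  if (!return_alpha) return(y)
  alpha <- out$alpha
  dim(alpha) <- c(1L, dim(x)[2], dim(x)[3])
  list(output = y, alpha = alpha)
}
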