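# The four learned blocks against straight-line scalar oracles and their
# exact identity constructions.

test_that("shift_tokens translates channel groups with zero fill and no wrap", {
  # hand translation: one group, +1 along height turns (a, b, c) into (0, a, b)
  x <- array(as.numeric(seq_len(2 * 3 * 3)), c(2, 3, 3))
  s <- shift_spec("height", 1, offsets = 1L)
  y <- shift_tokens(x, s)
  for (c in 1:2) for (j in 1:3) {
    expect_equal(y[c, , j], c(0, x[c, 1, j], x[c, 2, j]))
  }
  # all-zero offsets are the identity
  s0 <- shift_spec("height", 2, offsets = c(0L, 0L))
  expect_identical(shift_tokens(x, s0), x)
  # zero fill can only delete mass
  set.seed(11)
  for (rep in 1:10) {
    x <- rand_fm(5, 6, 7)
    ax <- sample(c("height", "width"), 1)
    s <- shift_spec(ax, 5, offsets = sample(-3:3, 5, replace = TRUE))
    y <- shift_tokens(x, s)
    expect_lte(sum(abs(y)), sum(abs(x)))
    # +k then -k restores the interior at distance >= k from the borders
    k <- max(abs(s$offsets))
    back <- s; back$offsets <- -s$offsets
    z <- shift_tokens(y, back)
    if (k < 3) {
      ii <- (k + 1):(6 - k); jj <- (k + 1):(7 - k)
      expect_equal(z[, ii, jj], x[, ii, jj])
    }
  }
})

test_that("shift_tokens matches the scalar oracle and rejects oversized offsets", {
  set.seed(12)
  x <- rand_fm(7, 5, 4)
  s <- shift_spec("width", 3, offsets = c(-2L, 0L, 3L))
  groups <- focusgate:::shift_groups(7, 3)
  expect_equal(shift_tokens(x, s), oracle_shift(x, "width", groups, s$offsets),
               tolerance = 1e-12)
  expect_error(shift_tokens(x, shift_spec("width", 1, offsets = 4L)),
               "extent")
})

test_that("conv_block matches the scalar oracle and honours its contracts", {
  set.seed(21)
  for (case in list(list(cin = 3, cout = 4, down = FALSE, H = 4, W = 4),
                    list(cin = 4, cout = 2, down = TRUE, H = 4, W = 6),
                    list(cin = 2, cout = 5, down = TRUE, H = 5, W = 5))) {
    b <- new_block("conv", in_channels = case$cin, out_channels = case$cout,
                   downsample = case$down)
    # non-identity running stats so BN arithmetic is exercised
    b$params$bn$run_mean <- stats::rnorm(case$cout, 0, 0.3)
    b$params$bn$run_var <- stats::runif(case$cout, 0.5, 2)
    b$params$bn$beta <- stats::rnorm(case$cout, 0, 0.2)
    x <- rand_fm(case$cin, case$H, case$W)
    y <- conv_block(x, b)
    ref <- oracle_conv_block(x, b, stride = if (case$down) 2L else 1L)
    expect_equal(y, ref, tolerance = 1e-5)
    expect_equal(dim(y)[1], case$cout)
    expect_equal(dim(y)[2], if (case$down) ceiling(case$H / 2) else case$H)
    expect_true(min(y) >= 0)  # ReLU nonnegativity
  }
  b <- new_block("conv", in_channels = 3, out_channels = 4)
  expect_error(conv_block(rand_fm(2, 4, 4), b), "channels")
})

test_that("conv_block preserves or halves resolution per the stage layout", {
  b1 <- new_block("conv", in_channels = 3, out_channels = 8, seed = 1)
  expect_equal(dim(conv_block(rand_fm(3, 32, 32), b1)), c(8, 32, 32))
  b2 <- new_block("conv", in_channels = 8, out_channels = 16,
                  downsample = TRUE, seed = 2)
  expect_equal(dim(conv_block(rand_fm(8, 32, 32), b2)), c(16, 16, 16))
})

test_that("stmlp_block matches the scalar oracle on small inputs", {
  set.seed(31)
  for (case in list(list(C = 2, H = 2, W = 2, hr = 2),
                    list(C = 4, H = 4, W = 3, hr = 4),
                    list(C = 3, H = 3, W = 4, hr = 3))) {
    b <- new_block("stmlp", channels = case$C, hidden_ratio = case$hr,
                   n_groups = 2L, offsets = c(-1L, 1L))
    # non-trivial biases
    for (nm in names(b$params)) b$params[[nm]]$b[] <-
        stats::rnorm(length(b$params[[nm]]$b), 0, 0.3)
    x <- rand_fm(case$C, case$H, case$W)
    expect_equal(stmlp_block(x, b), oracle_stmlp(x, b), tolerance = 1e-5)
  }
})

test_that("stmlp_block with zeroed output projections is exactly the identity", {
  b <- new_block("stmlp", channels = 6, hidden_ratio = 4, seed = 5)
  b$params$fc2h$w[] <- 0; b$params$fc2h$b[] <- 0
  b$params$fc2w$w[] <- 0; b$params$fc2w$b[] <- 0
  x <- rand_fm(6, 8, 8)
  expect_identical(stmlp_block(x, b), x)
  # shape preservation on a larger map
  b2 <- new_block("stmlp", channels = 16, seed = 6)
  expect_equal(dim(stmlp_block(rand_fm(16, 12, 10), b2)), c(16, 12, 10))
})

test_that("channel attention matches the scalar oracle and stays in (0,1)", {
  set.seed(41)
  for (C in c(2, 4, 8)) {
    b <- new_block("cbam", channels = C, reduction = 2)
    b$params$ca_fc1$b[] <- stats::rnorm(dim(b$params$ca_fc1$w)[4], 0, 0.3)
    b$params$ca_fc2$b[] <- stats::rnorm(C, 0, 0.3)
    x <- rand_fm(C, 4, 4)
    w <- channel_attention(x, b)
    expect_length(w, C)
    expect_true(all(w > 0 & w < 1))
    expect_equal(w, oracle_channel_attention(x, b), tolerance = 1e-5)
  }
  # zeroed MLP -> sigma(0) = 0.5 exactly
  b <- new_block("cbam", channels = 4, seed = 2)
  b$params$ca_fc1$w[] <- 0; b$params$ca_fc1$b[] <- 0
  b$params$ca_fc2$w[] <- 0; b$params$ca_fc2$b[] <- 0
  expect_equal(channel_attention(rand_fm(4, 3, 3), b), rep(0.5, 4))
})

test_that("bottleneck width floors at one channel when C < reduction", {
  b <- new_block("cbam", channels = 4, reduction = 16)
  expect_equal(b$config$bottleneck, 1L)
  expect_length(channel_attention(rand_fm(4, 4, 4), b), 4L)
})

test_that("spatial attention matches the scalar oracle and peaks correctly", {
  set.seed(51)
  b <- new_block("cbam", channels = 3, reduction = 2)
  b$params$sa_conv$b[] <- 0.1
  x <- rand_fm(3, 4, 4)
  m <- spatial_attention(x, b)
  expect_equal(dim(m), c(4, 4))
  expect_true(all(m > 0 & m < 1))
  expect_equal(m, oracle_spatial_attention(x, b), tolerance = 1e-5)
  # zeroed conv -> uniform 0.5
  b0 <- new_block("cbam", channels = 3, seed = 3)
  b0$params$sa_conv$w[] <- 0; b0$params$sa_conv$b[] <- 0
  expect_equal(spatial_attention(x, b0), matrix(0.5, 4, 4))
  # single-pixel peak with a centred positive kernel is maximal there
  bp <- new_block("cbam", channels = 1, seed = 4)
  bp$params$sa_conv$w[] <- 0
  bp$params$sa_conv$w[4, 4, , ] <- 1  # centre tap only, both pooled channels
  bp$params$sa_conv$b[] <- 0
  xp <- array(0, c(1, 9, 9)); xp[1, 5, 7] <- 3
  mp <- spatial_attention(xp, bp)
  expect_equal(which(mp == max(mp)), 5L + 9L * 6L)
})

test_that("cbam applies channel then spatial attention sequentially", {
  set.seed(61)
  b <- new_block("cbam", channels = 4, reduction = 2)
  x <- rand_fm(4, 4, 4)
  expect_equal(cbam(x, b), oracle_cbam(x, b), tolerance = 1e-5)
  expect_equal(dim(cbam(x, b)), dim(x))
  # uniform-0.5 maps under zeroed heads compose to F/4
  b0 <- new_block("cbam", channels = 4, seed = 7)
  for (nm in c("ca_fc1", "ca_fc2", "sa_conv")) {
    b0$params[[nm]]$w[] <- 0; b0$params[[nm]]$b[] <- 0
  }
  expect_equal(cbam(x, b0), x / 4, tolerance = 1e-12)
})

test_that("cbam evaluates spatial attention on the channel-refined map, not the input", {
  # make channel attention strongly non-uniform so M_s(F) != M_s(F * M_c):
  # the sequential composition then differs from the parallel one
  set.seed(62)
  b <- new_block("cbam", channels = 2, reduction = 1)
  b$params$ca_fc1$w[] <- 0; b$params$ca_fc1$b[] <- c(4, -4)
  b$params$ca_fc2$w[1, 1, , ] <- diag(2) * 3
  b$params$ca_fc2$b[] <- 0
  x <- rand_fm(2, 3, 3)
  got <- cbam(x, b)
  expect_equal(got, oracle_cbam(x, b), tolerance = 1e-5)
  # parallel (wrong) composition: spatial attention computed on raw input
  mc <- oracle_channel_attention(x, b)
  ms_raw <- oracle_spatial_attention(x, b)
  wrong <- x
  for (c in 1:2) wrong[c, , ] <- x[c, , ] * mc[c] * ms_raw
  expect_gt(max(abs(got - wrong)), 1e-6)
})

test_that("attention gate matches the scalar oracle, including the ReLU", {
  set.seed(71)
  for (case in list(list(cx = 1, cg = 1, H = 2, W = 2),
                    list(cx = 4, cg = 6, H = 3, W = 4),
                    list(cx = 3, cg = 2, H = 4, W = 4))) {
    b <- new_block("ag", x_channels = case$cx, g_channels = case$cg)
    b$params$phi_x$b[] <- stats::rnorm(b$config$int_channels, 0, 0.3)
    b$params$psi$b[] <- 0.2
    b$params$bn$run_mean <- stats::rnorm(1, 0, 0.1)
    b$params$bn$run_var <- stats::runif(1, 0.5, 2)
    x <- rand_fm(case$cx, case$H, case$W)
    g <- rand_fm(case$cg, case$H, case$W)
    expect_equal(attention_gate(x, g, b), oracle_attention_gate(x, g, b),
                 tolerance = 1e-5)
  }
})

test_that("attention gate identities, shape contract and error cases hold", {
  # zero psi at identity batch-norm init -> alpha = 0.5 -> output = x/2
  b <- new_block("ag", x_channels = 3, g_channels = 5, seed = 8)
  b$params$psi$w[] <- 0; b$params$psi$b[] <- 0
  x <- rand_fm(3, 4, 4); g <- rand_fm(5, 4, 4)
  out <- attention_gate(x, g, b, return_alpha = TRUE)
  expect_equal(out$alpha, array(0.5, c(1, 4, 4)))
  expect_equal(out$output, x / 2)
  # shape: channels follow x, not g
  b2 <- new_block("ag", x_channels = 4, g_channels = 8, seed = 9)
  y <- attention_gate(rand_fm(4, 8, 8), rand_fm(8, 8, 8), b2)
  expect_equal(dim(y), c(4, 8, 8))
  # alpha strictly in (0,1) for random finite inputs
  a <- attention_gate(rand_fm(4, 8, 8), rand_fm(8, 8, 8), b2,
                      return_alpha = TRUE)$alpha
  expect_true(all(a > 0 & a < 1))
  # no implicit spatial resampling
  expect_error(attention_gate(rand_fm(4, 8, 8), rand_fm(8, 4, 4), b2),
               "spatial")
  expect_error(attention_gate(rand_fm(3, 8, 8), rand_fm(8, 8, 8), b2),
               "channel")
})

test_that("intermediate AG width is half the skip channels", {
  b <- new_block("ag", x_channels = 256, g_channels = 512)
  expect_equal(b$config$int_channels, 128L)
  b1 <- new_block("ag", x_channels = 1, g_channels = 2)
  expect_equal(b1$config$int_channels, 1L)
})

test_that("parameter counts are deterministic functions of the configuration", {
  for (args in list(list(kind = "conv", in_channels = 3, out_channels = 8),
                    list(kind = "stmlp", channels = 6, hidden_ratio = 4),
                    list(kind = "cbam", channels = 8, reduction = 4),
                    list(kind = "ag", x_channels = 4, g_channels = 6))) {
    b1 <- do.call(new_block, c(args, seed = 1))
    b2 <- do.call(new_block, c(args, seed = 99))
    expect_identical(b1$parameter_count, b2$parameter_count)
    expect_identical(block_parameter_count(b1), b1$parameter_count)
  }
  # hand-computed count for a conv block: 3*3*3*8 + 8 (bias) + 2*8 (bn)
  b <- new_block("conv", in_channels = 3, out_channels = 8)
  expect_equal(b$parameter_count, 216 + 8 + 16)
})
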