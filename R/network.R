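#' @title Network assembly
#' @description Assemble the blocks into the full encoder-decoder,
#'   generate ablation variants, initialise weights and count parameters.
#' @name network
NULL

#' Model configuration
#'
#' Complete architectural hyperparameters of the segmentation network.
#' The encoder has five stages (the first keeps resolution, stages 2-5
#' each halve it, giving scales 1/1 ... 1/16); each stage applies a conv
#' block, then optionally an ST-MLP block and a CBAM block. The decoder
#' has four stages, each a 2x2 stride-2 transposed convolution, an
#' (optionally attention-gated) skip concatenation and two 3x3
#' conv+BN+ReLU refinements; a 1x1 convolution with sigmoid produces the
#' probability map.
#'
#' @param input_channels number of image channels (3 for RGB).
#' @param encoder_channels five encoder stage widths.
#' @param decoder_channels four decoder stage widths; must mirror
#'   `rev(encoder_channels[1:4])` so each skip concatenation pairs equal
#'   widths.
#' @param hidden_ratio ST-MLP hidden width multiplier.
#' @param cbam_reduction CBAM channel-attention bottleneck ratio.
#' @param use_stmlp,use_cbam,use_ag component switches (ablations).
#' @param out_channels output channels (1 for binary segmentation).
#' @param n_groups,shift_offsets token-shift grouping for the ST-MLP.
#' @return an object of class `fg_config`.
#' @export
model_config <- function(input_channels = 3L,
                         encoder_channels = c(64L, 128L, 256L, 512L, 1024L),
                         decoder_channels = rev(encoder_channels[1:4]),
                         hidden_ratio = 4L,
                         cbam_reduction = 16L,
                         use_stmlp = TRUE, use_cbam = TRUE, use_ag = TRUE,
                         out_channels = 1L,
                         n_groups = 5L, shift_offsets = -2:2) {
  encoder_channels <- as.integer(encoder_channels)
  decoder_channels <- as.integer(decoder_channels)
  if (length(encoder_channels) != 5L)
    stop("encoder_channels must have length 5")
  if (length(decoder_channels) != 4L)
    stop("decoder_channels must have length 4")
  if (!identical(decoder_channels, rev(encoder_channels[1:4])))
    stop("decoder_channels must mirror rev(encoder_channels[1:4])")
  structure(list(
    input_channels = as.integer(input_channels),
    encoder_channels = encoder_channels,
    decoder_channels = decoder_channels,
    hidden_ratio = as.integer(hidden_ratio),
    cbam_reduction = as.integer(cbam_reduction),
    use_stmlp = isTRUE(use_stmlp), use_cbam = isTRUE(use_cbam),
    use_ag = isTRUE(use_ag),
    out_channels = as.integer(out_channels),
    n_groups = as.integer(n_groups),
    shift_offsets = as.integer(shift_offsets)
  ), class = "fg_config")
}

#' Ablation variant presets
#'
#' @param id one of `"V1"` (full model) ... `"V7"`:
#'   V1 full; V2 reduced channels `[16, 32, 64, 128, 256]`; V3 no CBAM;
#'   V4 no attention gates; V5 convolution-only baseline; V6 no ST-MLP;
#'   V7 CBAM only (no attention gates).
#' @param ... further arguments passed to [model_config()] (e.g. reduced
#'   `encoder_channels` to study all variants at equal widths).
#' @return an `fg_config`.
#' @export
make_variant <- function(id = c("V1", "V2", "V3", "V4", "V5", "V6", "V7"),
                         ...) {
  id <- match.arg(id)
  base <- switch(id,
    V1 = list(),
    V2 = list(encoder_channels = c(16L, 32L, 64L, 128L, 256L)),
    V3 = list(use_cbam = FALSE),
    V4 = list(use_ag = FALSE),
    V5 = list(use_stmlp = FALSE, use_cbam = FALSE, use_ag = FALSE),
    V6 = list(use_stmlp = FALSE),
    V7 = list(use_ag = FALSE))
  args <- utils::modifyList(base, list(...))
  if (!is.null(args$encoder_channels) && is.null(args$decoder_channels))
    args$decoder_channels <- rev(args$encoder_channels[1:4])
  cfg <- do.call(model_config, args)
  attr(cfg, "variant") <- id
  cfg
}

# ---- construction -----------------------------------------------------------

#' Build a segmentation model from a configuration
#'
#' @param config an `fg_config`.
#' @param seed optional integer seed for reproducible weight
#'   initialisation (He for convolutions, Xavier for the MLP projections,
#'   identity for batch norm).
#' @return an object of class `fg_model`.
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "fg_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ec <- config$encoder_channels
  dc <- config$decoder_channels
  enc <- vector("list", 5L)
  enc_cfg <- vector("list", 5L)
  c_in <- config$input_channels
  for (i in 1:5) {
    cfg_i <- list(
      conv = list(in_channels = c_in, out_channels = ec[i],
                  downsample = i > 1L),
      stmlp = if (config$use_stmlp)
        list(channels = ec[i], hidden = config$hidden_ratio * ec[i],
             spec_h = shift_spec("height", config$n_groups,
                                 config$shift_offsets),
             spec_w = shift_spec("width", config$n_groups,
                                 config$shift_offsets)),
      cbam = if (config$use_cbam)
        list(channels = ec[i],
             bottleneck = max(1L, ec[i] %/% config$cbam_reduction)))
    p_i <- list(
      conv = list(conv = init_conv(3L, c_in, ec[i], "he"),
                  bn = init_bn(ec[i])),
      stmlp = if (config$use_stmlp) list(
        fc1h = init_conv(1L, ec[i], cfg_i$stmlp$hidden, "xavier"),
        fc2h = init_conv(1L, cfg_i$stmlp$hidden, ec[i], "xavier"),
        fc1w = init_conv(1L, ec[i], cfg_i$stmlp$hidden, "xavier"),
        fc2w = init_conv(1L, cfg_i$stmlp$hidden, ec[i], "xavier")),
      cbam = if (config$use_cbam) list(
        ca_fc1 = init_conv(1L, ec[i], cfg_i$cbam$bottleneck, "xavier"),
        ca_fc2 = init_conv(1L, cfg_i$cbam$bottleneck, ec[i], "xavier"),
        sa_conv = init_conv(7L, 2L, 1L, "he")))
    enc[[i]] <- p_i
    enc_cfg[[i]] <- cfg_i
    c_in <- ec[i]
  }
  # decoder stage j consumes d_{j-1} (stage 0 = bottleneck, ec[5] channels)
  # and the skip from encoder stage 5-j
  dec <- vector("list", 4L)
  dec_cfg <- vector("list", 4L)
  d_in <- ec[5]
  for (j in 1:4) {
    skip_c <- ec[5L - j]
    cfg_j <- list(
      tconv = list(in_channels = d_in, out_channels = dc[j]),
      ag = if (config$use_ag)
        list(x_channels = skip_c, g_channels = dc[j],
             int_channels = max(1L, skip_c %/% 2L)),
      conv1 = list(in_channels = dc[j] + skip_c, out_channels = dc[j],
                   downsample = FALSE),
      conv2 = list(in_channels = dc[j], out_channels = dc[j],
                   downsample = FALSE))
    p_j <- list(
      tconv = init_conv(2L, d_in, dc[j], "he"),
      ag = if (config$use_ag) list(
        phi_x = init_conv(1L, skip_c, cfg_j$ag$int_channels, "he"),
        phi_g = init_conv(1L, dc[j], cfg_j$ag$int_channels, "he"),
        psi = init_conv(1L, cfg_j$ag$int_channels, 1L, "he"),
        bn = init_bn(1L)),
      conv1 = list(conv = init_conv(3L, dc[j] + skip_c, dc[j], "he"),
                   bn = init_bn(dc[j])),
      conv2 = list(conv = init_conv(3L, dc[j], dc[j], "he"),
                   bn = init_bn(dc[j])))
    dec[[j]] <- p_j
    dec_cfg[[j]] <- cfg_j
    d_in <- dc[j]
  }
  head <- init_conv(1L, dc[4], config$out_channels, "he")
  structure(list(config = config,
                 params = list(enc = enc, dec = dec, head = head),
                 stage_cfg = list(enc = enc_cfg, dec = dec_cfg)),
            class = "fg_model")
}

#' Re-initialise all model weights reproducibly
#'
#' Convolution kernels are redrawn with He initialisation, the fully
#' connected (ST-MLP and channel-attention) projections with Xavier, and
#' every batch-norm layer is reset to the identity (scale 1, shift 0,
#' zeroed running mean, unit running variance).
#'
#' @param model an `fg_model`.
#' @param seed integer seed.
#' @return the re-initialised model.
#' @export
init_weights <- function(model, seed) {
  stopifnot(inherits(model, "fg_model"))
  set.seed(as.integer(seed))
  model$params <- fg_reinit(model$params)
  model
}

#' Count trainable parameters
#'
#' @param model an `fg_model` (or any parameter tree).
#' @return integer number of trainable scalars; batch-norm running
#'   statistics are buffers and excluded.
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "fg_model")) model$params else model
  fg_count_params(p)
}

# ---- forward / backward -----------------------------------------------------

# internal forward on [H,W,B,C] tensors.
# keep = TRUE retains every cache for the backward pass; features = TRUE
# also returns encoder stage outputs.  Updated batch-norm running
# statistics are threaded through the returned model params.
model_fwd <- function(model, x, train = FALSE, keep = FALSE,
                      features = FALSE, capture = NULL) {
  cfg <- model$config
  p <- model$params
  caches <- if (keep) list(enc = vector("list", 5L),
                           dec = vector("list", 4L)) else NULL
  acts <- list()
  skips <- vector("list", 5L)
  h <- x
  for (i in 1:5) {
    sc <- model$stage_cfg$enc[[i]]
    cb <- cb_fwd(h, p$enc[[i]]$conv, sc$conv, train = train)
    p$enc[[i]]$conv <- cb$p
    h <- cb$y
    st <- NULL; cm <- NULL
    if (!is.null(sc$stmlp)) {
      st <- stmlp_fwd(h, p$enc[[i]]$stmlp, sc$stmlp)
      h <- st$y
    }
    if (!is.null(sc$cbam)) {
      cm <- cbam_fwd(h, p$enc[[i]]$cbam)
      h <- cm$y
    }
    skips[[i]] <- h
    if (keep)
      caches$enc[[i]] <- list(conv = cb$cache,
                              stmlp = if (!is.null(st)) st$cache,
                              cbam = if (!is.null(cm)) cm$cache)
    if (!is.null(capture) && capture == paste0("enc.", i)) acts[[capture]] <- h
  }
  d <- skips[[5L]]
  for (j in 1:4) {
    sc <- model$stage_cfg$dec[[j]]
    up <- nn_tconv_fwd(d, p$dec[[j]]$tconv)
    skip <- skips[[5L - j]]
    if (!is.null(sc$ag)) {
      ag <- ag_fwd(skip, up$y, p$dec[[j]]$ag, train = train)
      p$dec[[j]]$ag <- ag$p
      gated <- ag$y
    } else {
      ag <- NULL
      gated <- skip
    }
    cat2 <- nn_concat(up$y, gated)
    c1 <- cb_fwd(cat2, p$dec[[j]]$conv1, sc$conv1, train = train)
    p$dec[[j]]$conv1 <- c1$p
    c2 <- cb_fwd(c1$y, p$dec[[j]]$conv2, sc$conv2, train = train)
    p$dec[[j]]$conv2 <- c2$p
    d <- c2$y
    if (keep)
      caches$dec[[j]] <- list(tconv = up$cache,
                              ag = if (!is.null(ag)) ag$cache,
                              conv1 = c1$cache, conv2 = c2$cache,
                              used_ag = !is.null(ag))
    if (!is.null(capture) && capture == paste0("dec.", j, ".conv2"))
      acts[[capture]] <- d
  }
  hd <- nn_conv_fwd(d, p$head)
  y <- fg_sigmoid(hd$y)
  if (keep) caches$head <- list(conv = hd$cache, y = y)
  model$params <- p
  list(y = y, model = model, caches = caches,
       skips = if (features) skips else NULL, acts = acts)
}

# backward pass; dy is the gradient with respect to the sigmoid output.
# Returns the gradient tree (congruent with model$params) and, when
# `capture` names a forward node, the gradient of the loss with respect
# to that activation.
model_bwd <- function(model, caches, dy, capture = NULL) {
  y <- caches$head$y
  dz <- dy * y * (1 - y)
  hb <- nn_conv_bwd(dz, caches$head$conv)
  g_head <- hb$dp
  dd <- hb$dx
  g_dec <- vector("list", 4L)
  dskips <- vector("list", 5L)
  cap_grad <- NULL
  for (j in 4:1) {
    cc <- caches$dec[[j]]
    if (!is.null(capture) && capture == paste0("dec.", j, ".conv2"))
      cap_grad <- dd
    c2 <- cb_bwd(dd, cc$conv2)
    c1 <- cb_bwd(c2$dx, cc$conv1)
    up_c <- dim(cc$tconv$p$w)[4]
    sp <- nn_split(c1$dx, up_c)
    dup <- sp$a
    if (cc$used_ag) {
      agb <- ag_bwd(sp$b, cc$ag)
      dskip <- agb$dx
      dup <- dup + agb$dg
      g_ag <- agb$dp
    } else {
      dskip <- sp$b
      g_ag <- NULL
    }
    tb <- nn_tconv_bwd(dup, cc$tconv)
    g_dec[[j]] <- list(tconv = tb$dp, ag = g_ag,
                       conv1 = c1$dp, conv2 = c2$dp)
    dskips[[5L - j]] <- dskip
    dd <- tb$dx
  }
  dskips[[5L]] <- dd  # bottleneck gradient arrives via the first tconv
  g_enc <- vector("list", 5L)
  dh <- NULL
  for (i in 5:1) {
    g <- dskips[[i]]
    if (!is.null(dh)) g <- g + dh
    cc <- caches$enc[[i]]
    if (!is.null(capture) && capture == paste0("enc.", i)) cap_grad <- g
    g_cbam <- NULL; g_stmlp <- NULL
    if (!is.null(cc$cbam)) {
      cb_ <- cbam_bwd(g, cc$cbam)
      g <- cb_$dx
      g_cbam <- cb_$dp
    }
    if (!is.null(cc$stmlp)) {
      st <- stmlp_bwd(g, cc$stmlp)
      g <- st$dx
      g_stmlp <- st$dp
    }
    cv <- cb_bwd(g, cc$conv)
    g_enc[[i]] <- list(conv = cv$dp, stmlp = g_stmlp, cbam = g_cbam)
    dh <- cv$dx
  }
  list(grads = list(enc = g_enc, dec = g_dec, head = g_head),
       dx = dh, capture = cap_grad)
}

#' Run the model on a batch of images
#'
#' @param object an `fg_model`.
#' @param batch numeric array `[B, channels, H, W]` or a single image
#'   `[channels, H, W]`; `H` and `W` must be divisible by 16.
#' @param ... unused.
#' @return probability maps `[B, out_channels, H, W]` with values in
#'   (0, 1). Evaluation mode: batch norm uses running statistics, so the
#'   output is deterministic for fixed weights and input.
#' @export
predict.fg_model <- function(object, batch, ...) {
  single <- length(dim(batch)) == 3L
  if (single) dim(batch) <- c(1L, dim(batch))
  d <- dim(batch)
  if (d[2] != object$config$input_channels)
    stop(sprintf("input has %d channels, model expects %d", d[2],
                 object$config$input_channels))
  if (d[3] %% 16L != 0L || d[4] %% 16L != 0L)
    stop("input spatial dimensions must be divisible by 16")
  out <- model_fwd(object, bchw_to_hwbc(batch), train = FALSE)$y
  y <- hwbc_to_bchw(out)
  if (single) {
    dim(y) <- dim(y)[-1]
  }
  y
}

#' Encoder stage outputs for an image
#'
#' Mainly a testing/inspection hook: returns the five encoder stage
#' feature maps (scales 1/1, 1/2, 1/4, 1/8, 1/16) for one image.
#'
#' @param model an `fg_model`.
#' @param image array `[channels, H, W]`.
#' @return list of five arrays `[C_i, H_i, W_i]`.
#' @export
encoder_features <- function(model, image) {
  stopifnot(inherits(model, "fg_model"))
  image <- as_feature_map(image)
  out <- model_fwd(model, chw_to_hwbc(image), train = FALSE, features = TRUE)
  lapply(out$skips, hwbc_to_chw)
}

#' @export
print.fg_model <- function(x, ...) {
  v <- attr(x$config, "variant")
  cat(sprintf("<fg_model%s> encoder [%s], %s parameters\n",
              if (is.null(v)) "" else paste0(" ", v),
              paste(x$config$encoder_channels, collapse = ", "),
              format(count_parameters(x), big.mark = ",")))
  cat(sprintf("  stmlp=%s cbam=%s ag=%s\n", x$config$use_stmlp,
              x$config$use_cbam, x$config$use_ag))
  invisible(x)
}

# ---- config serialization ---------------------------------------------------

#' Write / read a model configuration as YAML
#'
#' @param config an `fg_config`.
#' @param path file path.
#' @return `config_to_yaml` returns `path` invisibly; `config_from_yaml`
#'   returns an `fg_config`.
#' @export
config_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "fg_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  do.call(model_config, yaml::read_yaml(path))
}

#' Per-variant summary table
#'
#' Builds each ablation variant at the given encoder widths and reports
#' its parameter count; used by the `describe` CLI subcommand.
#'
#' @param encoder_channels widths used for every variant (V2 keeps its own
#'   reduced preset when `NULL`).
#' @return data frame with variant id, component flags and parameter count.
#' @export
variant_table <- function(encoder_channels = NULL) {
  ids <- paste0("V", 1:7)
  rows <- lapply(ids, function(id) {
    cfg <- if (is.null(encoder_channels)) make_variant(id)
           else if (id == "V2") make_variant(id)
           else make_variant(id, encoder_channels = encoder_channels)
    m <- build_model(cfg, seed = 0L)
    n <- count_parameters(m)
    rm(m)
    data.frame(variant = id,
               encoder = paste(cfg$encoder_channels, collapse = "-"),
               stmlp = cfg$use_stmlp, cbam = cfg$use_cbam, ag = cfg$use_ag,
               parameters = n,
               parameters_m = round(n / 1e6, 3))
  })
  do.call(rbind, rows)
}
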