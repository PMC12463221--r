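#' @title Interpretability tools
#' @description Grad-CAM heatmaps from decoder activations and
#'   false-positive / false-negative difference maps.
#' @name interpret
NULL

# stable dotted-path registry: public layer names resolve to internal
# forward-graph node ids regardless of internal naming
resolve_layer <- function(name) {
  if (grepl("^enc\\.[1-5]$", name) || grepl("^dec\\.[1-4]\\.conv2$", name))
    return(name)
  m <- regmatches(name, regexec("^decoder\\.([0-3])\\.conv$", name))[[1]]
  if (length(m) == 2L)
    return(sprintf("dec.%d.conv2", as.integer(m[2]) + 1L))
  m <- regmatches(name, regexec("^encoder\\.([0-4])$", name))[[1]]
  if (length(m) == 2L)
    return(sprintf("enc.%d", as.integer(m[2]) + 1L))
  stop("unknown layer name: ", name)
}

#' Grad-CAM heatmap for a segmentation prediction
#'
#' The target scalar is the sum of predicted foreground probabilities
#' over the image. Channel weights are the spatial means of the
#' gradient of that scalar with respect to the target layer's
#' activations; the heatmap is `ReLU(sum_k w_k A_k)`, max-normalised
#' (all-zero when no activation contributes, so a dead head cannot
#' divide by zero) and bilinearly upsampled to the input size.
#'
#' @param model an `fg_model`.
#' @param image array `[channels, H, W]` (H, W divisible by 16).
#' @param target_layer dotted layer path. `"decoder.3.conv"` (the default)
#'   addresses the last convolutional layer of the decoder; `"decoder.k.conv"`
#'   (k = 0..3) and `"encoder.k"` (k = 0..4) address the other stages.
#' @return heatmap matrix `[H, W]` with values in `[0, 1]`.
#' @export
grad_cam <- function(model, image, target_layer = "decoder.3.conv") {
  stopifnot(inherits(model, "fg_model"))
  image <- as_feature_map(image)
  node <- resolve_layer(target_layer)
  x <- chw_to_hwbc(image)
  fw <- model_fwd(model, x, train = FALSE, keep = TRUE, capture = node)
  act <- fw$acts[[node]]
  if (is.null(act)) stop("unknown layer name: ", target_layer)
  dy <- array(1, dim(fw$y))  # d(sum of probabilities)/d y = 1
  bw <- model_bwd(fw$model, fw$caches, dy, capture = node)
  g <- bw$capture
  d <- dim(act)
  gm <- g; dim(gm) <- c(d[1] * d[2], d[4])
  w <- colMeans(gm)
  am <- act; dim(am) <- c(d[1] * d[2], d[4])
  cam <- am %*% w
  cam <- pmax(cam, 0)
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  cam <- matrix(cam, d[1], d[2])
  co <- resize_coords(d[1], d[2], dim(image)[2], dim(image)[3])
  sample_bilinear(cam, co$si, co$sj)
}

#' Pixel-wise difference map between prediction and ground truth
#'
#' @param y binary ground-truth mask `[H, W]`.
#' @param pred binary predicted mask of the same shape.
#' @return character matrix with entries `"TP"`, `"FP"` (over-
#'   segmentation), `"FN"` (under-segmentation) or `"TN"`; its label
#'   histogram equals [confusion_counts()] for the same pair.
#' @export
difference_map <- function(y, pred) {
  check_pair(y, pred)
  yb <- y != 0; pb <- pred != 0
  out <- matrix("TN", nrow(y), ncol(y))
  out[yb & pb] <- "TP"
  out[!yb & pb] <- "FP"
  out[yb & !pb] <- "FN"
  out
}

#' Render a difference map as an RGB image
#'
#' TP white, FP red (over-segmentation), FN blue (under-segmentation),
#' TN black.
#'
#' @param dm output of [difference_map()].
#' @return array `[3, H, W]` in `[0, 1]`.
#' @export
render_difference_map <- function(dm) {
  cols <- list(TP = c(1, 1, 1), FP = c(1, 0.2, 0.2),
               FN = c(0.2, 0.4, 1), TN = c(0, 0, 0))
  out <- array(0, c(3L, nrow(dm), ncol(dm)))
  for (lab in names(cols)) {
    sel <- dm == lab
    for (c in 1:3) {
      ch <- out[c, , ]
      ch[sel] <- cols[[lab]][c]
      out[c, , ] <- ch
    }
  }
  out
}

#' Alpha-blend a Grad-CAM heatmap over an RGB image
#'
#' @param image array `[3, H, W]` in `[0, 1]`.
#' @param heatmap matrix `[H, W]` in `[0, 1]`.
#' @param alpha blend weight of the heatmap layer (default 0.5).
#' @return array `[3, H, W]`.
#' @export
render_gradcam_overlay <- function(image, heatmap, alpha = 0.5) {
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  rgbm <- ramp(as.vector(heatmap)) / 255
  out <- array(0, dim(image))
  for (c in 1:3) {
    hm <- matrix(rgbm[, c], nrow(heatmap), ncol(heatmap))
    out[c, , ] <- (1 - alpha) * image[c, , ] + alpha * hm
  }
  pmin(pmax(out, 0), 1)
}

#' Write an image or heatmap as PNG
#'
#' @param x `[3, H, W]` RGB array or `[H, W]` grayscale matrix, values in
#'   `[0, 1]`.
#' @param path file path.
#' @export
write_image_png <- function(x, path) {
  if (is.matrix(x)) png::writePNG(x, path)
  else png::writePNG(aperm(x, c(2, 3, 1)), path)
  invisible(path)
}
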