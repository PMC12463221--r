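#' @title Data handling
#' @description Synthetic dermoscopy-like sample generation, image/mask
#'   I/O, normalisation statistics, dataset splitting and the paired
#'   augmentation policy.
#' @name data
NULL

# ---- resampling primitives --------------------------------------------------

# Inverse-mapped sampling shared by resize, affine warps and elastic
# deformation.  `si`/`sj` hold real-valued source coordinates (1-based)
# for every output pixel.  Images use bilinear interpolation with border
# replication; masks use nearest-neighbour with zero (background) fill so
# labels stay strictly binary.
sample_bilinear <- function(mat, si, sj) {
  H <- nrow(mat); W <- ncol(mat)
  si <- pmin(pmax(si, 1), H); sj <- pmin(pmax(sj, 1), W)
  i0 <- pmin(floor(si), H - 1L); j0 <- pmin(floor(sj), W - 1L)
  di <- si - i0; dj <- sj - j0
  at <- function(ii, jj) mat[ii + (jj - 1) * H]
  v00 <- at(i0, j0);     v10 <- at(i0 + 1, j0)
  v01 <- at(i0, j0 + 1); v11 <- at(i0 + 1, j0 + 1)
  out <- v00 * (1 - di) * (1 - dj) + v10 * di * (1 - dj) +
    v01 * (1 - di) * dj + v11 * di * dj
  matrix(out, nrow(si), ncol(si))
}

sample_nearest <- function(mat, si, sj, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  ii <- round(si); jj <- round(sj)
  ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
  out <- rep(fill, length(ii))
  out[ok] <- mat[cbind(ii[ok], jj[ok])]
  matrix(out, nrow(si), ncol(si))
}

warp_image <- function(image, si, sj) {
  # image: [C,H,W]
  out <- array(0, c(dim(image)[1], nrow(si), ncol(si)))
  for (c in seq_len(dim(image)[1]))
    out[c, , ] <- sample_bilinear(image[c, , ], si, sj)
  out
}

resize_coords <- function(h_in, w_in, h_out, w_out) {
  si <- matrix((seq_len(h_out) - 0.5) * h_in / h_out + 0.5, h_out, w_out)
  sj <- matrix((seq_len(w_out) - 0.5) * w_in / w_out + 0.5, h_out, w_out,
               byrow = TRUE)
  list(si = si, sj = sj)
}

#' Resize an image or mask
#'
#' Bilinear for images (`[C, H, W]`), nearest-neighbour for masks
#' (`[H, W]` matrices), so mask labels remain strictly binary.
#'
#' @param x image array `[C, H, W]` or mask matrix `[H, W]`.
#' @param h,w output size.
#' @return resized array or matrix.
#' @export
resize_pair_member <- function(x, h, w) {
  if (is.matrix(x)) {
    co <- resize_coords(nrow(x), ncol(x), h, w)
    sample_nearest(x, co$si, co$sj)
  } else {
    co <- resize_coords(dim(x)[2], dim(x)[3], h, w)
    warp_image(x, co$si, co$sj)
  }
}

# separable gaussian smoothing of a matrix via dense 1-D kernel matrices
# (rows renormalised, so borders are handled without mass loss)
gauss_mat <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), `-`)
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

smooth_gauss <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  Kr <- gauss_mat(nrow(mat), sigma)
  Kc <- gauss_mat(ncol(mat), sigma)
  Kr %*% mat %*% t(Kc)
}

# ---- synthetic sample generation --------------------------------------------

#' Configuration of the synthetic dermoscopy-like generator
#'
#' The generator emulates the gross statistics of dermoscopic lesion
#' photographs: a single compact lesion whose area is drawn uniformly
#' from `area_fraction_range` (1%-75% of the image by default), an
#' irregular boundary (low-order Fourier perturbation of an ellipse-like
#' outline), a darker/redder lesion than the textured skin background at
#' a contrast drawn from `contrast_range`, plus optional hair-like dark
#' strokes and specular bright spots drawn over the image only.
#'
#' @param image_size side of the square image in pixels.
#' @param area_fraction_range lesion area as a fraction of image area.
#' @param boundary_irregularity standard-deviation scale of the Fourier
#'   boundary perturbation (0 gives a smooth oval).
#' @param contrast_range lesion-background luminance contrast range.
#' @param hair_probability probability that hair strokes are drawn.
#' @param specular_probability probability of specular bright spots.
#' @param noise_std pixel-wise Gaussian acquisition-noise s.d.
#' @return an object of class `fg_synth_config`.
#' @export
synthetic_config <- function(image_size = 256L,
                             area_fraction_range = c(0.01, 0.75),
                             boundary_irregularity = 0.15,
                             contrast_range = c(0.25, 0.6),
                             hair_probability = 0.5,
                             specular_probability = 0.3,
                             noise_std = 0.02) {
  stopifnot(area_fraction_range[1] > 0, area_fraction_range[2] < 1,
            area_fraction_range[1] < area_fraction_range[2],
            hair_probability >= 0, hair_probability <= 1,
            specular_probability >= 0, specular_probability <= 1,
            boundary_irregularity >= 0, noise_std >= 0)
  structure(list(image_size = as.integer(image_size),
                 area_fraction_range = area_fraction_range,
                 boundary_irregularity = boundary_irregularity,
                 contrast_range = contrast_range,
                 hair_probability = hair_probability,
                 specular_probability = specular_probability,
                 noise_std = noise_std),
            class = "fg_synth_config")
}

#' Generate one synthetic image/mask pair
#'
#' Fully reproducible from `seed`. The lesion outline is a low-order
#' Fourier-perturbed closed curve; the mask is exactly the lesion region
#' and its area fraction is matched to a uniform draw from the configured
#' range by construction (the outline is scaled through the empirical
#' quantile of the normalised radius field).
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return a `Sample`: list with `image` (`[3, H, W]`, values in [0,1]),
#'   `mask` (`[H, W]`, 0/1), `id`, and the realised `area_fraction`.
#' @export
generate_sample <- function(cfg = synthetic_config(), seed = 1L) {
  stopifnot(inherits(cfg, "fg_synth_config"))
  set.seed(as.integer(seed))
  n <- cfg$image_size
  if (n < 16L) stop("image_size too small to honour the area range")
  lo <- cfg$area_fraction_range[1]; hi <- cfg$area_fraction_range[2]
  margin <- min(0.003, (hi - lo) / 10)
  target <- min(max(stats::runif(1, lo, hi), lo + margin), hi - margin)

  # lesion geometry
  cx <- stats::runif(1, 0.38, 0.62) * n
  cy <- stats::runif(1, 0.38, 0.62) * n
  elong <- stats::runif(1, 0.7, 1.3)     # mild ellipticity
  kmax <- 8L
  ak <- stats::rnorm(kmax, 0, cfg$boundary_irregularity / seq_len(kmax))
  bk <- stats::rnorm(kmax, 0, cfg$boundary_irregularity / seq_len(kmax))
  ak[1] <- 0; bk[1] <- 0
  gi <- matrix(seq_len(n), n, n) - cy
  gj <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  r <- sqrt((gi / elong)^2 + (gj * elong)^2)
  th <- atan2(gi, gj)
  rt <- 1 + Reduce(`+`, lapply(seq_len(kmax), function(k)
    ak[k] * cos(k * th) + bk[k] * sin(k * th)))
  rt <- pmax(rt, 0.25)
  q <- r / rt
  scale <- stats::quantile(q, probs = target, type = 1, names = FALSE)
  mask <- (q <= scale) * 1

  # photometric rendering
  base <- c(0.78, 0.62, 0.55) + stats::runif(3, -0.05, 0.05)
  contrast <- stats::runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
  lesion_col <- base * (1 - contrast * c(0.75, 1.0, 1.1))
  tex <- smooth_gauss(matrix(stats::rnorm(n * n), n, n), sigma = max(2, n / 32))
  tex <- tex / max(1e-8, stats::sd(tex))
  m_soft <- smooth_gauss(mask, sigma = 1.5)
  img <- array(0, c(3L, n, n))
  for (c in 1:3) {
    bg <- base[c] + 0.03 * tex
    le <- lesion_col[c] + 0.04 * tex
    img[c, , ] <- bg * (1 - m_soft) + le * m_soft
  }
  if (cfg$noise_std > 0)
    img <- img + array(stats::rnorm(length(img), 0, cfg$noise_std), dim(img))

  # artifact layers (image only; drawn last so the artifact-free render
  # of the same seed is bit-identical up to this point)
  if (stats::runif(1) < cfg$hair_probability) {
    n_hair <- sample(2:6, 1)
    for (h in seq_len(n_hair)) {
      p0 <- stats::runif(2, 1, n); p1 <- stats::runif(2, 1, n)
      pc <- stats::runif(2, 1, n)
      tt <- seq(0, 1, length.out = 4L * n)
      pi_ <- round((1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * pc[1] + tt^2 * p1[1])
      pj <- round((1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * pc[2] + tt^2 * p1[2])
      shade <- stats::runif(1, 0.15, 0.4)
      for (off in list(c(0L, 0L), c(1L, 0L), c(0L, 1L))) {
        ii <- pi_ + off[1]; jj <- pj + off[2]
        ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n
        idx <- cbind(ii[ok], jj[ok])
        for (c in 1:3) {
          ch <- img[c, , ]
          ch[idx] <- ch[idx] * shade
          img[c, , ] <- ch
        }
      }
    }
  }
  if (stats::runif(1) < cfg$specular_probability) {
    n_spot <- sample(1:4, 1)
    for (s in seq_len(n_spot)) {
      sc <- stats::runif(2, 0.1, 0.9) * n
      rad <- stats::runif(1, 0.01, 0.03) * n
      blob <- exp(-((matrix(seq_len(n), n, n) - sc[1])^2 +
                      (matrix(seq_len(n), n, n, byrow = TRUE) - sc[2])^2) /
                    (2 * rad^2))
      for (c in 1:3) img[c, , ] <- img[c, , ] + 0.55 * blob
    }
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask,
       id = sprintf("synth_%010d", as.integer(seed)),
       area_fraction = mean(mask))
}

#' Generate and persist a synthetic dataset
#'
#' Writes `n` PNG image/mask pairs under `dir/images` and `dir/masks`
#' (8-bit RGB images; 8-bit single-channel 0/255 masks) plus a
#' `manifest.csv` with columns `id,image_path,mask_path,seed,area_fraction`.
#' Per-sample seeds are derived deterministically from `seed`.
#'
#' @param n number of samples.
#' @param cfg a [synthetic_config()].
#' @param seed master integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
generate_dataset <- function(n, cfg = synthetic_config(), seed = 1L,
                             dir = "synthetic") {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s_i <- (as.numeric(seed) * 1009 + 977 * i) %% 2147483647
    smp <- generate_sample(cfg, seed = as.integer(s_i))
    id <- sprintf("sample_%04d", i)
    ip <- file.path("images", paste0(id, ".png"))
    mp <- file.path("masks", paste0(id, "_mask.png"))
    png::writePNG(aperm(smp$image, c(2, 3, 1)), file.path(dir, ip))
    png::writePNG(smp$mask, file.path(dir, mp))
    rows[[i]] <- data.frame(id = id, image_path = ip, mask_path = mp,
                            seed = as.integer(s_i),
                            area_fraction = smp$area_fraction)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load image/mask pairs from a dataset directory or manifest
#'
#' Images are scaled to `[0, 1]`; grayscale images are promoted to three
#' identical channels; mask pixels above 127 (8-bit scale) map to 1.
#'
#' @param path dataset directory containing `manifest.csv` (as written by
#'   [generate_dataset()]) or the path of a manifest CSV itself.
#' @return list of `Sample`s (`image` `[3,H,W]`, `mask` `[H,W]`, `id`).
#' @export
load_pairs <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.csv")
                   else path
  if (!file.exists(manifest_path))
    stop("no manifest found at ", manifest_path)
  root <- dirname(manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    ip <- file.path(root, row$image_path)
    mp <- file.path(root, row$mask_path)
    if (!file.exists(ip)) stop("missing image file for id ", row$id)
    if (!file.exists(mp)) stop("missing mask file for id ", row$id)
    img <- png::readPNG(ip)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3]
    msk <- png::readPNG(mp)
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    list(image = aperm(img, c(3, 1, 2)),
         mask = (msk > 127.5 / 255) * 1,
         id = row$id)
  })
}

# ---- normalisation statistics -----------------------------------------------

#' Channel-wise mean and standard deviation of a training split
#'
#' Computed over all pixels of all samples on the `[0, 1]` scale, with a
#' population (1/n) variance so the statistics are invariant under
#' duplication of the split; standard deviations are floored at 1e-6.
#'
#' @param samples list of `Sample`s.
#' @return object of class `fg_channel_stats` with `mean` and `std`
#'   (length-3 vectors).
#' @export
compute_channel_stats <- function(samples) {
  if (length(samples) == 0L) stop("empty sample list")
  s1 <- numeric(3); s2 <- numeric(3); n <- 0
  for (s in samples) {
    for (c in 1:3) {
      v <- s$image[c, , ]
      s1[c] <- s1[c] + sum(v)
      s2[c] <- s2[c] + sum(v * v)
    }
    n <- n + length(s$image[1, , ])
  }
  m <- s1 / n
  v <- pmax(s2 / n - m^2, 0)
  structure(list(mean = m, std = pmax(sqrt(v), 1e-6)),
            class = "fg_channel_stats")
}

#' @rdname compute_channel_stats
#' @param stats an `fg_channel_stats`.
#' @param path YAML file path.
#' @export
stats_to_yaml <- function(stats, path) {
  yaml::write_yaml(list(mean = stats$mean, std = stats$std), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname compute_channel_stats
#' @export
stats_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(mean = as.numeric(x$mean), std = as.numeric(x$std)),
            class = "fg_channel_stats")
}

#' Resize and standardise a sample for the model
#'
#' The image is resized bilinearly to `size` x `size` and standardised
#' with the training-split channel statistics (`(x - mean) / std`); the
#' mask is resized with nearest-neighbour so it stays binary.
#'
#' @param s a `Sample`.
#' @param stats an `fg_channel_stats` (typically from the training split).
#' @param size output side; a warning is raised when not divisible by 16
#'   (the network will reject such inputs at forward time).
#' @return list with `x` (`[3, size, size]`, standardised) and `y`
#'   (`[size, size]`, 0/1).
#' @export
preprocess_sample <- function(s, stats, size = 256L) {
  if (size %% 16L != 0L)
    warning("size not divisible by 16; the network forward pass will reject it")
  img <- resize_pair_member(s$image, size, size)
  msk <- resize_pair_member(s$mask, size, size)
  for (c in 1:3) img[c, , ] <- (img[c, , ] - stats$mean[c]) / stats$std[c]
  list(x = img, y = msk, id = s$id)
}

# ---- splitting --------------------------------------------------------------

#' Split specification
#'
#' @param mode `"fractions"` (train/val/test) or `"kfold"`.
#' @param fractions three fractions summing to 1 (default 0.70/0.15/0.15).
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the shuffle.
#' @return an object of class `fg_split_spec`.
#' @export
split_spec <- function(mode = c("fractions", "kfold"),
                       fractions = c(0.70, 0.15, 0.15), k = 5L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "fractions" && abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  if (mode == "kfold" && k < 2L) stop("k must be at least 2")
  structure(list(mode = mode, fractions = fractions, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "fg_split_spec")
}

#' Split a dataset into train/val/test or k folds
#'
#' Fractions mode returns disjoint train/validation/test id sets covering
#' every sample (stratified within `strata` levels when labels are
#' given); k-fold mode returns `k` disjoint folds, each serving once as
#' the test set (e.g. 200 samples with `k = 5` give 160 training and 40
#' test images per round).
#'
#' @param samples list of `Sample`s or a character vector of ids.
#' @param spec a [split_spec()].
#' @param strata optional vector of labels (same length as `samples`) for
#'   stratified assignment.
#' @return fractions mode: list with `train`, `val`, `test` id vectors;
#'   kfold mode: list of `k` lists with `train` and `test` id vectors.
#' @export
split_dataset <- function(samples, spec = split_spec(), strata = NULL) {
  ids <- if (is.character(samples)) samples
         else vapply(samples, function(s) s$id, character(1))
  n <- length(ids)
  set.seed(spec$seed)
  if (spec$mode == "fractions") {
    groups <- if (is.null(strata)) list(seq_len(n))
              else split(seq_len(n), strata)
    out <- list(train = character(0), val = character(0), test = character(0))
    for (g in groups) {
      g <- sample(g)
      m <- length(g)
      n_tr <- round(spec$fractions[1] * m)
      n_va <- round(spec$fractions[2] * m)
      n_va <- min(n_va, m - n_tr)
      out$train <- c(out$train, ids[g[seq_len(n_tr)]])
      out$val <- c(out$val, ids[g[n_tr + seq_len(n_va)]])
      rest <- g[-seq_len(n_tr + n_va)]
      out$test <- c(out$test, ids[rest])
    }
    out
  } else {
    if (spec$k > n) stop("k exceeds the number of samples")
    perm <- sample(n)
    fold_of <- rep(seq_len(spec$k), length.out = n)[order(perm)]
    lapply(seq_len(spec$k), function(f)
      list(train = ids[fold_of != f], test = ids[fold_of == f]))
  }
}

#' Write/read split id lists as JSON
#' @param splits output of [split_dataset()].
#' @param path JSON file path.
#' @export
splits_to_json <- function(splits, path) {
  jsonlite::write_json(splits, path)
  invisible(path)
}

#' @rdname splits_to_json
#' @export
splits_from_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

# ---- augmentation -----------------------------------------------------------

#' Augmentation policy
#'
#' Per-transform probabilities and magnitudes of the training-time
#' augmentation pipeline: horizontal/vertical flips (p = 0.5 each),
#' rotation within ±30 degrees (p = 0.7), scaling within ±20% (p = 0.7),
#' elastic deformation (alpha = 1, sigma = 50, p = 0.5), brightness ±10%
#' (p = 0.7), contrast ±20% (p = 0.7), gamma in 0.8-1.2 (p = 0.5),
#' Gaussian noise of variance 0.01 (p = 0.3) and cutout of at most 32x32
#' pixels (p = 0.3). Geometric transforms are applied with identical
#' parameters to image and mask; photometric transforms, noise and
#' cutout touch the image only, preserving the ground truth.
#'
#' @param p_hflip,p_vflip,p_rotate,p_scale,p_elastic,p_brightness,p_contrast,p_gamma,p_noise,p_cutout per-transform probabilities.
#' @param rotate_deg,scale_frac,elastic_alpha,elastic_sigma,brightness_frac,contrast_frac,gamma_range,noise_var,cutout_max magnitudes.
#' @return an object of class `fg_aug_policy`.
#' @export
augmentation_policy <- function(p_hflip = 0.5, p_vflip = 0.5,
                                p_rotate = 0.7, rotate_deg = 30,
                                p_scale = 0.7, scale_frac = 0.2,
                                p_elastic = 0.5, elastic_alpha = 1,
                                elastic_sigma = 50,
                                p_brightness = 0.7, brightness_frac = 0.1,
                                p_contrast = 0.7, contrast_frac = 0.2,
                                p_gamma = 0.5, gamma_range = c(0.8, 1.2),
                                p_noise = 0.3, noise_var = 0.01,
                                p_cutout = 0.3, cutout_max = 32L) {
  pol <- list(p_hflip = p_hflip, p_vflip = p_vflip,
              p_rotate = p_rotate, rotate_deg = rotate_deg,
              p_scale = p_scale, scale_frac = scale_frac,
              p_elastic = p_elastic, elastic_alpha = elastic_alpha,
              elastic_sigma = elastic_sigma,
              p_brightness = p_brightness, brightness_frac = brightness_frac,
              p_contrast = p_contrast, contrast_frac = contrast_frac,
              p_gamma = p_gamma, gamma_range = gamma_range,
              p_noise = p_noise, noise_var = noise_var,
              p_cutout = p_cutout, cutout_max = as.integer(cutout_max))
  probs <- unlist(pol[startsWith(names(pol), "p_")])
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(pol, class = "fg_aug_policy")
}

#' A policy that applies no transformation
#' @return an `fg_aug_policy` with all probabilities zero (the
#'   validation/test pipeline).
#' @export
no_augmentation <- function() {
  augmentation_policy(p_hflip = 0, p_vflip = 0, p_rotate = 0, p_scale = 0,
                      p_elastic = 0, p_brightness = 0, p_contrast = 0,
                      p_gamma = 0, p_noise = 0, p_cutout = 0)
}

# rotation (degrees, counter-clockwise) + isotropic scale about the centre
affine_coords <- function(H, W, angle_deg = 0, scale = 1) {
  th <- angle_deg * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  oi <- matrix(seq_len(H), H, W) - ci
  oj <- matrix(seq_len(W), H, W, byrow = TRUE) - cj
  # inverse map: rotate by -theta and divide by scale
  si <- ci + (cos(th) * oi - sin(th) * oj) / scale
  sj <- cj + (sin(th) * oi + cos(th) * oj) / scale
  list(si = si, sj = sj)
}

elastic_coords <- function(H, W, alpha, sigma) {
  di <- smooth_gauss(matrix(stats::runif(H * W, -1, 1), H, W), sigma)
  dj <- smooth_gauss(matrix(stats::runif(H * W, -1, 1), H, W), sigma)
  nrm <- function(f) f / max(1e-8, max(abs(f)))
  si <- matrix(seq_len(H), H, W) + alpha * nrm(di)
  sj <- matrix(seq_len(W), H, W, byrow = TRUE) + alpha * nrm(dj)
  list(si = si, sj = sj)
}

apply_geometric <- function(s, co) {
  s$image <- warp_image(s$image, co$si, co$sj)
  s$mask <- sample_nearest(s$mask, co$si, co$sj)
  s
}

#' Apply the stochastic augmentation policy to a sample
#'
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @param s a `Sample` (`image` `[3,H,W]` in `[0,1]`, `mask` `[H,W]` 0/1).
#' @param policy an [augmentation_policy()].
#' @return the augmented `Sample`; the mask remains strictly binary and
#'   spatially aligned with the image.
#' @export
augment_sample <- function(s, policy = augmentation_policy()) {
  stopifnot(inherits(policy, "fg_aug_policy"))
  H <- nrow(s$mask); W <- ncol(s$mask)
  if (stats::runif(1) < policy$p_hflip) {
    s$image <- s$image[, , W:1, drop = FALSE]
    s$mask <- s$mask[, W:1, drop = FALSE]
  }
  if (stats::runif(1) < policy$p_vflip) {
    s$image <- s$image[, H:1, , drop = FALSE]
    s$mask <- s$mask[H:1, , drop = FALSE]
  }
  if (stats::runif(1) < policy$p_rotate) {
    ang <- stats::runif(1, -policy$rotate_deg, policy$rotate_deg)
    s <- apply_geometric(s, affine_coords(H, W, angle_deg = ang))
  }
  if (stats::runif(1) < policy$p_scale) {
    sc <- 1 + stats::runif(1, -policy$scale_frac, policy$scale_frac)
    s <- apply_geometric(s, affine_coords(H, W, scale = sc))
  }
  if (stats::runif(1) < policy$p_elastic) {
    s <- apply_geometric(
      s, elastic_coords(H, W, policy$elastic_alpha, policy$elastic_sigma))
  }
  if (stats::runif(1) < policy$p_brightness) {
    s$image <- s$image + stats::runif(1, -policy$brightness_frac,
                                      policy$brightness_frac)
  }
  if (stats::runif(1) < policy$p_contrast) {
    f <- 1 + stats::runif(1, -policy$contrast_frac, policy$contrast_frac)
    s$image <- (s$image - 0.5) * f + 0.5
  }
  if (stats::runif(1) < policy$p_gamma) {
    g <- stats::runif(1, policy$gamma_range[1], policy$gamma_range[2])
    s$image <- pmin(pmax(s$image, 0), 1)^g
  }
  if (stats::runif(1) < policy$p_noise) {
    s$image <- s$image +
      array(stats::rnorm(length(s$image), 0, sqrt(policy$noise_var)),
            dim(s$image))
  }
  if (stats::runif(1) < policy$p_cutout) {
    ch <- sample.int(policy$cutout_max, 1)
    cw <- sample.int(policy$cutout_max, 1)
    i0 <- sample.int(max(1L, H - ch + 1L), 1)
    j0 <- sample.int(max(1L, W - cw + 1L), 1)
    s$image[, i0:(i0 + ch - 1L), j0:(j0 + cw - 1L)] <- 0
  }
  s$image <- pmin(pmax(s$image, 0), 1)
  s
}
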