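# Synthetic generator, I/O round-trips, statistics, splitting and paired
# augmentation.

test_that("generate_sample is bitwise deterministic and honours its contract", {
  cfg <- synthetic_config(image_size = 64L)
  s1 <- generate_sample(cfg, seed = 123)
  s2 <- generate_sample(cfg, seed = 123)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  expect_equal(dim(s1$image), c(3, 64, 64))
  expect_equal(dim(s1$mask), c(64, 64))
  expect_true(all(s1$mask %in% c(0, 1)))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  s3 <- generate_sample(cfg, seed = 124)
  expect_false(identical(s1$mask, s3$mask))
})

test_that("lesion area fractions stay within the configured 1%-75% range", {
  cfg <- synthetic_config(image_size = 64L)
  fr <- vapply(1:40, function(i)
    mean(generate_sample(cfg, seed = 500 + i)$mask), numeric(1))
  expect_true(all(fr >= 0.01 & fr <= 0.75))
  expect_gt(max(fr) - min(fr), 0.1)  # the range is actually explored
})

test_that("area fractions are approximately uniform over the range", {
  cfg <- synthetic_config(image_size = 96L)
  fr <- vapply(seq_len(500), function(i)
    mean(generate_sample(cfg, seed = 9000 + i)$mask), numeric(1))
  ks <- suppressWarnings(
    stats::ks.test(fr, "punif", cfg$area_fraction_range[1],
                   cfg$area_fraction_range[2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("artifact layers touch the image only and ablate cleanly", {
  base_cfg <- synthetic_config(image_size = 64L, hair_probability = 0,
                               specular_probability = 0)
  art_cfg <- synthetic_config(image_size = 64L, hair_probability = 1,
                              specular_probability = 1)
  s0 <- generate_sample(base_cfg, seed = 7)
  s1 <- generate_sample(art_cfg, seed = 7)
  # identical geometry and mask; only the rendered image differs
  expect_identical(s0$mask, s1$mask)
  expect_false(identical(s0$image, s1$image))
  # disabling artifacts twice reproduces the same artifact-free render
  expect_identical(s0$image, generate_sample(base_cfg, seed = 7)$image)
})

test_that("generate_dataset persists PNG pairs with a complete manifest", {
  dir <- file.path(tempdir(), "fg_synth_test")
  unlink(dir, recursive = TRUE)
  cfg <- synthetic_config(image_size = 32L)
  man <- generate_dataset(10, cfg, seed = 5, dir = dir)
  expect_equal(nrow(man), 10)
  expect_length(list.files(file.path(dir, "images")), 10)
  expect_length(list.files(file.path(dir, "masks")), 10)
  expect_named(man, c("id", "image_path", "mask_path", "seed",
                      "area_fraction"))
  # deterministic manifest across runs
  dir2 <- file.path(tempdir(), "fg_synth_test2")
  unlink(dir2, recursive = TRUE)
  man2 <- generate_dataset(10, cfg, seed = 5, dir = dir2)
  expect_equal(man$seed, man2$seed)
  expect_equal(man$area_fraction, man2$area_fraction)
  # round-trip: masks are reproduced exactly, images to 8-bit precision
  pairs <- load_pairs(dir)
  expect_length(pairs, 10)
  src <- generate_sample(cfg, seed = man$seed[3])
  expect_equal(pairs[[3]]$mask, src$mask)
  expect_lt(max(abs(pairs[[3]]$image - src$image)), 1 / 255)
  unlink(dir, recursive = TRUE); unlink(dir2, recursive = TRUE)
})

test_that("load_pairs maps 8-bit masks to binary and errors on missing files", {
  dir <- file.path(tempdir(), "fg_load_test")
  unlink(dir, recursive = TRUE)
  dir.create(file.path(dir, "images"), recursive = TRUE)
  dir.create(file.path(dir, "masks"), recursive = TRUE)
  img <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  png::writePNG(img, file.path(dir, "images", "a.png"))
  msk <- matrix(c(0, 100 / 255, 128 / 255, 1), 4, 4)
  png::writePNG(msk, file.path(dir, "masks", "a_mask.png"))
  man <- data.frame(id = "a", image_path = "images/a.png",
                    mask_path = "masks/a_mask.png", seed = 0,
                    area_fraction = 0)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  p <- load_pairs(dir)[[1]]
  expect_true(all(p$mask %in% c(0, 1)))
  expect_equal(p$mask[3, 1], 1)  # 128 > 127 -> foreground
  expect_equal(p$mask[2, 1], 0)  # 100 -> background
  # grayscale image promotes to three identical channels
  png::writePNG(matrix(stats::runif(64), 8, 8),
                file.path(dir, "images", "g.png"))
  png::writePNG(matrix(1, 8, 8), file.path(dir, "masks", "g_mask.png"))
  man <- rbind(man, data.frame(id = "g", image_path = "images/g.png",
                               mask_path = "masks/g_mask.png", seed = 0,
                               area_fraction = 1))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  pg <- load_pairs(dir)[[2]]
  expect_equal(dim(pg$image), c(3, 8, 8))
  expect_equal(pg$image[1, , ], pg$image[3, , ])
  # missing mask names the id
  man$mask_path[2] <- "masks/missing.png"
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_error(load_pairs(dir), "g")
  unlink(dir, recursive = TRUE)
})

test_that("channel statistics are exact, guarded and duplication-invariant", {
  flat <- list(image = array(0.5, c(3, 8, 8)), mask = matrix(0, 8, 8),
               id = "flat")
  st <- compute_channel_stats(list(flat))
  expect_equal(st$mean, rep(0.5, 3))
  expect_equal(st$std, rep(1e-6, 3))  # epsilon floor on constant input
  set.seed(31)
  samples <- lapply(1:4, function(i)
    list(image = array(stats::runif(3 * 8 * 8), c(3, 8, 8)),
         mask = matrix(0, 8, 8), id = as.character(i)))
  s1 <- compute_channel_stats(samples)
  s2 <- compute_channel_stats(c(samples, samples))
  expect_equal(s1$mean, s2$mean, tolerance = 1e-12)
  expect_equal(s1$std, s2$std, tolerance = 1e-12)
  expect_error(compute_channel_stats(list()), "empty")
  # YAML round-trip
  tmp <- tempfile(fileext = ".yaml")
  stats_to_yaml(s1, tmp)
  back <- stats_from_yaml(tmp)
  expect_equal(back$mean, s1$mean, tolerance = 1e-9)
})

test_that("preprocessing resizes, standardises and keeps masks binary", {
  set.seed(32)
  s <- list(image = array(stats::runif(3 * 70 * 56), c(3, 70, 56)),
            mask = matrix(stats::rbinom(70 * 56, 1, 0.3), 70, 56),
            id = "odd")
  st <- compute_channel_stats(list(s))
  p <- preprocess_sample(s, st, size = 32L)
  expect_equal(dim(p$x), c(3, 32, 32))
  expect_equal(dim(p$y), c(32, 32))
  expect_true(all(p$y %in% c(0, 1)))
  expect_warning(preprocess_sample(s, st, size = 30L), "divisible")
  # standardising the defining split recentres it
  samples <- lapply(1:5, function(i) {
    set.seed(40 + i)
    list(image = array(stats::runif(3 * 32 * 32), c(3, 32, 32)),
         mask = matrix(0, 32, 32), id = as.character(i))
  })
  st <- compute_channel_stats(samples)
  pp <- lapply(samples, preprocess_sample, stats = st, size = 32L)
  for (c in 1:3) {
    vals <- unlist(lapply(pp, function(p) p$x[c, , ]))
    expect_lt(abs(mean(vals)), 0.05)
    expect_lt(abs(stats::sd(vals) - 1), 0.05)
  }
})

test_that("fraction splits partition the ids 70/15/15", {
  ids <- sprintf("s%03d", 1:200)
  sp <- split_dataset(ids, split_spec("fractions", seed = 3))
  expect_length(sp$train, 140)
  expect_length(sp$val, 30)
  expect_length(sp$test, 30)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  # same seed -> identical assignment
  sp2 <- split_dataset(ids, split_spec("fractions", seed = 3))
  expect_identical(sp, sp2)
  # stratified mode balances within strata
  strata <- rep(c("a", "b"), each = 100)
  sps <- split_dataset(ids, split_spec("fractions", seed = 4), strata = strata)
  expect_equal(sum(sps$train %in% ids[1:100]), 70)
})

test_that("5-fold cross-validation yields 160/40 folds serving once as test", {
  ids <- sprintf("p%03d", 1:200)
  folds <- split_dataset(ids, split_spec("kfold", k = 5, seed = 9))
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(f$train, 160)
    expect_length(f$test, 40)
    expect_length(intersect(f$train, f$test), 0)
  }
  # every id appears in exactly one test fold
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_length(all_test, 200)
  expect_error(split_dataset(ids[1:3], split_spec("kfold", k = 5)), "exceeds")
  # JSON round-trip
  tmp <- tempfile(fileext = ".json")
  splits_to_json(folds, tmp)
  back <- splits_from_json(tmp)
  expect_equal(back[[1]]$test, folds[[1]]$test)
})

test_that("zero-probability augmentation is the identity", {
  s <- generate_sample(synthetic_config(image_size = 32L), seed = 3)
  set.seed(1)
  a <- augment_sample(s, no_augmentation())
  expect_equal(a$image, s$image)
  expect_identical(a$mask, s$mask)
})

test_that("geometric transforms move image and mask together", {
  s <- generate_sample(synthetic_config(image_size = 32L), seed = 4)
  # forced horizontal flip mirrors both members identically
  pol <- augmentation_policy(p_hflip = 1, p_vflip = 0, p_rotate = 0,
                             p_scale = 0, p_elastic = 0, p_brightness = 0,
                             p_contrast = 0, p_gamma = 0, p_noise = 0,
                             p_cutout = 0)
  set.seed(2)
  a <- augment_sample(s, pol)
  expect_equal(a$image, s$image[, , 32:1])
  expect_identical(a$mask, s$mask[, 32:1])
  # forced rotation keeps the mask binary and aligned with an
  # independently transformed copy
  polr <- augmentation_policy(p_hflip = 0, p_vflip = 0, p_rotate = 1,
                              p_scale = 0, p_elastic = 0, p_brightness = 0,
                              p_contrast = 0, p_gamma = 0, p_noise = 0,
                              p_cutout = 0)
  set.seed(7)
  ar <- augment_sample(s, polr)
  expect_true(all(ar$mask %in% c(0, 1)))
  # independently replay the RNG draws and transform the mask alone
  set.seed(7)
  stats::runif(3)  # hflip, vflip and rotate acceptance draws
  ang <- stats::runif(1, -30, 30)
  co <- focusgate:::affine_coords(32, 32, angle_deg = ang)
  expect_identical(ar$mask, focusgate:::sample_nearest(s$mask, co$si, co$sj))
})

test_that("photometric transforms, noise and cutout leave the mask untouched", {
  s <- generate_sample(synthetic_config(image_size = 32L), seed = 5)
  pol <- augmentation_policy(p_hflip = 0, p_vflip = 0, p_rotate = 0,
                             p_scale = 0, p_elastic = 0, p_brightness = 1,
                             p_contrast = 1, p_gamma = 1, p_noise = 1,
                             p_cutout = 1)
  set.seed(3)
  a <- augment_sample(s, pol)
  expect_identical(a$mask, s$mask)
  expect_false(identical(a$image, s$image))
  expect_true(all(a$image >= 0 & a$image <= 1))
  # cutout zeroes a rectangle of bounded size
  polc <- augmentation_policy(p_hflip = 0, p_vflip = 0, p_rotate = 0,
                              p_scale = 0, p_elastic = 0, p_brightness = 0,
                              p_contrast = 0, p_gamma = 0, p_noise = 0,
                              p_cutout = 1, cutout_max = 8L)
  set.seed(4)
  ac <- augment_sample(s, polc)
  zeros <- which(ac$image[1, , ] == 0 & s$image[1, , ] != 0, arr.ind = TRUE)
  expect_gt(nrow(zeros), 0)
  expect_lte(diff(range(zeros[, 1])) + 1, 8)
  expect_lte(diff(range(zeros[, 2])) + 1, 8)
})

test_that("elastic deformation preserves binary labels and stays small", {
  s <- generate_sample(synthetic_config(image_size = 32L), seed = 6)
  pol <- augmentation_policy(p_hflip = 0, p_vflip = 0, p_rotate = 0,
                             p_scale = 0, p_elastic = 1, p_brightness = 0,
                             p_contrast = 0, p_gamma = 0, p_noise = 0,
                             p_cutout = 0)
  set.seed(5)
  a <- augment_sample(s, pol)
  expect_true(all(a$mask %in% c(0, 1)))
  # alpha = 1: displacement at most one pixel, so mask area barely moves
  expect_lt(abs(mean(a$mask) - mean(s$mask)), 0.02)
})
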