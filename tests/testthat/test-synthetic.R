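test_that("generation is a pure function of profile and seed", {
  prof <- synthetic_profile(image_size = 48)
  s1 <- generate_sample(prof, 5)
  s2 <- generate_sample(prof, 5)
  expect_identical(s1, s2)
  s3 <- generate_sample(prof, 6)
  expect_false(identical(s1$image, s3$image))
})

test_that("masks are binary, inside the leaf, and near the drawn target", {
  prof <- synthetic_profile(image_size = 64)
  for (seed in 1:12) {
    s <- generate_sample(prof, seed)
    expect_true(all(s$mask %in% c(0, 1)))
    expect_true(all(s$mask[!s$leaf] == 0)) # lesion support inside the leaf
    expect_lte(abs(s$proportion - s$target_proportion) / s$target_proportion,
               0.1)
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
})

test_that("boundary fuzz softens the image gradient at the mask rim", {
  p0 <- synthetic_profile(image_size = 64, fuzz_width = 0, noise_sd = 0,
                          illumination_gradient = FALSE)
  p8 <- synthetic_profile(image_size = 64, fuzz_width = 8, noise_sd = 0,
                          illumination_gradient = FALSE)
  rim_grad <- function(s) {
    gray <- (s$image[, , 1] + s$image[, , 2] + s$image[, , 3]) / 3
    gx <- gray[, -1] - gray[, -ncol(gray)]
    gy <- gray[-1, ] - gray[-nrow(gray), ]
    gmag <- sqrt(gx[-nrow(gx), ]^2 + gy[, -ncol(gy)]^2)
    m <- s$mask == 1
    er <- m
    er[-1, ] <- er[-1, ] & m[-nrow(m), ]; er[-nrow(m), ] <- er[-nrow(m), ] & m[-1, ]
    er[, -1] <- er[, -1] & m[, -ncol(m)]; er[, -ncol(m)] <- er[, -ncol(m)] & m[, -1]
    rim <- m & !er
    mean(gmag[rim[-nrow(rim), -ncol(rim)]])
  }
  s0 <- generate_sample(p0, 3)
  s8 <- generate_sample(p8, 3)
  expect_identical(s0$mask, s8$mask) # fuzz affects the image only
  expect_gt(rim_grad(s0), rim_grad(s8))
})

test_that("dataset layout, splits and manifest are consistent", {
  prof <- synthetic_profile(image_size = 32, n_images = 10, seed = 2)
  dir <- tempfile()
  man <- generate_dataset(prof, dir)
  counts <- vapply(c("train", "val", "test"), function(s) {
    length(list.files(file.path(dir, s, "images")))
  }, 1)
  expect_equal(unname(counts), c(6, 2, 2)) # 60 / 20 / 20
  expect_error(generate_dataset(prof, dir), "not empty")
  # manifest proportions match the masks on disk exactly
  for (e in man$images) {
    mk <- png::readPNG(file.path(dir, e$split, "masks", paste0(e$file, ".png")))
    expect_equal(mean(mk), e$proportion)
  }
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # a different seed gives different imagery
  dir2 <- tempfile()
  generate_dataset(synthetic_profile(image_size = 32, n_images = 10, seed = 3),
                   dir2)
  f1 <- file.path(dir, "train", "images", "img_0001.png")
  f2 <- file.path(dir2, "train", "images", "img_0001.png")
  expect_false(identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6)))
})

test_that("lesion statistics summarize proportions correctly", {
  dir <- tempfile(); dir.create(dir)
  # masks with exact proportions 0.1, 0.2, 0.3 on a 10x10 grid
  for (i in 1:3) {
    m <- matrix(0, 10, 10); m[seq_len(i * 10)] <- 1
    png::writePNG(m, file.path(dir, sprintf("m%d.png", i)))
  }
  st <- lesion_stats(dir)
  expect_equal(st$mean, 20)
  expect_equal(st$median, 20)
  expect_equal(st$std, 10)
  expect_equal(st$n, 3)
  expect_equal(sum(st$histogram$counts), 3)
  # all-background masks
  dir0 <- tempfile(); dir.create(dir0)
  for (i in 1:3) png::writePNG(matrix(0, 6, 6), file.path(dir0, sprintf("z%d.png", i)))
  st0 <- lesion_stats(dir0)
  expect_equal(c(st0$mean, st0$median, st0$std), c(0, 0, 0))
  expect_error(lesion_stats(tempfile()), "no masks")
  png::writePNG(matrix(0.37, 4, 4), file.path(dir, "bad.png"))
  expect_error(lesion_stats(dir), "not binary.*bad\\.png")
})

test_that("proportions follow the truncated lognormal (quadrature oracle)", {
  prof <- synthetic_profile(prop_meanlog = -2, prop_sdlog = 0.9)
  lo <- prof$prop_range[1]; hi <- prof$prop_range[2]
  dens <- function(x) stats::dlnorm(x, -2, 0.9)
  Z <- stats::integrate(dens, lo, hi)$value
  mu_true <- stats::integrate(function(x) x * dens(x), lo, hi)$value / Z
  set.seed(7)
  draws <- draw_lesion_proportion(prof, 1000)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu_true), 3 * se)
  expect_true(all(draws > lo & draws < hi))
  # achieved mask proportions track the same distribution
  ns <- asNamespace("gardenseg")
  props <- vapply(1:300, function(i) {
    mean(ns$generate_mask_only(prof, seed = 7000 + i))
  }, numeric(1))
  se2 <- stats::sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - mu_true), 3 * se2)
})

test_that("the default profile reproduces the right-skew signature", {
  ns <- asNamespace("gardenseg")
  prof <- synthetic_profile()
  props <- vapply(1:500, function(i) {
    mean(ns$generate_mask_only(prof, seed = 20000 + i))
  }, numeric(1))
  expect_gt(mean(props), stats::median(props)) # mean above median
})

test_that("proportion statistics are invariant to nearest-neighbour upscaling", {
  prof <- synthetic_profile(image_size = 32, n_images = 6, seed = 4)
  dir <- tempfile()
  generate_dataset(prof, dir, overwrite = TRUE)
  mdir <- file.path(dir, "train", "masks")
  up <- tempfile(); dir.create(up)
  for (f in list.files(mdir, full.names = TRUE)) {
    m <- png::readPNG(f)
    m2 <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
    png::writePNG(m2, file.path(up, basename(f)))
  }
  expect_equal(lesion_stats(up)$proportions, lesion_stats(mdir)$proportions)
})

test_that("generated datasets feed the training pipeline unmodified", {
  dir <- make_tiny_dataset(n = 10, size = 32, seed = 61)
  res <- run_training(tiny_model_cfg(32),
                      train_config(epochs = 1, image_size = 32, seed = 1),
                      dir, tempfile())
  expect_equal(nrow(res$log), 1)
  expect_true(is.finite(res$log$train_loss))
})
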