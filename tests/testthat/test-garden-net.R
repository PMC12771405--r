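small_cfg <- function(size = 64, pools = c(1, 2, 3)) {
  garden_config(base_width = 8, msca = msca_config(pools),
                ssm_state_size = 4, image_size = size)
}

test_that("configuration validation catches invalid settings", {
  expect_error(garden_config(image_size = 100), "divisible by 16")
  expect_error(garden_config(image_size = 64), "exceeds") # pool 6 at a 4x4 bottleneck
  expect_error(garden_config(ggbp_kernel = 4), "3 or 5")
  cfg <- small_cfg()
  expect_equal(cfg$depth, 4L)
})

test_that("encoder widths double while spatial dims halve", {
  model <- build_garden(small_cfg())
  widths <- vapply(model$down, function(d) dim(d$convs[[1]]$w$value)[4], 1)
  expect_equal(dim(model$stem$convs[[1]]$w$value)[4], 8)
  expect_equal(widths, c(16, 32, 64, 128))
  x <- array(runif(64 * 64 * 3 * 1), dim = c(64, 64, 3, 1))
  fw <- garden_forward(model, x)
  expect_equal(fw$bottleneck_shape, c(4, 4))
})

test_that("forward pass honours the shape and range contract", {
  set.seed(18)
  model <- build_garden(small_cfg())
  x <- array(runif(64 * 64 * 3 * 2), dim = c(64, 64, 3, 2))
  fw <- garden_forward(model, x)
  expect_equal(dim(fw$probs), c(64, 64, 1, 2))
  expect_true(all(fw$probs > 0 & fw$probs < 1))
  # all-zero input on a fresh model: finite output, no NaNs
  fz <- garden_forward(model, array(0, dim = c(64, 64, 3, 1)))
  expect_true(all(is.finite(fz$probs)))
  # spatial round-trip at a second, non-square-power size
  m96 <- build_garden(small_cfg(96, pools = c(1, 2, 3, 6)))
  f96 <- garden_forward(m96, array(runif(96 * 96 * 3), dim = c(96, 96, 3, 1)))
  expect_equal(dim(f96$probs)[1:2], c(96, 96))
  expect_equal(f96$bottleneck_shape, c(6, 6))
  expect_error(garden_forward(model, array(0, dim = c(64, 64, 4, 1))),
               "3 input channels")
  expect_error(garden_forward(model, array(0, dim = c(60, 60, 3, 1))),
               "divisible by 16")
})

test_that("evaluation is deterministic and batch-independent", {
  set.seed(19)
  model <- build_garden(small_cfg())
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  batch <- array(0, dim = c(64, 64, 3, 3))
  for (i in 1:3) batch[, , , i] <- img # duplicated image
  fw <- garden_forward(model, batch)
  expect_identical(fw$probs[, , , 1], fw$probs[, , , 2])
  expect_identical(fw$probs[, , , 1], fw$probs[, , , 3])
  fw2 <- garden_forward(model, batch)
  expect_identical(fw$probs, fw2$probs) # bitwise reproducible
})

test_that("adding a pyramid branch strictly increases the parameter count", {
  cfg_a <- garden_config(base_width = 8, ssm_state_size = 4,
                         msca = msca_config(c(1, 2, 3), branch_channels = 32),
                         image_size = 224)
  cfg_b <- garden_config(base_width = 8, ssm_state_size = 4,
                         msca = msca_config(c(1, 2, 3, 6), branch_channels = 32),
                         image_size = 224)
  ns <- asNamespace("gardenseg")
  expect_gt(ns$n_parameters(build_garden(cfg_b)),
            ns$n_parameters(build_garden(cfg_a)))
})

test_that("channel-wise cross-attention scales the skip as specified", {
  set.seed(20)
  C <- 6
  p <- cca_params(C)
  skip <- array(rnorm(C * 5 * 5), dim = c(C, 5, 5))
  dec <- array(rnorm(C * 5 * 5), dim = c(C, 5, 5))
  expect_identical(cca_refine(skip, dec, p, weights_override = rep(1, C)), skip)
  w0 <- rep(1, C); w0[3] <- 0
  out <- cca_refine(skip, dec, p, weights_override = w0)
  expect_true(all(out[3, , ] == 0))
  expect_identical(out[-3, , ], skip[-3, , ])
  # constant skip per channel stays constant, scaled by the learned weight
  cs <- array(rep(1:C, times = 25), dim = c(C, 5, 5))
  outc <- cca_refine(cs, dec, p)
  expect_true(all(apply(outc, 1, function(ch) max(ch) - min(ch)) < 1e-12))
  expect_true(all(outc / cs > 0 & outc / cs < 1)) # sigmoid weights
  expect_error(cca_refine(skip, dec[, 1:3, ], p), "spatially aligned")
})

test_that("at initialization the network equals its scan-free ablation", {
  ns <- asNamespace("gardenseg")
  set.seed(21)
  model <- build_garden(small_cfg())
  x <- ns$standardize_images(array(runif(64 * 64 * 3 * 2), dim = c(64, 64, 3, 2)))
  f1 <- ns$garden_fwd(model, ns$gdt(x))
  f2 <- ns$garden_fwd(model, ns$gdt(x), skip_bass = TRUE)
  expect_identical(ns$gd_value(f1$logits), ns$gd_value(f2$logits))
})

test_that("checkpoints round-trip parameters and configuration", {
  set.seed(22)
  model <- build_garden(small_cfg())
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3, 1))
  p1 <- garden_forward(model, x)$probs
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path, extra = list(note = "round-trip"))
  ck <- load_checkpoint(path)
  expect_equal(ck$extra$note, "round-trip")
  expect_identical(garden_forward(ck$model, x)$probs, p1)
})
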