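test_that("confusion counting is exact", {
  gt <- matrix(0, 10, 10); gt[1:2, 1:5] <- 1 # |gt| = 10
  pred <- matrix(0, 10, 10); pred[1:2, 1:4] <- 1; pred[3, 1:2] <- 1
  cc <- confusion_counts(pred, gt)
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")],
               list(TP = 8, FP = 2, FN = 2, TN = 88))
  ci <- confusion_counts(gt, gt)
  expect_equal(ci$FP + ci$FN, 0)
  expect_equal(ci$TP, 10)
  disj <- matrix(0, 10, 10); disj[9:10, 9:10] <- 1
  expect_equal(confusion_counts(disj, gt)$TP, 0)
  expect_error(confusion_counts(pred, gt * 0.5), "not binary")
})

test_that("metric formulas and the Dice/IoU identity hold", {
  m <- compute_metrics(structure(list(TP = 8, FP = 2, FN = 2, TN = 88),
                                 class = "confusion_counts"))
  expect_equal(m$dice, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$accuracy, 0.96)
  expect_equal(m$iou_fg, 2 / 3, tolerance = 1e-4)
  expect_equal(m$specificity, 88 / 90)
  expect_equal(m$miou, (2 / 3 + 88 / 92) / 2)
  # perfect prediction: everything 1
  mp <- compute_metrics(structure(list(TP = 5, FP = 0, FN = 0, TN = 95),
                                  class = "confusion_counts"))
  expect_true(all(unlist(mp) == 1))
  # dice = 2 IoU / (1 + IoU) on random mask pairs
  set.seed(23)
  for (i in 1:100) {
    a <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8)
    b <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8)
    mm <- compute_metrics(confusion_counts(a, b))
    expect_equal(mm$dice, 2 * mm$iou_fg / (1 + mm$iou_fg), tolerance = 1e-12)
  }
})

test_that("loss terms match their closed forms", {
  t1 <- matrix(c(1, 1, 0, 0), 2)
  l1 <- matrix(c(20, 20, -20, -20), 2)
  expect_lt(dice_loss_with_logits(l1, t1), 1e-6)
  expect_lt(combined_loss(l1, t1), 1e-6)
  # p ~ 0 against n positives: loss ~ n / (n + 1)
  n <- 36
  expect_equal(dice_loss_with_logits(matrix(-20, 6, 6), matrix(1, 6, 6)),
               n / (n + 1), tolerance = 1e-6)
  # logits 0 on 100 positive pixels: 1 - 101/151
  expect_equal(dice_loss_with_logits(matrix(0, 10, 10), matrix(1, 10, 10)),
               1 - 101 / 151, tolerance = 1e-12)
  expect_equal(dice_loss_with_logits(matrix(0, 10, 10), matrix(1, 10, 10)),
               0.3311, tolerance = 1e-4)
  # balanced target at logits 0: CE term is log(2)
  tb <- matrix(c(1, 0), 4, 4)
  z0 <- matrix(0, 4, 4)
  expect_equal(combined_loss(z0, tb),
               0.5 * dice_loss_with_logits(z0, tb) + 0.5 * log(2),
               tolerance = 1e-12)
  expect_error(dice_loss_with_logits(matrix(0, 2, 2), matrix(1, 3, 3)),
               "shape mismatch")
})

test_that("plateau schedule halves after patience non-improving epochs", {
  cfg <- train_config()
  expect_equal(scheduler_step(rep(1, 11), 1e-4, cfg), 5e-5)
  expect_equal(scheduler_step(seq(1, 0.5, length.out = 30), 1e-4, cfg), 1e-4)
  # two successive plateaus (improvement in between) give two halvings
  hist <- c(rep(1, 11), rep(0.9, 11))
  expect_equal(scheduler_step(hist, 1e-4, cfg), 2.5e-5)
  # an improvement resets the counter
  hist2 <- c(rep(1, 9), 0.95, rep(0.95, 9))
  expect_equal(scheduler_step(hist2, 1e-4, cfg), 1e-4)
})

test_that("global-count metric accumulation equals pooled evaluation", {
  set.seed(24)
  preds <- lapply(1:4, function(i) matrix(rbinom(100, 1, 0.3), 10))
  gts <- lapply(1:4, function(i) matrix(rbinom(100, 1, 0.3), 10))
  acc <- structure(list(TP = 0, FP = 0, FN = 0, TN = 0),
                   class = "confusion_counts")
  for (i in 1:4) acc <- add_counts(acc, confusion_counts(preds[[i]], gts[[i]]))
  pooled <- confusion_counts(do.call(cbind, preds), do.call(cbind, gts))
  expect_equal(compute_metrics(acc), compute_metrics(pooled))
})

test_that("mask and pairing validation report the offending files", {
  dir <- tempfile()
  dir.create(file.path(dir, "train", "images"), recursive = TRUE)
  dir.create(file.path(dir, "train", "masks"), recursive = TRUE)
  png::writePNG(array(0.5, dim = c(8, 8, 3)),
                file.path(dir, "train", "images", "a.png"))
  png::writePNG(array(0.5, dim = c(8, 8, 3)),
                file.path(dir, "train", "images", "b.png"))
  png::writePNG(matrix(0, 8, 8), file.path(dir, "train", "masks", "a.png"))
  expect_error(load_split(dir, "train"), "b")
  png::writePNG(matrix(0.4, 8, 8), file.path(dir, "train", "masks", "b.png"))
  expect_error(load_split(dir, "train"), "not binary.*b\\.png")
})

test_that("a short optimization run logs, checkpoints, and resumes exactly", {
  dir <- make_tiny_dataset(n = 15, size = 32, seed = 31)
  cfg <- tiny_model_cfg(32)
  out1 <- tempfile(); out2 <- tempfile()
  t3 <- train_config(epochs = 3, image_size = 32, seed = 7, batch_size = 4)
  res3 <- run_training(cfg, t3, dir, out1)
  expect_equal(nrow(res3$log), 3) # one row per epoch
  expect_true(file.exists(res3$best_path) && file.exists(res3$last_path))

  # two epochs, then resume for the third: identical trajectory
  t2 <- train_config(epochs = 2, image_size = 32, seed = 7, batch_size = 4)
  res2 <- run_training(cfg, t2, dir, out2)
  res23 <- run_training(cfg, t3, dir, out2, resume_from = res2$last_path)
  expect_equal(nrow(res23$log), 3)
  expect_equal(res23$log$train_loss[3], res3$log$train_loss[3],
               tolerance = 1e-4)
  # evaluation of a checkpoint is deterministic
  m1 <- evaluate_model(res3$best_path, dir, "val")
  m2 <- evaluate_model(res3$best_path, dir, "val")
  expect_identical(m1, m2)
})

test_that("training loss descends smoothly over the first epochs", {
  dir <- make_tiny_dataset(n = 40, size = 32, seed = 41)
  # enough capacity and data for the descent to dominate batch noise
  cfg <- garden_config(base_width = 8, msca = msca_config(c(1, 2)),
                       ssm_state_size = 8, image_size = 32)
  drops <- vapply(1:5, function(s) {
    res <- run_training(cfg, train_config(epochs = 5, image_size = 32,
                                          seed = s, batch_size = 8),
                        dir, tempfile())
    all(diff(res$log$train_loss) < 0)
  }, logical(1))
  expect_gte(sum(drops), 4) # monotone descent in at least 4 of 5 seeds
})

test_that("prediction writes a two-valued mask at native resolution", {
  set.seed(25)
  dir <- make_tiny_dataset(n = 5, size = 32, seed = 51)
  model <- build_garden(tiny_model_cfg(32))
  img <- file.path(dir, "train", "images", list.files(file.path(dir, "train", "images"))[1])
  # non-square, non-divisible native size
  odd <- tempfile(fileext = ".png")
  png::writePNG(resize_bilinear(gardenseg:::read_image_rgb(img), 45, 37), odd)
  outp <- tempfile(fileext = ".png")
  predict_mask(model, odd, outp)
  written <- png::readPNG(outp)
  expect_equal(dim(written), c(45, 37))
  expect_lte(length(unique(as.numeric(written))), 2)
  expect_true(all(written %in% c(0, 1))) # 0 / 255 in the 8-bit file
})
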