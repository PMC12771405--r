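#' Pixel confusion counts
#'
#' @param pred Binary predicted mask (values in \{0, 1\}); typically
#'   probabilities thresholded at 0.5.
#' @param gt Binary ground-truth mask of the same shape.
#' @return List of class `confusion_counts` with TP, FP, FN, TN.
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(length(pred), length(gt))) {
    stop("confusion_counts: shape mismatch")
  }
  if (!all(gt %in% c(0, 1))) {
    stop("confusion_counts: ground-truth mask is not binary")
  }
  if (!all(pred %in% c(0, 1))) {
    stop("confusion_counts: predicted mask is not binary")
  }
  p <- as.logical(pred); g <- as.logical(gt)
  structure(list(TP = sum(p & g), FP = sum(p & !g),
                 FN = sum(!p & g), TN = sum(!p & !g)),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param a,b `confusion_counts` to accumulate (global-count aggregation).
#' @export
add_counts <- function(a, b) {
  structure(list(TP = a$TP + b$TP, FP = a$FP + b$FP,
                 FN = a$FN + b$FN, TN = a$TN + b$TN),
            class = "confusion_counts")
}

ratio1 <- function(num, den) if (den == 0) 1 else num / den

#' Segmentation metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FP+FN); precision, recall, specificity, accuracy as
#' usual; mIoU is the mean of the foreground IoU TP/(TP+FP+FN) and the
#' background IoU TN/(TN+FP+FN). Degenerate 0/0 ratios are defined as 1.
#'
#' @param counts A `confusion_counts`.
#' @return List of class `metrics_report` with accuracy, dice, precision,
#'   specificity, recall, miou, iou_fg (all in `[0, 1]`).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  iou_fg <- ratio1(TP, TP + FP + FN)
  iou_bg <- ratio1(TN, TN + FP + FN)
  structure(list(
    accuracy = ratio1(TP + TN, TP + FP + FN + TN),
    dice = ratio1(2 * TP, 2 * TP + FP + FN),
    precision = ratio1(TP, TP + FP),
    specificity = ratio1(TN, TN + FP),
    recall = ratio1(TP, TP + FN),
    iou_fg = iou_fg,
    miou = (iou_fg + iou_bg) / 2
  ), class = "metrics_report")
}

#' Dice loss on logits
#'
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with
#' `p = sigmoid(logits)` and smoothing `eps = 1`.
#'
#' @param logits,target Arrays of identical shape; target binary.
#' @return Scalar loss.
#' @export
dice_loss_with_logits <- function(logits, target) {
  if (!identical(length(logits), length(target))) {
    stop("dice_loss_with_logits: shape mismatch")
  }
  p <- stable_sigmoid(logits)
  1 - (2 * sum(p * target) + 1) / (sum(p) + sum(target) + 1)
}

#' Combined segmentation loss
#'
#' Weighted sum of the Dice loss and pixelwise binary cross-entropy, both
#' computed on logits; default weights 0.5 / 0.5.
#'
#' @param logits,target Arrays of identical shape; target binary.
#' @param weights Length-2 weights for (dice, cross-entropy).
#' @return Scalar loss.
#' @export
combined_loss <- function(logits, target, weights = c(0.5, 0.5)) {
  ce <- mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
  weights[1] * dice_loss_with_logits(logits, target) + weights[2] * ce
}

#' Training configuration
#'
#' Defaults follow the training protocol: Adam at 1e-4, batch size 8,
#' 100 epochs, 224px inputs, equal-weight Dice + cross-entropy, and a
#' reduce-on-plateau schedule halving the learning rate after 10
#' non-improving validation epochs.
#'
#' @param lr,batch_size,epochs,scheduler_factor,scheduler_patience,image_size
#'   See description.
#' @param loss_weights Length-2 weights for (dice, cross-entropy).
#' @param seed Integer seed controlling initialization and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 8, epochs = 100,
                         scheduler_factor = 0.5, scheduler_patience = 10,
                         image_size = 224, loss_weights = c(0.5, 0.5),
                         seed = 0) {
  stopifnot(scheduler_factor > 0, scheduler_factor < 1, scheduler_patience >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 image_size = as.integer(image_size),
                 loss_weights = loss_weights, seed = as.integer(seed)),
            class = "train_config")
}

#' Reduce-on-plateau learning-rate rule
#'
#' The learning rate is multiplied by `scheduler_factor` once the validation
#' loss has gone `scheduler_patience` consecutive epochs without strict
#' improvement over the best value seen so far (the counter resets after
#' each reduction).
#'
#' @param val_loss_history Numeric vector of per-epoch validation losses.
#' @param current_lr Learning rate at the start of the history.
#' @param cfg A [train_config()] (factor and patience are used).
#' @return The learning rate after the last epoch in the history.
#' @examples
#' scheduler_step(rep(1, 11), 1e-4, train_config()) # 5e-5
#' @export
scheduler_step <- function(val_loss_history, current_lr, cfg = train_config()) {
  stopifnot(length(val_loss_history) >= 1)
  st <- plateau_state(current_lr, cfg$scheduler_factor, cfg$scheduler_patience)
  for (v in val_loss_history) plateau_update(st, v)
  st$lr
}

plateau_state <- function(lr, factor, patience) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$factor <- factor; e$patience <- patience
  e$best <- Inf; e$bad <- 0L
  e
}

plateau_update <- function(st, val_loss) {
  if (val_loss < st$best) {
    st$best <- val_loss
    st$bad <- 0L
  } else {
    st$bad <- st$bad + 1L
    if (st$bad >= st$patience) {
      st$lr <- st$lr * st$factor
      st$bad <- 0L
    }
  }
  st$lr
}

# ---------------------------------------------------------------------------
# Dataset I/O
# ---------------------------------------------------------------------------

list_stems <- function(dir) {
  fs <- list.files(dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE)
  stats::setNames(fs, sub("\\.[^.]+$", "", fs))
}

#' Load one split of a segmentation dataset
#'
#' Expects `<data_dir>/<split>/images/*.png` and matching
#' `<data_dir>/<split>/masks/*.png` with identical file stems; masks must be
#' binary after loading.
#'
#' @param data_dir Dataset root.
#' @param split Split name ("train", "val" or "test").
#' @return List with `images` (list of (H,W,3) arrays in `[0,1]`), `masks`
#'   (list of (H,W) binary matrices) and `stems`.
#' @export
load_split <- function(data_dir, split) {
  idir <- file.path(data_dir, split, "images")
  mdir <- file.path(data_dir, split, "masks")
  if (!dir.exists(idir) || !dir.exists(mdir)) {
    stop("load_split: missing images/ or masks/ under ", file.path(data_dir, split))
  }
  im <- list_stems(idir); mk <- list_stems(mdir)
  only_i <- setdiff(names(im), names(mk))
  only_m <- setdiff(names(mk), names(im))
  if (length(only_i) || length(only_m)) {
    stop("load_split: image/mask pairing mismatch; unmatched images: [",
         paste(only_i, collapse = ", "), "]; unmatched masks: [",
         paste(only_m, collapse = ", "), "]")
  }
  stems <- sort(names(im))
  images <- lapply(stems, function(s) read_image_rgb(file.path(idir, im[[s]])))
  masks <- lapply(stems, function(s) {
    read_mask_binary(file.path(mdir, mk[[s]]))
  })
  list(images = images, masks = masks, stems = stems)
}

read_image_rgb <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  a
}

read_mask_binary <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  if (!all(a %in% c(0, 1))) {
    stop("mask is not binary after loading: ", path)
  }
  a
}

#' Bilinear resize (align_corners = FALSE)
#'
#' @param x (H,W) matrix or (H,W,C) array.
#' @param H2,W2 Target size.
#' @return Resized matrix/array.
#' @export
resize_bilinear <- function(x, H2, W2) {
  d <- dim(x)
  if (length(d) == 2) {
    y <- kn_upsample_fwd(array(x, dim = c(d, 1, 1)), c(d, 1L, 1L),
                         as.integer(H2), as.integer(W2))
    matrix(y, nrow = H2)
  } else {
    y <- kn_upsample_fwd(array(x, dim = c(d[1], d[2], d[3], 1)),
                         c(d[1:3], 1L), as.integer(H2), as.integer(W2))
    array(y, dim = c(H2, W2, d[3]))
  }
}

prep_batch <- function(images, masks, size) {
  B <- length(images)
  xb <- array(0, dim = c(size, size, 3, B))
  tb <- array(0, dim = c(size, size, 1, B))
  for (i in seq_len(B)) {
    im <- images[[i]]
    if (!identical(dim(im)[1:2], c(size, size))) im <- resize_bilinear(im, size, size)
    xb[, , , i] <- im
    mk <- masks[[i]]
    if (!identical(dim(mk), c(size, size))) {
      mk <- (resize_bilinear(mk, size, size) >= 0.5) * 1
    }
    tb[, , 1, i] <- mk
  }
  list(x = xb, t = tb)
}

# ---------------------------------------------------------------------------
# Training / evaluation / prediction
# ---------------------------------------------------------------------------

#' Train the network
#'
#' Adam optimization of the combined Dice + cross-entropy loss with the
#' reduce-on-plateau schedule; per-epoch train loss, validation loss and
#' validation Dice are logged to `<out_dir>/log.csv`, the best-validation-
#' Dice checkpoint is kept as `<out_dir>/best.rds` and the rolling state
#' (with optimizer and RNG state, for exact resuming) as `<out_dir>/last.rds`.
#'
#' @param model_cfg A [garden_config()].
#' @param train_cfg A [train_config()].
#' @param data_dir Dataset root with train/ and val/ splits.
#' @param out_dir Output directory (created if needed).
#' @param resume_from Optional `last.rds` checkpoint to continue from.
#' @param verbose Print a line per epoch.
#' @return List with `log` (data.frame), `best_val_dice`, `best_path`,
#'   `last_path`, and the trained `model`.
#' @export
run_training <- function(model_cfg, train_cfg, data_dir, out_dir,
                         resume_from = NULL, verbose = FALSE) {
  if (model_cfg$out_channels != 1) {
    stop("run_training: training is defined for binary (out_channels = 1) masks")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tr <- load_split(data_dir, "train")
  va <- load_split(data_dir, "val")
  size <- train_cfg$image_size
  trd <- prep_batch(tr$images, tr$masks, size)
  vad <- prep_batch(va$images, va$masks, size)
  n_tr <- length(tr$images)

  set.seed(train_cfg$seed)
  if (is.null(resume_from)) {
    model <- build_garden(model_cfg)
    params <- gd_parameters(model)
    opt <- adam_init(params, lr = train_cfg$lr)
    sched <- plateau_state(train_cfg$lr, train_cfg$scheduler_factor,
                           train_cfg$scheduler_patience)
    start_epoch <- 1L
    log <- NULL
    best_dice <- -Inf
  } else {
    ck <- load_checkpoint(resume_from)
    model <- ck$model
    params <- gd_parameters(model)
    opt <- adam_init(params, lr = ck$extra$lr)
    opt$m <- ck$extra$adam_m; opt$v <- ck$extra$adam_v; opt$t <- ck$extra$adam_t
    sched <- plateau_state(ck$extra$lr, train_cfg$scheduler_factor,
                           train_cfg$scheduler_patience)
    sched$best <- ck$extra$sched_best; sched$bad <- ck$extra$sched_bad
    start_epoch <- ck$extra$epoch + 1L
    log <- ck$extra$log
    best_dice <- ck$extra$best_dice
    assign(".Random.seed", ck$extra$rng, envir = globalenv())
  }

  best_path <- file.path(out_dir, "best.rds")
  last_path <- file.path(out_dir, "last.rds")

  for (epoch in seq(start_epoch, train_cfg$epochs)) {
    ord <- sample.int(n_tr)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    opt$lr <- sched$lr
    tl <- 0
    for (bi in batches) {
      xb <- standardize_images(trd$x[, , , bi, drop = FALSE])
      tb <- trd$t[, , , bi, drop = FALSE]
      gd_zero_grad(params)
      gd_start_tape()
      fw <- garden_fwd(model, gdt(xb), training = TRUE)
      loss <- gd_combined_loss(fw$logits, tb,
                               w_dice = train_cfg$loss_weights[1],
                               w_ce = train_cfg$loss_weights[2])
      gd_stop_tape()
      gd_backward(loss)
      adam_step(opt, params)
      tl <- tl + gd_value(loss) * length(bi)
    }
    gd_clear_tape()
    train_loss <- tl / n_tr
    ev <- eval_split(model, vad, train_cfg)
    plateau_update(sched, ev$loss)
    row <- data.frame(epoch = epoch, lr = opt$lr, train_loss = train_loss,
                      val_loss = ev$loss, val_dice = ev$metrics$dice)
    log <- rbind(log, row)
    utils::write.csv(log, file.path(out_dir, "log.csv"), row.names = FALSE)
    if (ev$metrics$dice > best_dice) {
      best_dice <- ev$metrics$dice
      save_checkpoint(model, best_path,
                      extra = list(epoch = epoch, val_dice = best_dice))
    }
    save_checkpoint(model, last_path, extra = list(
      epoch = epoch, lr = sched$lr, adam_m = opt$m, adam_v = opt$v,
      adam_t = opt$t, sched_best = sched$best, sched_bad = sched$bad,
      log = log, best_dice = best_dice,
      rng = get(".Random.seed", envir = globalenv())))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f  dice %.4f",
                      epoch, opt$lr, train_loss, ev$loss, ev$metrics$dice))
    }
  }
  list(log = log, best_val_dice = best_dice, best_path = best_path,
       last_path = last_path, model = model)
}

# Loss + metrics over a prepared split in eval mode.
eval_split <- function(model, data, train_cfg, batch_size = 8L) {
  n <- dim(data$x)[4]
  counts <- structure(list(TP = 0, FP = 0, FN = 0, TN = 0),
                      class = "confusion_counts")
  lsum <- 0
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    xb <- standardize_images(data$x[, , , bi, drop = FALSE])
    tb <- data$t[, , , bi, drop = FALSE]
    fw <- garden_fwd(model, gdt(xb), training = FALSE)
    z <- gd_value(fw$logits)
    lsum <- lsum + combined_loss(z, tb, train_cfg$loss_weights) * length(bi)
    pred <- (stable_sigmoid(z) >= 0.5) * 1
    counts <- add_counts(counts, confusion_counts(pred, tb))
  }
  list(loss = lsum / n, metrics = compute_metrics(counts), counts = counts)
}

#' Evaluate a checkpoint (or model) on a dataset split
#'
#' Metrics are accumulated over global pixel counts across the split.
#'
#' @param model_or_ckpt A model object or a checkpoint path.
#' @param data_dir Dataset root.
#' @param split Split name (default "test").
#' @param image_size Evaluation resolution (defaults to the training size
#'   stored in the model configuration).
#' @return A `metrics_report` with the confusion counts attached as
#'   attribute `"counts"`.
#' @export
evaluate_model <- function(model_or_ckpt, data_dir, split = "test",
                           image_size = NULL) {
  model <- if (is.character(model_or_ckpt)) {
    load_checkpoint(model_or_ckpt)$model
  } else {
    model_or_ckpt
  }
  sp <- load_split(data_dir, split)
  size <- image_size %||% model$cfg$image_size
  data <- prep_batch(sp$images, sp$masks, size)
  ev <- eval_split(model, data, train_config(image_size = size))
  structure(ev$metrics, counts = ev$counts)
}

#' Predict a lesion mask for one image
#'
#' Probabilities are computed at the model's training resolution and
#' bilinearly resized back to the native image resolution before
#' thresholding at 0.5; the mask is written as an 8-bit PNG with values
#' \{0, 255\}.
#'
#' @param model_or_ckpt Model object or checkpoint path.
#' @param image_path Input RGB image (PNG).
#' @param out_path Output mask PNG.
#' @return Invisibly, the binary mask matrix.
#' @export
predict_mask <- function(model_or_ckpt, image_path, out_path) {
  model <- if (is.character(model_or_ckpt)) {
    load_checkpoint(model_or_ckpt)$model
  } else {
    model_or_ckpt
  }
  im <- read_image_rgb(image_path)
  d <- dim(im)
  size <- model$cfg$image_size
  x <- resize_bilinear(im, size, size)
  fw <- garden_forward(model, array(x, dim = c(size, size, 3, 1)))
  prob <- matrix(fw$probs[, , 1, 1], nrow = size)
  native <- resize_bilinear(prob, d[1], d[2])
  mask <- (native >= 0.5) * 1
  png::writePNG(mask, out_path)
  invisible(mask)
}
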