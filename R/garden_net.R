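#' Network configuration
#'
#' Describes the full encoder-decoder segmentation network: a 4-stage
#' encoder (widths base_width * 1,2,4,8,16), the multi-scale context
#' bottleneck, and a symmetric decoder whose stages refine skips with
#' channel-wise cross-attention and sharpen contours with the
#' boundary-aware selective-scanning block.
#'
#' @param base_width Channels of the first encoder stage (default 64).
#' @param out_channels Output channels of the head (1, binary masks, default;
#'   3 is accepted for compatibility but metrics always evaluate the
#'   foreground channel).
#' @param msca [msca_config()] for the bottleneck pyramid.
#' @param ggbp_kernel Boundary-predictor kernel size, 3 or 5.
#' @param sharpening Initial gate gain of every BASS block (1, 5 or 10).
#' @param ssm_state_size Selective-scan state size N.
#' @param learnable_gate Whether the gate affine (gamma, beta) is trained.
#' @param image_size Nominal input size; must be divisible by 16 and large
#'   enough for the largest pool size at the 1/16-scale bottleneck.
#' @return A `garden_config` list.
#' @export
garden_config <- function(base_width = 64, out_channels = 1,
                          msca = msca_config(), ggbp_kernel = 3,
                          sharpening = 1, ssm_state_size = 16,
                          learnable_gate = TRUE, image_size = 224) {
  if (image_size %% 16 != 0) {
    stop("garden_config: image_size must be divisible by 16 (got ",
         image_size, ")")
  }
  if (!ggbp_kernel %in% c(3, 5)) stop("garden_config: ggbp_kernel must be 3 or 5")
  if (!out_channels %in% c(1, 3)) stop("garden_config: out_channels must be 1 or 3")
  bott <- image_size %/% 16
  if (any(msca$pool_sizes > bott)) {
    stop("garden_config: pool size ", max(msca$pool_sizes),
         " exceeds the ", bott, "x", bott, " bottleneck of a ",
         image_size, "px input")
  }
  structure(list(base_width = as.integer(base_width), depth = 4L,
                 out_channels = as.integer(out_channels), msca = msca,
                 ggbp_kernel = as.integer(ggbp_kernel),
                 sharpening = sharpening,
                 ssm_state_size = as.integer(ssm_state_size),
                 learnable_gate = isTRUE(learnable_gate),
                 image_size = as.integer(image_size)),
            class = "garden_config")
}

# Channel-wise cross-attention parameters for one skip connection:
# a two-layer bottleneck MLP on the concatenated channel descriptors.
cca_init <- function(C) {
  m <- new_module("cca")
  m$C <- C
  hidden <- max(C %/% 2L, 2L)
  m$fc1 <- dense_layer(2L * C, hidden)
  m$fc2 <- dense_layer(hidden, C)
  m
}

cca_fwd <- function(m, skip, dec, weights_override = NULL) {
  if (!is.null(weights_override)) {
    return(gd_channel_scale(skip, weights_override))
  }
  d1 <- gd_gap(skip); d2 <- gd_gap(dec)
  h <- gd_relu(dense_fwd(m$fc1, gd_concat_rows(d1, d2)))
  w <- gd_sigmoid(dense_fwd(m$fc2, h))
  gd_channel_scale(skip, w)
}

gd_concat_rows <- function(a, b) {
  a <- as_gdt(a); b <- as_gdt(b)
  na <- nrow(a$value)
  gd_op(rbind(a$value, b$value), list(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

#' Channel-wise cross-attention skip refinement
#'
#' Global-average-pool descriptors of the encoder skip and the decoder
#' feature are concatenated and passed through a two-layer bottleneck MLP
#' with sigmoid output; the skip is rescaled per channel by the resulting
#' weights before fusion.
#'
#' @param skip Encoder feature, array (C, H, W).
#' @param dec Spatially aligned decoder feature, array (C', H, W).
#' @param params Parameters from [cca_params()].
#' @param weights_override Optional length-C vector of attention weights to
#'   apply directly (bypasses the MLP; used for inspection).
#' @return Array (C, H, W): the reweighted skip.
#' @export
cca_refine <- function(skip, dec, params, weights_override = NULL) {
  ds <- dim(skip); dd <- dim(dec)
  if (is.null(ds) || is.null(dd) || !identical(ds[2:3], dd[2:3])) {
    stop("cca_refine: skip and decoder features must be spatially aligned")
  }
  st <- gdt(array(aperm(skip, c(2, 3, 1)), dim = c(ds[2], ds[3], ds[1], 1)))
  dt <- gdt(array(aperm(dec, c(2, 3, 1)), dim = c(dd[2], dd[3], dd[1], 1)))
  ov <- if (!is.null(weights_override)) gdt(matrix(weights_override, ncol = 1))
  y <- gd_value(cca_fwd(params, st, dt, ov))
  aperm(array(y, dim = c(ds[2], ds[3], ds[1])), c(3, 1, 2))
}

#' @rdname cca_refine
#' @param C Skip channel count.
#' @param C_dec Decoder channel count (descriptor width is C + C_dec).
#' @export
cca_params <- function(C, C_dec = C) {
  m <- cca_init(C)
  m$fc1 <- dense_layer(C + C_dec, max(C %/% 2L, 2L))
  m
}

#' Build the segmentation network
#'
#' Assembles stem, four DownBlocks (2x2 maxpool + two 3x3 conv-BN-ReLU),
#' the MSCA bottleneck, and four UpBlocks (bilinear 2x upsample + 1x1
#' projection, CCA-refined skip concatenation, 1x1 reduction, BASS, two
#' conv-BN-ReLU), ending in a 1x1 head with sigmoid. All BASS output
#' projections start at zero, so at initialization the network is
#' functionally its BASS-free ablation.
#'
#' @param cfg A [garden_config()].
#' @return A model object for [garden_forward()].
#' @export
build_garden <- function(cfg = garden_config()) {
  w <- cfg$base_width * c(1L, 2L, 4L, 8L, 16L)
  m <- new_module("garden")
  m$cfg <- cfg
  m$stem <- convbn_block(3L, w[1])
  m$down <- lapply(1:4, function(i) convbn_block(w[i], w[i + 1]))
  m$msca <- msca_init(w[5], cfg$msca)
  dec_in <- msca_out_channels(m$msca)
  m$up <- lapply(4:1, function(i) {
    u <- new_module("upblock")
    u$C <- w[i]
    u$proj_up <- conv_layer(if (i == 4) dec_in else w[i + 1], w[i], k = 1)
    u$cca <- cca_init(w[i])
    u$reduce <- conv_layer(2L * w[i], w[i], k = 1)
    u$bass <- bass_init(w[i], cfg$ggbp_kernel, cfg$ssm_state_size,
                        cfg$sharpening, cfg$learnable_gate)
    u$convs <- convbn_block(w[i], w[i])
    u
  })
  m$head <- conv_layer(w[1], cfg$out_channels, k = 1)
  # class-prior bias: lesions are the minority class, so start the head at a
  # low foreground logit instead of p = 0.5 (standard imbalanced-class init)
  m$head$b$value[] <- -2
  m
}

# Internal forward on a (H,W,3,B) tensor/array of standardized inputs.
# Returns logits plus bookkeeping (encoder shapes, boundary priors).
garden_fwd <- function(m, x, training = FALSE, skip_bass = FALSE,
                       collect_priors = FALSE) {
  xv <- gd_value(x)
  d <- dim(xv)
  if (d[3] != 3) stop("garden_forward: expected 3 input channels, got ", d[3])
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
    stop("garden_forward: spatial dims must be divisible by 16 (got ",
         d[1], "x", d[2], ")")
  }
  x <- as_gdt(x)
  enc <- vector("list", 5)
  enc[[1]] <- convbn_fwd(m$stem, x, training)
  for (i in 1:4) {
    enc[[i + 1]] <- convbn_fwd(m$down[[i]], gd_maxpool2(enc[[i]]), training)
  }
  bott_shape <- dim(gd_value(enc[[5]]))[1:2]
  dec <- msca_fwd(m$msca, enc[[5]], training)
  priors <- if (collect_priors) vector("list", 4) else NULL
  for (j in 1:4) {
    u <- m$up[[j]]
    skip <- enc[[5 - j]]
    sd_ <- dim(gd_value(skip))
    up <- conv_fwd(u$proj_up, gd_upsample(dec, sd_[1], sd_[2]))
    refined <- cca_fwd(u$cca, skip, up)
    fused <- conv_fwd(u$reduce, gd_cat(list(refined, up)))
    if (skip_bass) {
      bout <- fused
    } else if (collect_priors) {
      parts <- bass_fwd(u$bass, fused, training, return_parts = TRUE)
      bout <- parts$out
      priors[[j]] <- gd_value(parts$M_b)
    } else {
      bout <- bass_fwd(u$bass, fused, training)
    }
    dec <- convbn_fwd(u$convs, bout, training)
  }
  logits <- conv_fwd(m$head, dec)
  list(logits = logits, bottleneck_shape = bott_shape, priors = priors)
}

#' Run the network on a batch of images
#'
#' @param model Model from [build_garden()].
#' @param batch Array (H, W, 3, B) of RGB images in `[0, 1]` (standardization
#'   to mean 0.5 / sd 0.5 is applied internally), H and W divisible by 16.
#' @param return_priors If TRUE, also return the per-stage boundary priors.
#' @return List with `probs` (H, W, out_channels, B) sigmoid probabilities,
#'   `logits`, `bottleneck_shape`, and optionally `priors` (coarse to fine).
#' @export
garden_forward <- function(model, batch, return_priors = FALSE) {
  x <- standardize_images(batch)
  fw <- garden_fwd(model, x, training = FALSE, collect_priors = return_priors)
  out <- list(probs = stable_sigmoid(gd_value(fw$logits)),
              logits = gd_value(fw$logits),
              bottleneck_shape = fw$bottleneck_shape)
  if (return_priors) out$priors <- fw$priors
  out
}

standardize_images <- function(batch) {
  d <- dim(batch)
  if (length(d) == 3) dim(batch) <- c(d, 1L)
  (batch - 0.5) / 0.5
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file embedding the full
#' `garden_config` alongside every parameter and normalization buffer, plus
#' arbitrary extra entries (optimizer state, epoch, RNG state) used for
#' resuming.
#'
#' @param model Model object.
#' @param path Destination file.
#' @param extra Named list stored verbatim alongside the parameters.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  obj <- list(cfg = model$cfg, state = module_state(model), extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a list with the rebuilt `model` and the
#'   stored `extra` entries.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- build_garden(obj$cfg)
  module_load_state(model, obj$state)
  list(model = model, extra = obj$extra, cfg = obj$cfg)
}
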