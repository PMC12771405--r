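# Synthetic leaf-lesion imagery. The generator emulates the structure that
# makes real lesion datasets hard: per-image lesion area following a
# right-skewed (truncated lognormal) distribution spanning minute spots to
# large coalesced regions, and lesion rims that fade gradually into healthy
# tissue (controllable boundary fuzziness). Ground-truth masks stay hard.

#' Synthetic dataset profile
#'
#' The default proportion distribution, lognormal(-2.15, 0.80) truncated to
#' (0.001, 0.75), reproduces the scale statistics of curated leaf-lesion
#' collections: median ~11.6%, mean ~16%, sd ~15%, strongly right-skewed.
#'
#' @param image_size Square image side in pixels.
#' @param n_images Number of images to generate.
#' @param prop_meanlog,prop_sdlog Lognormal parameters of the target lesion
#'   proportion.
#' @param prop_range Truncation interval for the proportion.
#' @param lesion_counts Integer vector of possible blob counts per image.
#' @param fuzz_width Boundary alpha-fade width in pixels (0 = hard edge).
#' @param illumination_gradient Apply a random linear illumination ramp.
#' @param clutter Textured (rather than flat) background.
#' @param noise_sd Additive Gaussian pixel noise.
#' @param seed Base seed; generation is a pure function of (profile, seed).
#' @return A `synthetic_profile` list.
#' @export
synthetic_profile <- function(image_size = 64, n_images = 250,
                              prop_meanlog = -2.15, prop_sdlog = 0.80,
                              prop_range = c(0.001, 0.75),
                              lesion_counts = 1:8, fuzz_width = 2,
                              illumination_gradient = TRUE, clutter = TRUE,
                              noise_sd = 0.02, seed = 0) {
  structure(list(image_size = as.integer(image_size),
                 n_images = as.integer(n_images),
                 prop_meanlog = prop_meanlog, prop_sdlog = prop_sdlog,
                 prop_range = prop_range,
                 lesion_counts = as.integer(lesion_counts),
                 fuzz_width = fuzz_width,
                 illumination_gradient = isTRUE(illumination_gradient),
                 clutter = isTRUE(clutter), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_profile")
}

#' Draw target lesion proportions
#'
#' Samples from the profile's truncated lognormal by rejection.
#'
#' @param profile A [synthetic_profile()].
#' @param n Number of draws.
#' @return Numeric vector in `prop_range`.
#' @export
draw_lesion_proportion <- function(profile, n) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, profile$prop_meanlog, profile$prop_sdlog)
    x <- x[x > profile$prop_range[1] & x < profile$prop_range[2]]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

# Smooth random texture: coarse white noise bilinearly upsampled.
smooth_noise <- function(H, W, cells = 6, amp = 1) {
  g <- matrix(stats::rnorm(cells * cells), cells, cells)
  amp * resize_bilinear(g, H, W)
}

# Wobbly ellipse support on a pixel grid; radial perturbation by a short
# Fourier series gives organic, non-elliptical outlines.
blob_mask <- function(H, W, cy, cx, ry, rx, theta, wobble = 0.15) {
  kk <- sample(2:5, 1)
  ph <- stats::runif(3, 0, 2 * pi)
  aa <- wobble * stats::runif(3) / (1:3)
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  r <- sqrt((u / rx)^2 + (v / ry)^2)
  ang <- atan2(v, u)
  lim <- 1 + aa[1] * sin(kk * ang + ph[1]) + aa[2] * sin((kk + 1) * ang + ph[2]) +
    aa[3] * sin((kk + 2) * ang + ph[3])
  r <= lim
}

# Number of 4-neighbour erosions each foreground pixel survives; a cheap
# integer distance-to-boundary used for the rim alpha-fade.
erosion_depth <- function(mask, max_depth) {
  depth <- matrix(0, nrow(mask), ncol(mask))
  cur <- mask
  for (i in seq_len(max_depth)) {
    if (!any(cur)) break
    depth <- depth + cur
    H <- nrow(cur); W <- ncol(cur)
    er <- cur
    er[2:H, ] <- er[2:H, ] & cur[1:(H - 1), ]
    er[1:(H - 1), ] <- er[1:(H - 1), ] & cur[2:H, ]
    er[, 2:W] <- er[, 2:W] & cur[, 1:(W - 1)]
    er[, 1:(W - 1)] <- er[, 1:(W - 1)] & cur[, 2:W]
    er[1, ] <- FALSE; er[H, ] <- FALSE; er[, 1] <- FALSE; er[, W] <- FALSE
    cur <- er
  }
  depth
}

#' Generate one synthetic leaf image with lesions
#'
#' A textured green leaf (wobbly ellipse) on a cluttered background; lesions
#' are unions of randomly perturbed ellipses placed inside the leaf and
#' rescaled until the achieved area proportion is within 10% relative of
#' the target drawn from the profile's distribution. Lesion pixels are
#' recolored brown with an alpha fade of `fuzz_width` pixels at the rim;
#' the returned mask is the hard pre-fade support.
#'
#' @param profile A [synthetic_profile()].
#' @param seed Seed for this sample (pure function of (profile, seed)).
#' @return List with `image` (H,W,3 in `[0,1]`), `mask` (H,W binary),
#'   `leaf` (H,W logical leaf support), `target_proportion`, `proportion`
#'   (achieved).
#' @export
generate_sample <- function(profile, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  H <- profile$image_size; W <- profile$image_size

  for (attempt in seq_len(100)) {
    # leaf support
    leaf <- blob_mask(H, W,
                      cy = H / 2 + stats::runif(1, -H / 16, H / 16),
                      cx = W / 2 + stats::runif(1, -W / 16, W / 16),
                      ry = H * stats::runif(1, 0.33, 0.42),
                      rx = W * stats::runif(1, 0.33, 0.42),
                      theta = stats::runif(1, 0, pi), wobble = 0.1)
    leaf_frac <- mean(leaf)
    target <- draw_lesion_proportion(profile, 1)
    if (target > 0.8 * leaf_frac) {
      # heavily diseased leaves are photographed close up: enlarge the leaf
      # (possibly past the frame) so the drawn proportion stays reachable
      grow <- sqrt(target / (0.8 * leaf_frac))
      leaf <- blob_mask(H, W,
                        cy = H / 2 + stats::runif(1, -H / 32, H / 32),
                        cx = W / 2 + stats::runif(1, -W / 32, W / 32),
                        ry = H * min(0.42 * grow, 0.75),
                        rx = W * min(0.42 * grow, 0.75),
                        theta = stats::runif(1, 0, pi), wobble = 0.08)
      leaf_frac <- mean(leaf)
    }
    if (target > 0.85 * leaf_frac) next # lesion could not fit inside the leaf

    k <- sample(profile$lesion_counts, 1)
    inside <- which(leaf)
    ctr <- inside[sample.int(length(inside), k, replace = TRUE)]
    cys <- (ctr - 1) %% H + 1
    cxs <- (ctr - 1) %/% H + 1
    base_r <- sqrt(target * H * W / (k * pi))
    rel <- exp(stats::rnorm(k, 0, 0.35))
    ratio <- stats::runif(k, 0.6, 1)
    thetas <- stats::runif(k, 0, pi)
    scale <- 1
    lesion <- NULL
    ok <- FALSE
    wobble_seed <- (seed %% 100000L) * 17L + attempt * 131L + 7L
    for (it in seq_len(30)) {
      lesion <- matrix(FALSE, H, W)
      set.seed(wobble_seed) # same wobble across rescaling iterations
      for (i in seq_len(k)) {
        ri <- base_r * rel[i] * scale
        lesion <- lesion | blob_mask(H, W, cys[i], cxs[i],
                                     ry = ri, rx = ri * ratio[i],
                                     theta = thetas[i], wobble = 0.2)
      }
      lesion <- lesion & leaf
      ach <- mean(lesion)
      if (ach > 0 && abs(ach - target) / target <= 0.1) { ok <- TRUE; break }
      if (ach == 0) scale <- scale * 1.5 else {
        scale <- scale * sqrt(target / ach)
      }
    }
    if (ok) {
      img <- render_leaf_scene(profile, leaf, lesion)
      return(list(image = img, mask = lesion * 1, leaf = leaf,
                  target_proportion = target, proportion = mean(lesion)))
    }
  }
  stop("generate_sample: could not reach target lesion proportion in 100 attempts")
}

render_leaf_scene <- function(profile, leaf, lesion) {
  H <- nrow(leaf); W <- ncol(leaf)
  img <- array(0, dim = c(H, W, 3))
  if (profile$clutter) {
    base <- c(0.42, 0.33, 0.22) # soil
    tex <- smooth_noise(H, W, cells = 5, amp = 0.08) +
      smooth_noise(H, W, cells = 11, amp = 0.04)
    for (c in 1:3) img[, , c] <- base[c] + tex
  } else {
    for (c in 1:3) img[, , c] <- c(0.65, 0.65, 0.65)[c]
  }
  leaf_tex <- smooth_noise(H, W, cells = 7, amp = 0.05)
  leaf_col <- c(0.20, 0.52, 0.18)
  for (c in 1:3) {
    ch <- img[, , c]
    ch[leaf] <- leaf_col[c] + leaf_tex[leaf] * c(0.5, 1, 0.5)[c]
    img[, , c] <- ch
  }
  # lesion recoloring with rim alpha-fade (image only; the mask stays hard)
  if (any(lesion)) {
    alpha <- if (profile$fuzz_width > 0) {
      pmin(erosion_depth(lesion, ceiling(profile$fuzz_width) + 1L) /
             profile$fuzz_width, 1)
    } else {
      lesion * 1
    }
    les_tex <- smooth_noise(H, W, cells = 9, amp = 0.05)
    les_col <- c(0.45, 0.29, 0.13)
    for (c in 1:3) {
      img[, , c] <- img[, , c] * (1 - alpha) +
        (les_col[c] + les_tex * c(1, 0.8, 0.5)[c]) * alpha
    }
  }
  if (profile$illumination_gradient) {
    ang <- stats::runif(1, 0, 2 * pi)
    ramp <- outer(seq(-0.5, 0.5, length.out = H), rep(1, W)) * cos(ang) +
      outer(rep(1, H), seq(-0.5, 0.5, length.out = W)) * sin(ang)
    img <- img * array(rep(1 + 0.3 * ramp, 3), dim = c(H, W, 3))
  }
  img <- img + array(stats::rnorm(H * W * 3, 0, profile$noise_sd),
                     dim = c(H, W, 3))
  pmin(pmax(img, 0), 1)
}

#' Generate a full dataset on disk
#'
#' Writes train/val/test splits (60/20/20) of paired PNG images and masks,
#' plus `manifest.json` recording the profile, the seed and every image's
#' achieved lesion proportion.
#'
#' @param profile A [synthetic_profile()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return Invisibly, the manifest list.
#' @export
generate_dataset <- function(profile, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stop("generate_dataset: ", out_dir, " exists and is not empty ",
         "(use overwrite = TRUE)")
  }
  n <- profile$n_images
  n_train <- floor(0.6 * n)
  n_val <- floor(0.2 * n)
  splits <- rep(c("train", "val", "test"), c(n_train, n_val, n - n_train - n_val))
  for (s in unique(splits)) {
    dir.create(file.path(out_dir, s, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, s, "masks"), recursive = TRUE,
               showWarnings = FALSE)
  }
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    smp <- generate_sample(profile, seed = profile$seed + i)
    stem <- sprintf("img_%04d", i)
    png::writePNG(smp$image,
                  file.path(out_dir, splits[i], "images", paste0(stem, ".png")))
    png::writePNG(smp$mask,
                  file.path(out_dir, splits[i], "masks", paste0(stem, ".png")))
    entries[[i]] <- list(file = stem, split = splits[i],
                         target = smp$target_proportion,
                         proportion = smp$proportion)
  }
  manifest <- list(profile = unclass(profile), seed = profile$seed,
                   images = entries)
  writeLines(manifest_json(manifest), file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# Small hand-rolled JSON writer for the manifest (numbers, strings, logical,
# vectors and named/unnamed lists) keeps jsonlite out of the hard imports.
manifest_json <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      body <- vapply(names(x), function(nm) {
        paste0(pad, "  \"", nm, "\": ", trimws(manifest_json(x[[nm]], indent + 2), "left"))
      }, character(1))
      paste0(pad, "{\n", paste(body, collapse = ",\n"), "\n", pad, "}")
    } else {
      body <- vapply(x, function(e) paste0(pad, "  ",
                                           trimws(manifest_json(e, indent + 2), "left")),
                     character(1))
      paste0(pad, "[\n", paste(body, collapse = ",\n"), "\n", pad, "]")
    }
  } else if (is.character(x)) {
    if (length(x) == 1) paste0("\"", x, "\"") else
      paste0("[", paste0("\"", x, "\"", collapse = ", "), "]")
  } else if (is.logical(x)) {
    v <- ifelse(x, "true", "false")
    if (length(x) == 1) v else paste0("[", paste(v, collapse = ", "), "]")
  } else {
    v <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
    if (length(x) == 1) v else paste0("[", paste(v, collapse = ", "), "]")
  }
}

#' Lesion-scale statistics of a mask directory
#'
#' Computes the per-image lesion proportion (lesion pixels / total pixels,
#' at each mask's native resolution) for every PNG mask in a directory and
#' summarizes the distribution: mean, median and standard deviation in
#' percent, plus a fixed 20-bin histogram on `[0, 1]`.
#'
#' @param mask_dir Directory of binary mask PNGs.
#' @return List of class `lesion_stats`: `mean`, `median`, `std` (percent),
#'   `histogram` (list with `breaks`, `counts`), `n`, `proportions`.
#' @export
lesion_stats <- function(mask_dir) {
  fs <- list.files(mask_dir, pattern = "\\.png$", ignore.case = TRUE,
                   full.names = TRUE)
  if (length(fs) == 0) stop("lesion_stats: no masks found in ", mask_dir)
  props <- vapply(fs, function(f) mean(read_mask_binary(f)), numeric(1))
  br <- seq(0, 1, length.out = 21)
  cuts <- findInterval(props, br, rightmost.closed = TRUE, all.inside = TRUE)
  structure(list(
    mean = 100 * mean(props),
    median = 100 * stats::median(props),
    std = 100 * stats::sd(props),
    histogram = list(breaks = br, counts = tabulate(cuts, nbins = 20)),
    n = length(props),
    proportions = unname(props)
  ), class = "lesion_stats")
}

# Mask-only generation (no rendering); used where only proportions matter.
generate_mask_only <- function(profile, seed) {
  p2 <- profile
  p2$clutter <- FALSE
  p2$illumination_gradient <- FALSE
  p2$noise_sd <- 0
  p2$fuzz_width <- 0
  smp <- generate_sample(p2, seed)
  smp$mask
}
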