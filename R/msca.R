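#' Adaptive average pooling
#'
#' Pools a (C, H, W) feature map to a fixed s x s output. Output cell (i, j)
#' averages input rows `[floor(i*H/s), ceil((i+1)*H/s))` and the analogous
#' column window, so the windows tile (and may overlap) the full input.
#'
#' @param X Array of shape (C, H, W).
#' @param s Output size, `1 <= s <= min(H, W)`.
#' @return Array of shape (C, s, s).
#' @examples
#' adaptive_avg_pool(array(1:4, dim = c(1, 2, 2)), 1) # global mean 2.5
#' @export
adaptive_avg_pool <- function(X, s) {
  d <- dim(X)
  if (is.null(d) || length(d) != 3) stop("adaptive_avg_pool: X must be (C,H,W)")
  if (s < 1 || s > d[2] || s > d[3]) {
    stop("adaptive_avg_pool: output size ", s, " invalid for ", d[2], "x", d[3],
         " input")
  }
  xt <- gdt(array(aperm(X, c(2, 3, 1)), dim = c(d[2], d[3], d[1], 1)))
  y <- gd_value(gd_adaptive_pool(xt, s))
  aperm(array(y, dim = c(s, s, d[1])), c(3, 1, 2))
}

#' Multi-scale context aggregation configuration
#'
#' @param pool_sizes Strictly increasing pyramid of adaptive-pool output
#'   sizes; the default (1, 2, 3, 6) captures global, sub-regional and local
#'   context at the bottleneck.
#' @param branch_channels Channels each branch is reduced to by its 1x1
#'   convolution. `NULL` (default) uses C/4 for the four-branch pyramid and
#'   C %/% n_branches otherwise, keeping the concatenated width near 2C.
#' @return An `msca_config` list.
#' @export
msca_config <- function(pool_sizes = c(1, 2, 3, 6), branch_channels = NULL) {
  if (length(pool_sizes) < 1 || any(pool_sizes < 1) ||
      any(diff(pool_sizes) <= 0)) {
    stop("msca_config: pool sizes must be a strictly increasing positive list")
  }
  structure(list(pool_sizes = as.integer(pool_sizes),
                 branch_channels = branch_channels),
            class = "msca_config")
}

msca_branch_channels <- function(C, cfg) {
  if (!is.null(cfg$branch_channels)) return(as.integer(cfg$branch_channels))
  as.integer(C %/% length(cfg$pool_sizes))
}

# Bottleneck module: one (1x1 conv + BN + ReLU) branch per pool size.
msca_init <- function(C, cfg) {
  m <- new_module("msca")
  m$C <- C
  m$pool_sizes <- cfg$pool_sizes
  bc <- msca_branch_channels(C, cfg)
  m$bc <- bc
  m$convs <- lapply(cfg$pool_sizes, function(s) conv_layer(C, bc, k = 1))
  m$bns <- lapply(cfg$pool_sizes, function(s) bn_layer(bc))
  m
}

msca_out_channels <- function(m) m$C + length(m$pool_sizes) * m$bc

msca_fwd <- function(m, x, training = FALSE) {
  d <- dim(gd_value(x))
  if (any(m$pool_sizes > min(d[1], d[2]))) {
    stop("msca: pool size ", max(m$pool_sizes), " exceeds bottleneck size ",
         d[1], "x", d[2])
  }
  branches <- lapply(seq_along(m$pool_sizes), function(i) {
    p <- gd_adaptive_pool(x, m$pool_sizes[i])
    p <- gd_relu(bn_fwd(m$bns[[i]], conv_fwd(m$convs[[i]], p), training))
    gd_upsample(p, d[1], d[2])
  })
  gd_cat(c(list(x), branches))
}

#' Multi-scale context aggregation
#'
#' Bottleneck module: parallel adaptive-average-pooling branches at the
#' configured output sizes, each reduced by a 1x1 convolution (with batch
#' normalization and ReLU) and bilinearly upsampled back to the input
#' resolution, then concatenated with the input along channels.
#'
#' @param f_in Deepest encoder feature map, array of shape (C, H', W').
#' @param module Module created by [msca_module()].
#' @return Array of shape (C + n_branches * branch_channels, H', W').
#' @export
msca_forward <- function(f_in, module) {
  d <- dim(f_in)
  if (is.null(d) || length(d) != 3) stop("msca_forward: f_in must be (C,H,W)")
  xt <- gdt(array(aperm(f_in, c(2, 3, 1)), dim = c(d[2], d[3], d[1], 1)))
  y <- gd_value(msca_fwd(module, xt))
  dy <- dim(y)
  aperm(array(y, dim = dy[1:3]), c(3, 1, 2))
}

#' Construct an MSCA module
#'
#' @param C Input channel count (the deepest encoder width).
#' @param cfg An [msca_config()].
#' @return Module object for [msca_forward()] and the network assembly.
#' @export
msca_module <- function(C, cfg = msca_config()) {
  msca_init(C, cfg)
}
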