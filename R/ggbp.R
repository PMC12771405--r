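#' Sobel-initialized directional gradient kernels
#'
#' Returns the horizontal/vertical derivative pair used to initialize the
#' boundary predictor's learnable filters. The 3x3 pair is the canonical
#' Sobel operator; the 5x5 pair is the separable smoothed-derivative
#' construction `outer(smooth, deriv)` with smooth = (1,4,6,4,1) and
#' deriv = (-1,-2,0,2,1). In both cases `K_y` is the transpose of `K_x`.
#'
#' @param k Kernel size, 3 or 5.
#' @return List with k x k matrices `K_x` (horizontal gradient) and `K_y`.
#' @examples
#' sobel_kernels(3)$K_x
#' @export
sobel_kernels <- function(k) {
  if (!(is.numeric(k) && length(k) == 1 && k %in% c(3, 5))) {
    stop("sobel_kernels: kernel size must be 3 or 5")
  }
  if (k == 3) {
    Kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), nrow = 3, byrow = TRUE)
  } else {
    Kx <- outer(c(1, 4, 6, 4, 1), c(-1, -2, 0, 2, 1))
  }
  list(K_x = Kx, K_y = t(Kx))
}

# Learnable boundary-predictor parameters: a depthwise Sobel pair per input
# channel plus a 1x1 fusion from 2C channels to the single boundary channel.
ggbp_init <- function(C, k = 3) {
  sk <- sobel_kernels(k)
  m <- new_module("ggbp")
  m$k <- k
  m$C <- C
  m$Kx <- gd_param(array(sk$K_x, dim = c(k, k, C)))
  m$Ky <- gd_param(array(sk$K_y, dim = c(k, k, C)))
  m$fuse <- conv_layer(2 * C, 1, k = 1)
  m$fuse$w$value <- rand_array(c(1, 1, 2 * C, 1), sd = 0.1)
  m
}

# Tensor-path forward: x is (H,W,C,B); returns the (H,W,1,B) boundary prior.
ggbp_fwd <- function(m, x) {
  gx <- gd_dwconv(x, m$Kx)
  gy <- gd_dwconv(x, m$Ky)
  gd_sigmoid(conv_fwd(m$fuse, gd_cat(list(gx, gy))))
}

#' Gradient-guided boundary prediction
#'
#' Applies the learnable Sobel-initialized filter pair depthwise (one pair
#' per input channel, replicate padding), concatenates the horizontal and
#' vertical responses, fuses them with a 1x1 convolution, and squashes with
#' a sigmoid into a continuous boundary prior in (0, 1).
#'
#' @param X Feature map, array of shape (C, H, W).
#' @param params Parameters created by [ggbp_params()].
#' @return Boundary prior, array of shape (1, H, W), values strictly in (0,1).
#' @export
ggbp_forward <- function(X, params) {
  d <- dim(X)
  if (is.null(d) || length(d) != 3) stop("ggbp_forward: X must be (C,H,W)")
  if (d[1] != params$C) {
    stop("ggbp_forward: channel mismatch (got ", d[1], ", params built for ",
         params$C, ")")
  }
  if (!all(is.finite(X))) stop("ggbp_forward: non-finite input")
  xt <- gdt(array(aperm(X, c(2, 3, 1)), dim = c(d[2], d[3], d[1], 1)))
  mb <- gd_value(ggbp_fwd(params, xt))
  array(aperm(mb, c(3, 1, 2, 4)), dim = c(1, d[2], d[3]))
}

#' Construct boundary-predictor parameters
#'
#' @param C Number of input channels.
#' @param k Filter size (3 or 5), Sobel-initialized.
#' @param fuse_weights Optional numeric vector of length 2C fixing the 1x1
#'   fusion weights (the horizontal responses come first); default random.
#' @param fuse_bias Fusion bias, default 0.
#' @return A parameter object consumed by [ggbp_forward()].
#' @export
ggbp_params <- function(C, k = 3, fuse_weights = NULL, fuse_bias = 0) {
  m <- ggbp_init(C, k)
  if (!is.null(fuse_weights)) {
    stopifnot(length(fuse_weights) == 2 * C)
    m$fuse$w$value <- array(fuse_weights, dim = c(1, 1, 2 * C, 1))
  }
  m$fuse$b$value <- fuse_bias
  m
}
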