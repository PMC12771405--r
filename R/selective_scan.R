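#' Discretize selective state-space parameters
#'
#' Zero-order-hold discretization of the state matrix with the simplified
#' Euler rule for the input matrix, the standard choice for selective SSMs:
#' \eqn{\bar A = \exp(\Delta A)}, \eqn{\bar B = \Delta B}.
#'
#' @param delta Step size(s), non-negative real.
#' @param A State matrix entries (typically negative).
#' @param B Input projection entries.
#' @return A list with elements `A_bar` and `B_bar`, same shape as the inputs.
#' @examples
#' discretize(log(2), -1, 1) # A_bar = 0.5
#' @export
discretize <- function(delta, A, B) {
  if (!all(is.finite(delta)) || !all(is.finite(A)) || !all(is.finite(B))) {
    stop("discretize: non-finite state-space parameters")
  }
  if (any(delta < 0)) stop("discretize: delta must be non-negative")
  list(A_bar = exp(delta * A), B_bar = delta * B)
}

#' Traversal layouts for the four directional scans
#'
#' Each layout is a bijection between sequence position `t` in `1..H*W` and a
#' grid cell, returned as `index_map` (t -> column-major cell index) together
#' with its `inverse_map`. Directions: D1 row-major top-left to bottom-right,
#' D2 its exact reversal, D3 column-major top-left to bottom-right, D4 its
#' reversal.
#'
#' @param H,W Grid dimensions (positive integers).
#' @return Named list `D1..D4`; each element has `index_map` and `inverse_map`.
#' @export
scan_layouts <- function(H, W) {
  if (H < 1 || W < 1) stop("scan_layouts: empty grid")
  # column-major cell index of cell (r, c) is r + (c-1) * H
  grid <- matrix(seq_len(H * W), nrow = H)
  d1 <- as.integer(t(grid)) # row-major traversal
  d3 <- seq_len(H * W) # column-major traversal
  mk <- function(idx) {
    inv <- integer(length(idx))
    inv[idx] <- seq_along(idx)
    list(index_map = idx, inverse_map = inv)
  }
  list(D1 = mk(d1), D2 = mk(rev(d1)), D3 = mk(d3), D4 = mk(rev(d3)))
}

#' Flatten a feature map into four directional sequences
#'
#' @param X Array of shape (C, H, W).
#' @return Named list `D1..D4` of C x L matrices, L = H*W, each a permutation
#'   of the grid cells of `X` in the corresponding traversal order.
#' @export
cross_scan <- function(X) {
  d <- dim(X)
  if (is.null(d) || length(d) != 3) stop("cross_scan: X must be a (C,H,W) array")
  C <- d[1]; H <- d[2]; W <- d[3]
  if (H < 1 || W < 1) stop("cross_scan: empty feature map")
  lay <- scan_layouts(H, W)
  Xm <- matrix(aperm(X, c(2, 3, 1)), nrow = H * W) # L x C, column-major cells
  lapply(lay, function(l) t(Xm[l$index_map, , drop = FALSE]))
}

#' Merge four directional sequences back onto the grid
#'
#' Each sequence is inverse-permuted to its grid positions and the four grids
#' are summed elementwise (the summation half of the fuse step).
#'
#' @param Y Named list `D1..D4` of C x L matrices.
#' @param H,W Grid dimensions with `H*W == L`.
#' @return Array of shape (C, H, W).
#' @export
cross_merge <- function(Y, H, W) {
  if (!all(c("D1", "D2", "D3", "D4") %in% names(Y))) {
    stop("cross_merge: Y must have directions D1..D4")
  }
  lay <- scan_layouts(H, W)
  L <- H * W
  C <- nrow(Y[[1]])
  acc <- matrix(0, nrow = L, ncol = C)
  for (d in names(lay)) {
    Yd <- Y[[d]]
    if (ncol(Yd) != L) stop("cross_merge: sequence length mismatch for ", d)
    acc[lay[[d]]$index_map, ] <- acc[lay[[d]]$index_map, ] + t(Yd)
  }
  aperm(array(acc, dim = c(H, W, C)), c(3, 1, 2))
}

#' Run the selective-scan recurrence along one sequence
#'
#' Evaluates \eqn{h_t = \bar A_t \odot h_{t-1} + \bar B_t u_t},
#' \eqn{y_t = C_t \cdot h_t + D u_t} with \eqn{h_0 = 0}, per channel, with
#' input-dependent per-position parameters.
#'
#' @param u C x L matrix (or length-L vector for C = 1) of inputs.
#' @param delta C x L matrix of non-negative step sizes.
#' @param B,C_t N x L matrices of per-position input/output projections.
#' @param A C x N matrix of (diagonal) state entries.
#' @param D Length-C skip coefficients.
#' @return C x L matrix of outputs.
#' @export
selective_scan_1d <- function(u, delta, B, C_t, A, D) {
  if (is.vector(u)) u <- matrix(u, nrow = 1)
  if (is.vector(delta)) delta <- matrix(delta, nrow = 1)
  if (is.vector(A)) A <- matrix(A, nrow = 1)
  L <- ncol(u); C <- nrow(u); N <- nrow(B)
  if (ncol(delta) != L || ncol(B) != L || ncol(C_t) != L) {
    stop("selective_scan_1d: per-position parameter length mismatch")
  }
  if (nrow(delta) != C || ncol(A) != N || nrow(A) != C || length(D) != C) {
    stop("selective_scan_1d: channel/state dimension mismatch")
  }
  if (!all(is.finite(u)) || !all(is.finite(delta)) || !all(is.finite(A))) {
    stop("selective_scan_1d: non-finite inputs")
  }
  fw <- kn_ssm_fwd(t(u), t(delta), t(B), t(C_t), A, as.numeric(D),
                   L, C, N, 1L)
  t(matrix(fw$y, nrow = L))
}
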