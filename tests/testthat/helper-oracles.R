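# Independent oracles, written as plain position-by-position loops so they
# share no code with the package's kernels.

# Naive selective-scan recurrence: u, delta C x L; B, Ct N x L; A C x N; D C.
naive_scan <- function(u, delta, B, Ct, A, D) {
  C <- nrow(u); L <- ncol(u); N <- nrow(B)
  y <- matrix(0, C, L)
  h <- matrix(0, C, N)
  for (t in seq_len(L)) {
    for (c in seq_len(C)) {
      for (n in seq_len(N)) {
        a_bar <- exp(delta[c, t] * A[c, n])
        b_bar <- delta[c, t] * B[n, t]
        h[c, n] <- a_bar * h[c, n] + b_bar * u[c, t]
      }
      y[c, t] <- sum(Ct[, t] * h[c, ]) + D[c] * u[c, t]
    }
  }
  y
}

random_scan_instance <- function(seed, Lmax = 64, Nmax = 4, Cmax = 3) {
  set.seed(seed)
  L <- sample(2:Lmax, 1)
  N <- sample(1:Nmax, 1)
  C <- sample(1:Cmax, 1)
  list(u = matrix(rnorm(C * L), C, L),
       delta = matrix(runif(C * L, 0, 0.8), C, L),
       B = matrix(rnorm(N * L), N, L),
       Ct = matrix(rnorm(N * L), N, L),
       A = matrix(-runif(C * N, 0.1, 3), C, N),
       D = rnorm(C))
}

# Explicit index-bookkeeping merge oracle for a (C,H,W) grid: walks every
# grid cell, finds its position in each direction's traversal, and sums.
naive_merge <- function(Y, H, W) {
  C <- nrow(Y$D1)
  out <- array(0, dim = c(C, H, W))
  # traversal orders as (row, col) lists
  rowmaj <- cbind(rep(seq_len(H), each = W), rep(seq_len(W), times = H))
  colmaj <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  orders <- list(D1 = rowmaj, D2 = rowmaj[nrow(rowmaj):1, ],
                 D3 = colmaj, D4 = colmaj[nrow(colmaj):1, ])
  for (d in names(orders)) {
    ord <- orders[[d]]
    for (t in seq_len(nrow(ord))) {
      out[, ord[t, 1], ord[t, 2]] <- out[, ord[t, 1], ord[t, 2]] + Y[[d]][, t]
    }
  }
  out
}

# Finite-difference gradient of a scalar function.
fd_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny on-disk dataset for training-path tests.
make_tiny_dataset <- function(n = 15, size = 32, seed = 11) {
  dir <- tempfile("tinyds")
  prof <- synthetic_profile(image_size = size, n_images = n, seed = seed,
                            lesion_counts = 1:3)
  generate_dataset(prof, dir)
  dir
}

tiny_model_cfg <- function(size = 32) {
  garden_config(base_width = 4, msca = msca_config(c(1, 2)),
                ssm_state_size = 4, image_size = size)
}
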