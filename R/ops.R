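# Autograd wrappers around the compiled kernels, plus normalization layers
# whose backward passes are implemented analytically.

gd_conv2d <- function(x, w, b, pad) {
  x <- as_gdt(x); w <- as_gdt(w); b <- as_gdt(b)
  xv <- x$value; wv <- w$value
  y <- kn_conv2d_fwd(xv, dim(xv), wv, dim(wv), b$value, as.integer(pad))
  gd_op(y, list(x, w, b), function(g) {
    bw <- kn_conv2d_bwd(xv, dim(xv), wv, dim(wv), g, as.integer(pad))
    list(bw$dx, bw$dw, bw$db)
  })
}

gd_dwconv <- function(x, w) {
  x <- as_gdt(x); w <- as_gdt(w)
  xv <- x$value; wv <- w$value
  k <- dim(wv)[1]
  y <- kn_dwconv_fwd(xv, dim(xv), wv, as.integer(k))
  gd_op(y, list(x, w), function(g) {
    bw <- kn_dwconv_bwd(xv, dim(xv), wv, as.integer(k), g)
    list(bw$dx, bw$dw)
  })
}

gd_maxpool2 <- function(x) {
  x <- as_gdt(x)
  xv <- x$value
  fw <- kn_maxpool2_fwd(xv, dim(xv))
  gd_op(fw$y, list(x), function(g) {
    list(kn_maxpool2_bwd(g, fw$idx, dim(xv)))
  })
}

gd_upsample <- function(x, Ho, Wo) {
  x <- as_gdt(x)
  xv <- x$value
  d <- dim(xv)
  y <- kn_upsample_fwd(xv, d, as.integer(Ho), as.integer(Wo))
  gd_op(y, list(x), function(g) {
    list(kn_upsample_bwd(g, dim(g) %||% c(Ho, Wo, d[3], d[4]), d[1], d[2]))
  })
}

# Adaptive average pooling to s x s with the standard overlapping-window
# binning: row window i covers [floor(i*H/s), ceil((i+1)*H/s)).
adaptive_bins <- function(H, s) {
  lapply(seq_len(s), function(i) {
    lo <- floor((i - 1) * H / s)
    hi <- ceiling(i * H / s)
    seq.int(lo + 1L, hi)
  })
}

gd_adaptive_pool <- function(x, s) {
  x <- as_gdt(x)
  xv <- x$value
  d <- dim(xv)
  if (s > d[1] || s > d[2]) {
    stop("adaptive pool size ", s, " exceeds spatial dims ", d[1], "x", d[2])
  }
  rb <- adaptive_bins(d[1], s); cb <- adaptive_bins(d[2], s)
  y <- array(0, dim = c(s, s, d[3], d[4]))
  for (i in seq_len(s)) for (j in seq_len(s)) {
    sub <- xv[rb[[i]], cb[[j]], , , drop = FALSE]
    n <- length(rb[[i]]) * length(cb[[j]])
    y[i, j, , ] <- colSums(matrix(sub, nrow = n))
  }
  for (i in seq_len(s)) for (j in seq_len(s)) {
    y[i, j, , ] <- y[i, j, , ] / (length(rb[[i]]) * length(cb[[j]]))
  }
  gd_op(y, list(x), function(g) {
    dx <- array(0, dim = d)
    for (i in seq_len(s)) for (j in seq_len(s)) {
      n <- length(rb[[i]]) * length(cb[[j]])
      gij <- g[i, j, , ] / n
      add <- aperm(array(gij, dim = c(d[3], d[4], length(rb[[i]]), length(cb[[j]]))),
                   c(3, 4, 1, 2))
      dx[rb[[i]], cb[[j]], , ] <- dx[rb[[i]], cb[[j]], , , drop = FALSE] + add
    }
    list(dx)
  })
}

# Batch normalization over (H,W,B) per channel. `state` is an environment
# carrying running_mean / running_var; training mode uses batch statistics
# and updates the running buffers (momentum 0.1).
gd_batchnorm <- function(x, gamma, beta, state, training, eps = 1e-5) {
  x <- as_gdt(x); gamma <- as_gdt(gamma); beta <- as_gdt(beta)
  xv <- x$value
  d <- dim(xv)
  C <- d[3]; M <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(xv, c(1, 2, 4, 3)), ncol = C) # M x C
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    state$running_mean <- 0.9 * state$running_mean + 0.1 * mu
    state$running_var <- 0.9 * state$running_var + 0.1 * va * M / max(M - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  ym <- sweep(sweep(xhat, 2, gamma$value, `*`), 2, beta$value, `+`)
  y <- aperm(array(ym, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  gd_op(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    if (training) {
      t1 <- sweep(gm, 2, dbeta / M)
      t2 <- sweep(xhat, 2, colSums(gm * xhat) / M, `*`)
      dxm <- sweep(t1 - t2, 2, gamma$value * invstd, `*`)
    } else {
      dxm <- sweep(gm, 2, gamma$value * invstd, `*`)
    }
    dx <- aperm(array(dxm, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    list(dx, dgamma, dbeta)
  })
}

# Layer normalization across channels at each spatial position.
gd_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_gdt(x); gamma <- as_gdt(gamma); beta <- as_gdt(beta)
  xv <- x$value
  d <- dim(xv)
  C <- d[3]
  xm <- matrix(aperm(xv, c(3, 1, 2, 4)), nrow = C) # C x (H*W*B)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, `*`)
  ym <- sweep(xhat, 1, gamma$value, `*`) + beta$value
  y <- aperm(array(ym, dim = c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  gd_op(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(3, 1, 2, 4)), nrow = C)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    gh <- sweep(gm, 1, gamma$value, `*`)
    t1 <- sweep(gh, 2, colMeans(gh))
    t2 <- sweep(xhat, 2, colMeans(gh * xhat), `*`)
    dxm <- sweep(t1 - t2, 2, invstd, `*`)
    dx <- aperm(array(dxm, dim = c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
    list(dx, dgamma, dbeta)
  })
}

# Selective-scan recurrence as a single differentiable op.
# u, delta: (L,C,B); Bt, Ct: (L,N,B); A: (C,N); D: (C).
gd_ssm_scan <- function(u, delta, Bt, Ct, A, D) {
  u <- as_gdt(u); delta <- as_gdt(delta)
  Bt <- as_gdt(Bt); Ct <- as_gdt(Ct)
  A <- as_gdt(A); D <- as_gdt(D)
  du <- dim(u$value); dn <- dim(Bt$value)
  L <- du[1]; C <- du[2]; B <- du[3]; N <- dn[2]
  fw <- kn_ssm_fwd(u$value, delta$value, Bt$value, Ct$value,
                   A$value, D$value, L, C, N, B,
                   keep_state = gd_recording())
  uv <- u$value; dv <- delta$value; bv <- Bt$value; cv <- Ct$value
  av <- A$value; Dv <- D$value
  gd_op(fw$y, list(u, delta, Bt, Ct, A, D), function(g) {
    bw <- kn_ssm_bwd(uv, dv, bv, cv, av, Dv, fw$cache, g, L, C, N, B)
    list(bw$du, bw$ddelta, bw$dB, bw$dC, bw$dA, bw$dD)
  })
}

# Combined segmentation loss on logits: 0.5 * Dice (smooth eps = 1) +
# 0.5 * pixelwise binary cross-entropy. Scalar output with analytic gradient.
gd_combined_loss <- function(logits, target, w_dice = 0.5, w_ce = 0.5) {
  logits <- as_gdt(logits)
  z <- logits$value
  t <- target
  n <- length(z)
  p <- stable_sigmoid(z)
  num <- 2 * sum(p * t) + 1
  den <- sum(p) + sum(t) + 1
  dice <- 1 - num / den
  ce <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  val <- w_dice * dice + w_ce * ce
  gd_op(val, list(logits), function(g) {
    gdice_p <- -(2 * t * den - num) / den^2
    dz <- w_dice * gdice_p * p * (1 - p) + w_ce * (p - t) / n
    list(as.numeric(g) * dz)
  })
}
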