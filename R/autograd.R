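# Minimal reverse-mode automatic differentiation on dense R arrays.
#
# Tensors are environments holding $value (an array), $grad and a
# requires_grad flag. Operations executed while recording is enabled append
# a node (output, inputs, backward closure) to a global tape; gd_backward()
# walks the tape in reverse, accumulating gradients. Only the training loop
# records; all inference paths run with recording off and carry zero
# overhead beyond the kernel calls.

.gd <- new.env(parent = emptyenv())
.gd$tape <- vector("list", 512L)
.gd$k <- 0L
.gd$recording <- FALSE
.gd$param_id <- 0L

gdt <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  class(e) <- "gdt"
  e
}

is_gdt <- function(x) inherits(x, "gdt")

gd_param <- function(value) {
  p <- gdt(value, requires_grad = TRUE)
  .gd$param_id <- .gd$param_id + 1L
  p$id <- .gd$param_id
  p
}

#' @keywords internal
gd_value <- function(x) if (is_gdt(x)) x$value else x

as_gdt <- function(x) if (is_gdt(x)) x else gdt(x)

gd_recording <- function() .gd$recording

gd_start_tape <- function() {
  .gd$k <- 0L
  .gd$tape <- vector("list", 512L)
  .gd$recording <- TRUE
}

gd_stop_tape <- function() {
  .gd$recording <- FALSE
}

gd_clear_tape <- function() {
  .gd$k <- 0L
  .gd$tape <- vector("list", 512L)
}

# Create an output tensor and, when recording and any input needs gradients,
# push a tape node. `backward` maps the output gradient to a list of input
# gradients (NULL entries allowed for non-differentiable inputs).
gd_op <- function(value, inputs, backward) {
  out <- gdt(value)
  if (.gd$recording) {
    needs <- vapply(inputs, function(i) is_gdt(i) && isTRUE(i$requires_grad),
                    logical(1))
    if (any(needs)) {
      out$requires_grad <- TRUE
      k <- .gd$k + 1L
      if (k > length(.gd$tape)) .gd$tape <- c(.gd$tape, vector("list", length(.gd$tape)))
      .gd$tape[[k]] <- list(out = out, inputs = inputs, backward = backward)
      .gd$k <- k
    }
  }
  out
}

gd_backward <- function(loss) {
  stopifnot(is_gdt(loss))
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  if (.gd$k > 0L) {
    for (i in seq(.gd$k, 1L)) {
      nd <- .gd$tape[[i]]
      g <- nd$out$grad
      if (is.null(g)) next
      gs <- nd$backward(g)
      for (j in seq_along(nd$inputs)) {
        inp <- nd$inputs[[j]]
        if (is_gdt(inp) && isTRUE(inp$requires_grad) && !is.null(gs[[j]])) {
          inp$grad <- if (is.null(inp$grad)) gs[[j]] else inp$grad + gs[[j]]
        }
      }
      nd$out$grad <- NULL # free intermediate gradients as we go
      .gd$tape[i] <- list(NULL)
    }
  }
  .gd$k <- 0L
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Elementwise and shape primitives
# ---------------------------------------------------------------------------

gd_add <- function(a, b) {
  a <- as_gdt(a); b <- as_gdt(b)
  gd_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

gd_mul <- function(a, b) {
  a <- as_gdt(a); b <- as_gdt(b)
  av <- a$value; bv <- b$value
  gd_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

gd_relu <- function(x) {
  x <- as_gdt(x)
  m <- x$value > 0
  gd_op(x$value * m, list(x), function(g) list(g * m))
}

gd_sigmoid <- function(x) {
  x <- as_gdt(x)
  s <- stable_sigmoid(x$value)
  gd_op(s, list(x), function(g) list(g * s * (1 - s)))
}

gd_softplus <- function(x) {
  x <- as_gdt(x)
  v <- x$value
  y <- pmax(v, 0) + log1p(exp(-abs(v)))
  dim(y) <- dim(v)
  s <- stable_sigmoid(v)
  gd_op(y, list(x), function(g) list(g * s))
}

stable_sigmoid <- function(v) {
  s <- ifelse(v >= 0, 1 / (1 + exp(-v)), exp(v) / (1 + exp(v)))
  dim(s) <- dim(v)
  s
}

# Concatenate feature maps (H,W,C,B) along the channel dimension.
gd_cat <- function(xs) {
  xs <- lapply(xs, as_gdt)
  vals <- lapply(xs, function(x) x$value)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  H <- d1[1]; W <- d1[2]; B <- d1[4]
  out <- array(0, dim = c(H, W, sum(cs), B))
  off <- 0L
  for (v in vals) {
    out[, , off + seq_len(dim(v)[3]), ] <- v
    off <- off + dim(v)[3]
  }
  offs <- cumsum(c(0, cs[-length(cs)]))
  gd_op(out, xs, function(g) {
    lapply(seq_along(cs), function(i) {
      g[, , offs[i] + seq_len(cs[i]), , drop = FALSE]
    })
  })
}

# Broadcast a (H,W,1,B) field over channels of (H,W,C,B):
# out = (1 - alpha) * xhat + alpha * z  (the boundary-conditioned blend).
gd_blend <- function(xhat, z, alpha) {
  xhat <- as_gdt(xhat); z <- as_gdt(z); alpha <- as_gdt(alpha)
  xv <- xhat$value; zv <- z$value; av <- alpha$value
  d <- dim(xv); C <- d[3]
  ab <- array(av[, , rep(1L, C), , drop = FALSE], dim = d)
  out <- (1 - ab) * xv + ab * zv
  L <- d[1] * d[2]
  gd_op(out, list(xhat, z, alpha), function(g) {
    tmp <- g * (zv - xv)
    dim(tmp) <- c(L, C, d[4])
    da <- colSums(matrix(aperm(tmp, c(2, 1, 3)), nrow = C))
    list(g * (1 - ab), g * ab,
         array(da, dim = c(d[1], d[2], 1, d[4])))
  })
}

# Gate field alpha = sigmoid(gamma * m + beta) with scalar gamma, beta.
gd_gate <- function(m, gamma, beta) {
  m <- as_gdt(m); gamma <- as_gdt(gamma); beta <- as_gdt(beta)
  mv <- m$value
  a <- stable_sigmoid(gamma$value[1] * mv + beta$value[1])
  gv <- gamma$value[1]
  gd_op(a, list(m, gamma, beta), function(g) {
    ds <- g * a * (1 - a)
    list(ds * gv, sum(ds * mv), sum(ds))
  })
}

# Per-channel, per-sample scaling: x (H,W,C,B) * w (C,B).
gd_channel_scale <- function(x, w) {
  x <- as_gdt(x); w <- as_gdt(w)
  xv <- x$value; wv <- w$value
  d <- dim(xv)
  L <- d[1] * d[2]
  wb <- array(rep(wv, each = L), dim = d)
  gd_op(xv * wb, list(x, w), function(g) {
    dw <- colSums(matrix(g * xv, nrow = L))
    list(g * wb, matrix(dw, nrow = d[3]))
  })
}

# Global average pool (H,W,C,B) -> (C,B).
gd_gap <- function(x) {
  x <- as_gdt(x)
  d <- dim(x$value)
  L <- d[1] * d[2]
  v <- matrix(colMeans(matrix(x$value, nrow = L)), nrow = d[3])
  gd_op(v, list(x), function(g) {
    list(array(rep(g / L, each = L), dim = d))
  })
}

# Dense layer on column-wise samples: x (Cin,B), W (Cout,Cin), b (Cout).
gd_dense <- function(x, W, b) {
  x <- as_gdt(x); W <- as_gdt(W); b <- as_gdt(b)
  xv <- x$value; Wv <- W$value
  out <- Wv %*% xv + b$value
  gd_op(out, list(x, W, b), function(g) {
    list(crossprod(Wv, g), g %*% t(xv), rowSums(g))
  })
}

# Gather flattened spatial positions: x (H,W,C,B) -> (L,C,B) in `perm` order,
# where perm maps sequence position t to the column-major spatial index.
gd_gather_spatial <- function(x, perm) {
  x <- as_gdt(x)
  d <- dim(x$value)
  L <- d[1] * d[2]
  xv <- x$value
  dim(xv) <- c(L, d[3], d[4])
  out <- xv[perm, , , drop = FALSE]
  gd_op(out, list(x), function(g) {
    dx <- array(0, dim = c(L, d[3], d[4]))
    dx[perm, , ] <- g
    dim(dx) <- d
    list(dx)
  })
}

# Inverse of gd_gather_spatial: (L,C,B) sequence back onto the (H,W) grid.
gd_scatter_spatial <- function(y, perm, H, W) {
  y <- as_gdt(y)
  d <- dim(y$value)
  out <- array(0, dim = c(H * W, d[2], d[3]))
  out[perm, , ] <- y$value
  dim(out) <- c(H, W, d[2], d[3])
  gd_op(out, list(y), function(g) {
    dim(g) <- c(H * W, d[2], d[3])
    list(g[perm, , , drop = FALSE])
  })
}

gd_sum_list <- function(xs) {
  xs <- lapply(xs, as_gdt)
  v <- xs[[1]]$value
  for (i in seq_along(xs)[-1]) v <- v + xs[[i]]$value
  gd_op(v, xs, function(g) rep(list(g), length(xs)))
}
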