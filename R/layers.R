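# Layer constructors and the Adam optimizer. A "module" is an environment of
# class gd_module whose fields are parameter tensors (gdt with
# requires_grad), plain buffers, or child modules; parameters are collected
# recursively by gd_parameters().

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  class(m) <- "gd_module"
  m
}

rand_array <- function(dim, sd) array(stats::rnorm(prod(dim), sd = sd), dim = dim)

# 2D convolution layer, He-initialized; zero = TRUE gives an exactly zero
# branch (used for the residual output projections).
conv_layer <- function(cin, cout, k = 3, zero = FALSE) {
  m <- new_module("conv")
  m$pad <- (k - 1) %/% 2
  sd <- sqrt(2 / (k * k * cin))
  m$w <- gd_param(if (zero) array(0, dim = c(k, k, cin, cout)) else
    rand_array(c(k, k, cin, cout), sd))
  m$b <- gd_param(numeric(cout))
  m
}

conv_fwd <- function(m, x) gd_conv2d(x, m$w, m$b, m$pad)

bn_layer <- function(C) {
  m <- new_module("bn")
  m$gamma <- gd_param(rep(1, C))
  m$beta <- gd_param(numeric(C))
  m$running_mean <- numeric(C)
  m$running_var <- rep(1, C)
  m
}

bn_fwd <- function(m, x, training) gd_batchnorm(x, m$gamma, m$beta, m, training)

ln_layer <- function(C) {
  m <- new_module("ln")
  m$gamma <- gd_param(rep(1, C))
  m$beta <- gd_param(numeric(C))
  m
}

dense_layer <- function(cin, cout) {
  m <- new_module("dense")
  m$w <- gd_param(rand_array(c(cout, cin), sqrt(2 / cin)))
  m$b <- gd_param(numeric(cout))
  m
}

dense_fwd <- function(m, x) gd_dense(x, m$w, m$b)

# Two serial 3x3 conv + BN + ReLU layers (the nConvs = 2 unit used by every
# encoder and decoder stage).
convbn_block <- function(cin, cout, n_convs = 2) {
  m <- new_module("convbn")
  m$convs <- lapply(seq_len(n_convs), function(i) {
    conv_layer(if (i == 1) cin else cout, cout, k = 3)
  })
  m$bns <- lapply(seq_len(n_convs), function(i) bn_layer(cout))
  m
}

convbn_fwd <- function(m, x, training) {
  for (i in seq_along(m$convs)) {
    x <- gd_relu(bn_fwd(m$bns[[i]], conv_fwd(m$convs[[i]], x), training))
  }
  x
}

# Recursively collect parameter tensors from a module tree.
gd_parameters <- function(x) {
  out <- list()
  walk <- function(v) {
    if (is_gdt(v)) {
      if (isTRUE(v$requires_grad)) out[[length(out) + 1L]] <<- v
    } else if (inherits(v, "gd_module")) {
      for (nm in ls(v, sorted = TRUE)) walk(get(nm, envir = v))
    } else if (is.list(v)) {
      for (e in v) walk(e)
    }
  }
  walk(x)
  out
}

n_parameters <- function(x) {
  sum(vapply(gd_parameters(x), function(p) length(p$value), numeric(1)))
}

gd_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0) # zeros, same shape class
  st$v <- st$m
  st
}

adam_step <- function(st, params) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g * g
    p$value <- p$value - st$lr * (st$m[[i]] / bc1) /
      (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  invisible(NULL)
}

# Plain nested-list snapshot of all parameter values and buffers, used for
# checkpointing (see save_checkpoint).
module_state <- function(x) {
  if (is_gdt(x)) return(x$value)
  if (inherits(x, "gd_module")) {
    nms <- setdiff(ls(x, sorted = TRUE), c("type", "pad"))
    st <- lapply(nms, function(nm) module_state(get(nm, envir = x)))
    names(st) <- nms
    return(st)
  }
  if (is.list(x)) return(lapply(x, module_state))
  x
}

module_load_state <- function(x, st) {
  if (is_gdt(x)) {
    x$value <- st
    return(invisible(NULL))
  }
  if (inherits(x, "gd_module")) {
    nms <- setdiff(ls(x, sorted = TRUE), c("type", "pad"))
    for (nm in nms) {
      cur <- get(nm, envir = x)
      if (is_gdt(cur) || inherits(cur, "gd_module") || is.list(cur)) {
        module_load_state(cur, st[[nm]])
        if (!is_gdt(cur) && !inherits(cur, "gd_module") && is.list(cur)) {
          # lists of plain buffers were replaced in place below
        }
      } else {
        assign(nm, st[[nm]], envir = x)
      }
    }
    return(invisible(NULL))
  }
  if (is.list(x)) {
    for (i in seq_along(x)) module_load_state(x[[i]], st[[i]])
    return(invisible(NULL))
  }
  invisible(NULL)
}
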