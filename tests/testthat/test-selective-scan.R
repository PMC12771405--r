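test_that("discretization follows the zero-order-hold / Euler rule", {
  d0 <- discretize(0, -1, 5)
  expect_identical(d0$A_bar, 1)
  expect_identical(d0$B_bar, 0)
  expect_equal(discretize(log(2), -1, 1)$A_bar, 0.5)
  d <- discretize(0.5, -2, 3)
  expect_equal(d$A_bar, exp(-1))
  expect_equal(d$B_bar, 1.5)
  # vectorized over positions
  dv <- discretize(c(0.1, 0.2), -1, c(2, 4))
  expect_equal(dv$A_bar, exp(-c(0.1, 0.2)))
  expect_equal(dv$B_bar, c(0.2, 0.8))
  expect_error(discretize(NA, -1, 1), "non-finite")
  expect_error(discretize(0.1, Inf, 1), "non-finite")
})

test_that("single-step and cumulative-sum unrollings of the scan are exact", {
  # L = 1: y_1 = C_1 (B_bar_1 u_1) + D u_1
  u <- matrix(2, 1, 1); delta <- matrix(0.3, 1, 1)
  B <- matrix(1.5, 2, 1); Ct <- matrix(c(0.5, -1), 2, 1)
  A <- matrix(c(-1, -2), 1, 2); D <- 0.25
  y <- selective_scan_1d(u, delta, B, Ct, A, D)
  expect_equal(as.numeric(y), sum(Ct[, 1] * (0.3 * 1.5 * 2)) + 0.25 * 2)
  # A = 0, delta = 1, B = C = 1, D = 0 reduces to a cumulative sum
  y2 <- selective_scan_1d(matrix(1, 1, 3), matrix(1, 1, 3),
                          matrix(1, 1, 3), matrix(1, 1, 3),
                          matrix(0, 1, 1), 0)
  expect_equal(as.numeric(y2), c(1, 2, 3))
})

test_that("selective scan matches the naive loop oracle on random instances", {
  for (seed in 1:50) {
    inst <- random_scan_instance(seed)
    y <- selective_scan_1d(inst$u, inst$delta, inst$B, inst$Ct, inst$A, inst$D)
    y0 <- naive_scan(inst$u, inst$delta, inst$B, inst$Ct, inst$A, inst$D)
    expect_lt(max(abs(y - y0)) / max(abs(y0)), 1e-6)
  }
})

test_that("the scan is causal, and reversed scans are anti-causal", {
  inst <- random_scan_instance(99, Lmax = 32)
  L <- ncol(inst$u)
  y <- selective_scan_1d(inst$u, inst$delta, inst$B, inst$Ct, inst$A, inst$D)
  t0 <- floor(L / 2)
  u2 <- inst$u; u2[, (t0 + 1):L] <- 0
  y2 <- selective_scan_1d(u2, inst$delta, inst$B, inst$Ct, inst$A, inst$D)
  expect_equal(y2[, 1:t0], y[, 1:t0])
  # a reversed-direction scan (reversed input and per-position parameters)
  # reads the sequence anti-causally: its output at original position t
  # depends only on positions t..L
  rv <- function(m) m[, ncol(m):1, drop = FALSE]
  yr <- rv(selective_scan_1d(rv(inst$u), rv(inst$delta), rv(inst$B),
                             rv(inst$Ct), inst$A, inst$D))
  u3 <- inst$u; u3[, 1:(t0 - 1)] <- 0 # zero strictly-earlier positions
  yr3 <- rv(selective_scan_1d(rv(u3), rv(inst$delta), rv(inst$B),
                              rv(inst$Ct), inst$A, inst$D))
  expect_equal(yr3[, t0:L], yr[, t0:L])
  expect_false(isTRUE(all.equal(yr3[, 1:(t0 - 1)], yr[, 1:(t0 - 1)])))
})

test_that("scan parameter validation rejects malformed inputs", {
  expect_error(selective_scan_1d(matrix(1, 1, 3), matrix(1, 1, 2),
                                 matrix(1, 1, 3), matrix(1, 1, 3),
                                 matrix(0, 1, 1), 0),
               "length mismatch")
  expect_error(selective_scan_1d(matrix(NA_real_, 1, 2), matrix(1, 1, 2),
                                 matrix(1, 1, 2), matrix(1, 1, 2),
                                 matrix(0, 1, 1), 0),
               "non-finite")
})

test_that("cross-scan produces the four raster traversals", {
  # 2x2 grid [[a,b],[c,d]]
  X <- array(0, dim = c(1, 2, 2))
  X[1, , ] <- matrix(c(1, 3, 2, 4), 2, 2) # a=1 b=2 / c=3 d=4
  sc <- cross_scan(X)
  expect_equal(as.numeric(sc$D1), c(1, 2, 3, 4))
  expect_equal(as.numeric(sc$D2), c(4, 3, 2, 1))
  expect_equal(as.numeric(sc$D3), c(1, 3, 2, 4))
  expect_equal(as.numeric(sc$D4), c(4, 2, 3, 1))
  # single cell: all four sequences are that pixel
  X1 <- array(7, dim = c(3, 1, 1))
  expect_true(all(vapply(cross_scan(X1), function(m) all(m == 7), TRUE)))
  # permutation property on a random map
  set.seed(3)
  Xr <- array(rnorm(2 * 3 * 5), dim = c(2, 3, 5))
  for (m in cross_scan(Xr)) {
    expect_equal(apply(m, 1, sort), apply(matrix(Xr, nrow = 2), 1, sort),
                 ignore_attr = TRUE)
  }
  expect_error(cross_scan(matrix(1, 2, 2)), "array")
})

test_that("cross-merge inverts the layouts and sums the four grids", {
  lay <- scan_layouts(3, 4)
  for (l in lay) {
    expect_equal(sort(l$index_map), 1:12)
    expect_equal(l$inverse_map[l$index_map], 1:12)
  }
  # constant sequences of value v merge to 4v
  Yc <- lapply(lay, function(l) matrix(2.5, 1, 12))
  names(Yc) <- names(lay)
  expect_true(all(cross_merge(Yc, 3, 4) == 10))
  # merge(scan(X)) = 4X exactly
  set.seed(4)
  X <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
  expect_identical(cross_merge(cross_scan(X), 3, 4), 4 * X)
  # random per-direction outputs against the index-bookkeeping oracle
  Y <- lapply(lay, function(l) matrix(rnorm(2 * 12), 2, 12))
  names(Y) <- names(lay)
  expect_equal(cross_merge(Y, 3, 4), naive_merge(Y, 3, 4))
  # errors
  Ybad <- Y; Ybad$D2 <- Y$D2[, 1:6, drop = FALSE]
  expect_error(cross_merge(Ybad, 3, 4), "length mismatch")
  expect_error(cross_merge(Y[c("D1", "D2", "D3")], 3, 4), "directions")
})
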