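## Validation of the network primitives against independent oracles:
## a naive triple-loop convolution and central finite differences.

naive_conv3d <- function(x, w, b, stride, pad, groups) {
  d <- dim(x); k <- dim(w)[1]; cing <- dim(w)[4]; cout <- dim(w)[5]
  coutg <- cout / groups
  os <- (d[1:3] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(os, cout, d[5]))
  for (n in seq_len(d[5])) for (co in seq_len(cout)) {
    g <- (co - 1) %/% coutg
    for (oz in seq_len(os[3])) for (oy in seq_len(os[2]))
      for (ox in seq_len(os[1])) {
        acc <- if (length(b)) b[co] else 0
        for (ci in seq_len(cing)) {
          ch <- g * cing + ci
          for (kz in 1:k) for (ky in 1:k) for (kx in 1:k) {
            ix <- (ox - 1) * stride - pad + kx
            iy <- (oy - 1) * stride - pad + ky
            iz <- (oz - 1) * stride - pad + kz
            if (ix >= 1 && ix <= d[1] && iy >= 1 && iy <= d[2] &&
                iz >= 1 && iz <= d[3])
              acc <- acc + x[ix, iy, iz, ch, n] * w[kx, ky, kz, ci, co]
          }
        }
        y[ox, oy, oz, co, n] <- acc
      }
  }
  y
}

test_that("grouped 3D convolution matches a naive triple-loop oracle", {
  ns <- asNamespace("msnet3d")
  set.seed(21)
  cases <- list(list(k = 3L, s = 1L, p = 1L, g = 2L),
                list(k = 3L, s = 2L, p = 1L, g = 1L),
                list(k = 1L, s = 1L, p = 0L, g = 1L),
                list(k = 5L, s = 1L, p = 2L, g = 4L))
  for (cs in cases) {
    x <- array(rnorm(5 * 5 * 5 * 4 * 2), c(5, 5, 5, 4, 2))
    w <- array(rnorm(cs$k^3 * (4 / cs$g) * 8), c(cs$k, cs$k, cs$k,
                                                 4 / cs$g, 8))
    b <- rnorm(8)
    got <- ns$conv3d_fw(x, w, b, cs$s, cs$p, cs$g)
    want <- naive_conv3d(x, w, b, cs$s, cs$p, cs$g)
    expect_equal(as.vector(got), as.vector(want), tolerance = 1e-12)
  }
})

test_that("convolution gradients match central finite differences", {
  ns <- asNamespace("msnet3d")
  set.seed(22)
  x <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
  w <- array(rnorm(27 * 1 * 4), c(3, 3, 3, 1, 4))  # groups = 2
  gy <- array(rnorm(4 * 4 * 4 * 4 * 2), c(4, 4, 4, 4, 2))
  bw <- ns$conv3d_bw(x, w, gy, 1L, 1L, 2L, FALSE, TRUE)
  L <- function(x., w.) sum(ns$conv3d_fw(x., w., numeric(0), 1L, 1L, 2L) *
                              gy)
  eps <- 1e-6
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bw$gx[i], (L(xp, w) - L(xm, w)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (j in sample(length(w), 5)) {
    wp <- w; wp[j] <- wp[j] + eps
    wm <- w; wm[j] <- wm[j] - eps
    expect_equal(bw$gw[j], (L(x, wp) - L(x, wm)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("batch norm normalises per channel and back-propagates exactly", {
  ns <- asNamespace("msnet3d")
  set.seed(23)
  layer <- ns$layer_bn(3L)
  x <- array(rnorm(6 * 6 * 6 * 3 * 4, mean = 2, sd = 3), c(6, 6, 6, 3, 4))
  fw <- ns$layer_forward(layer, x, training = TRUE, keep = TRUE)
  ## per-channel mean ~0, var ~1 after normalisation (gamma=1, beta=0)
  for (c in 1:3) {
    ch <- fw$y[, , , c, ]
    expect_equal(mean(ch), 0, tolerance = 1e-10)
    expect_equal(var(as.vector(ch)) * (length(ch) - 1) / length(ch), 1,
                 tolerance = 1e-3)
  }
  ## finite-difference check through a scalar objective
  gy <- array(rnorm(length(x)), dim(x))
  bw <- ns$layer_backward(fw$layer, fw$cache, gy)
  eps <- 1e-5
  Lat <- function(x.) {
    f <- ns$layer_forward(layer, x., training = TRUE, keep = FALSE)
    sum(f$y * gy)
  }
  for (i in sample(length(x), 4)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bw$gx[i], (Lat(xp) - Lat(xm)) / (2 * eps),
                 tolerance = 1e-4)
  }
  ## evaluation mode uses running statistics and is deterministic
  ev1 <- ns$layer_forward(fw$layer, x, training = FALSE, keep = FALSE)
  ev2 <- ns$layer_forward(fw$layer, x, training = FALSE, keep = FALSE)
  expect_identical(ev1$y, ev2$y)
})

test_that("channel split is an exact exhaustive partition", {
  set.seed(24)
  x <- array(rnorm(4 * 4 * 4 * 48 * 2), c(4, 4, 4, 48, 2))
  parts <- split_channels(x, c(8, 8, 16, 8, 8))
  expect_length(parts, 5L)
  expect_equal(dim(parts[[3]])[4], 16L)
  expect_identical(concat_channels(parts), x)
  ## single part: identity
  expect_identical(split_channels(x, 48L)[[1]], x)
  expect_error(split_channels(x, c(8, 8)), "widths sum")
})

test_that("Xavier initialisation uses the Glorot bound and zero shifts", {
  ns <- asNamespace("msnet3d")
  set.seed(25)
  fc <- ns$xavier_fill(ns$layer_fc(1024L, 256L))
  bound <- sqrt(6 / (1024 + 256))
  expect_lte(max(abs(fc$params$W)), bound)
  expect_gt(max(abs(fc$params$W)), 0.9 * bound)  # fills the range
  expect_true(all(fc$params$b == 0))
  bn <- ns$xavier_fill(ns$layer_bn(8L))
  expect_true(all(bn$params$beta == 0) && all(bn$params$gamma == 1))
})
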