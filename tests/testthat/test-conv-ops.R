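# Convolution, gating and SCR-block behaviour on single feature maps.

test_that("conv_bn_relu: zero weights give a zero map", {
  x <- random_map(4, 4, 3)
  k <- array(0, c(3, 3, 3, 5))
  out <- conv_bn_relu(x, k)
  expect_equal(dim(out), c(4L, 4L, 5L))
  expect_true(all(out == 0))
})

test_that("conv_bn_relu: 1x1 identity kernel is the identity", {
  x <- random_map(5, 6, 4)
  k <- array(0, c(1, 1, 4, 4))
  for (c in 1:4) k[1, 1, c, c] <- 1
  out <- conv_bn_relu(x, k, activation = "none")
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("conv_bn_relu matches a sliding-window oracle", {
  # frozen example: 2x2 input [[1,2],[3,4]], single 3x3 kernel of ones,
  # "same" padding -> every output pixel sees the whole input, sum = 10
  x <- array(c(1, 3, 2, 4), c(2, 2, 1))
  k <- array(1, c(3, 3, 1, 1))
  out <- conv_bn_relu(x, k)
  expect_equal(array(out, c(2, 2)), matrix(10, 2, 2))

  # random case against a direct R sliding-window implementation
  set.seed(42)
  x <- random_map(6, 5, 3, seed = 42)
  k <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  out <- conv_bn_relu(x, k, activation = "none")
  oracle <- array(0, c(6, 5, 2))
  for (h in 1:6) for (w in 1:5) for (co in 1:2) {
    s <- 0
    for (di in -1:1) for (dj in -1:1) for (ci in 1:3) {
      hh <- h + di; ww <- w + dj
      if (hh >= 1 && hh <= 6 && ww >= 1 && ww <= 5)
        s <- s + x[hh, ww, ci] * k[di + 2, dj + 2, ci, co]
    }
    oracle[h, w, co] <- s
  }
  expect_equal(out, oracle, tolerance = 1e-10)
})

test_that("conv_bn_relu enforces channel agreement and relu sign", {
  x <- random_map(4, 4, 3)
  expect_error(conv_bn_relu(x, array(1, c(3, 3, 2, 4))), "channel")
  out <- conv_bn_relu(x, array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)))
  expect_true(all(out >= 0))
})

test_that("channel gate scales by sigmoid of pooled statistics", {
  z <- random_map(3, 3, 4)
  # zero 1x1 weights and bias -> scale is exactly sigmoid(0) = 0.5
  g <- gate_channels(z, matrix(0, 4, 4), rep(0, 4))
  expect_equal(g$scale, rep(0.5, 4))
  expect_equal(g$out, 0.5 * z, tolerance = 1e-12)

  # saturating bias -> scale ~ 1, output ~ z
  g <- gate_channels(z, matrix(0, 4, 4), rep(50, 4))
  expect_equal(g$out, z, tolerance = 1e-8)

  # 2x2x2 case against a hand-computed pool -> conv -> sigmoid -> multiply
  z <- array(c(1, 2, 3, 4, -1, 0, 1, 2), c(2, 2, 2))
  W <- matrix(c(0.1, -0.2, 0.3, 0.4), 2, 2)
  b <- c(0.05, -0.1)
  p <- c(mean(z[, , 1]), mean(z[, , 2]))            # (2.5, 0.5)
  u <- as.vector(t(W) %*% p) + b
  s <- 1 / (1 + exp(-u))
  g <- gate_channels(z, W, b)
  expect_equal(g$scale, s, tolerance = 1e-12)
  expect_equal(g$out[, , 1], z[, , 1] * s[1], tolerance = 1e-12)
  expect_equal(g$out[, , 2], z[, , 2] * s[2], tolerance = 1e-12)
})

test_that("gating never increases activation magnitude", {
  for (seed in 1:5) {
    z <- random_map(4, 4, 6, seed)
    set.seed(seed)
    g <- gate_channels(z, matrix(rnorm(36), 6, 6), rnorm(6))
    expect_true(all(abs(g$out) <= abs(z)))
  }
})

test_that("zero-weight SCR block is the identity map", {
  blk <- zero_block(scr_layer(4L, seed = 1))
  x <- random_map(6, 6, 4)
  expect_equal(scr_block(x, blk), x, tolerance = 1e-12)
  # also for the no-sharing and strict-gate forms
  expect_equal(scr_block(x, zero_block(scr_layer(4L, sharing = FALSE))), x,
               tolerance = 1e-12)
  expect_equal(scr_block(x, zero_block(scr_layer(4L, strict_gate = TRUE))),
               x, tolerance = 1e-12)
})

test_that("SCR block equals the composition of its constituent ops", {
  set.seed(11)
  blk <- scr_layer(4L, seed = 11)
  x <- random_map(8, 8, 4, seed = 12)

  # independent composition using the single-map functional ops
  bn_of <- function(lay) list(gamma = lay$params$gamma,
                              beta = lay$params$beta,
                              mean = lay$state$rmean, var = lay$state$rvar)
  y <- conv_bn_relu(x, blk$sub$conv1$params$W, bn = bn_of(blk$sub$conv1))
  sh <- share_channels(x, y)
  xsc <- conv_bn_relu(sh$x_concat, blk$sub$conv_x$params$W,
                      bn = bn_of(blk$sub$conv_x))
  ysc <- conv_bn_relu(sh$y_concat, blk$sub$conv_y$params$W,
                      bn = bn_of(blk$sub$conv_y))
  gx <- gate_channels(xsc, blk$sub$gate_x$params$W, blk$sub$gate_x$params$b,
                      bn = bn_of(blk$sub$gate_x))
  gy <- gate_channels(ysc, blk$sub$gate_y$params$W, blk$sub$gate_y$params$b,
                      bn = bn_of(blk$sub$gate_y))
  manual <- gx$out + gy$out + x

  expect_equal(scr_block(x, blk), manual, tolerance = 1e-10)
})

test_that("sharing rearranges but never creates parameters or values", {
  # with sharing disabled the paths see x and conv(x) directly
  blk <- scr_layer(4L, sharing = FALSE, seed = 2)
  x <- random_map(4, 4, 4, seed = 3)
  expect_equal(dim(scr_block(x, blk)), dim(x))
  expect_error(scr_layer(5L), "even")
})
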