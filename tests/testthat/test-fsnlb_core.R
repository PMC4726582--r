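test_that("parameter validation rejects non-positive delta/slope/sigma", {
  expect_error(bc_params(delta = 0), "delta")
  expect_error(bc_params(slope = -1), "slope")
  expect_error(bc_params(sigma_mm = 0), "sigma_mm")
  expect_error(bc_params(high_weight = -0.1), "high_weight")
})

test_that("transfer curve fixes the center, has slope-at-center gain and saturates", {
  p <- bc_params()
  expect_equal(bc_transfer(30, p), 30)
  expect_equal(bc_transfer(35, p), 30 + 25 * tanh(1), tolerance = 1e-10)
  expect_equal(contrast_gain(p, 30), 5)
  expect_lt(contrast_gain(p, 1e6), 1e-12)
  # output confined to the saturation band [center -/+ slope*delta]
  x <- seq(-1000, 3000, length.out = 1000)
  y <- bc_transfer(x, p)
  expect_true(all(y >= 30 - 25 & y <= 30 + 25))
})

test_that("transfer is strictly monotone and tends to identity for wide delta", {
  # strict ordering over the brain attenuation range (the curve is flat to
  # machine precision deep in the saturated tails)
  p <- bc_params()
  set.seed(21)
  x <- runif(10000, -45, 105)
  y <- runif(10000, -45, 105)
  lo <- pmin(x, y); hi <- pmax(x, y)
  keep <- lo < hi
  expect_true(all(bc_transfer(lo[keep], p) < bc_transfer(hi[keep], p)))
  # non-strict monotone everywhere
  xs <- sort(runif(5000, -1024, 3071))
  expect_true(all(diff(bc_transfer(xs, p)) >= 0))

  ident <- bc_params(slope = 1, delta = 1e6)
  x <- seq(-100, 150, length.out = 101)
  expect_lt(max(abs(bc_transfer(x, ident) - x)), 1e-6)
})

test_that("contrast gain agrees with a finite difference of the transfer", {
  p <- bc_params(center = 32, delta = 7, slope = 4)
  set.seed(22)
  at <- runif(100, -20, 90)
  h <- 1e-4
  fd <- (bc_transfer(at + h, p) - bc_transfer(at - h, p)) / (2 * h)
  expect_lt(max(abs(contrast_gain(p, at) - fd)), 1e-6)
})

test_that("band split passes DC, reconstructs exactly, and rejects tiny images", {
  p <- bc_params()
  const <- ct_slice(matrix(30, 32, 32), spacing = c(1, 1))
  b <- decompose_bands(const, p)
  expect_lt(max(abs(b$low - 30)), 1e-9)
  expect_lt(max(abs(b$high)), 1e-9)

  set.seed(23)
  for (i in 1:5) {
    px <- matrix(rnorm(48 * 80, 30, 10), 48, 80)
    s <- ct_slice(px, spacing = c(runif(1, 0.4, 1.2), runif(1, 0.4, 1.2)))
    b <- decompose_bands(s, p)
    expect_lt(max(abs(b$low + b$high - px)), 1e-6)
  }
  expect_error(decompose_bands(ct_slice(matrix(0, 4, 4)), p), "8x8")
})

test_that("filter response on a sinusoid matches the analytic Gaussian MTF", {
  sp <- 0.86
  p <- bc_params(sigma_mm = 2)
  sigma_px <- 2 / sp
  n <- 256
  crop <- 41:216  # away from the mirrored borders
  for (f in c(0.02, 0.05, 0.1)) {
    px <- 30 + 10 * sin(2 * pi * f * col(matrix(0, n, n)))
    s <- ct_slice(px, spacing = c(sp, sp))
    b <- decompose_bands(s, p)
    measured <- sd(b$low[crop, crop] - mean(b$low[crop, crop])) /
      sd(px[crop, crop] - mean(px[crop, crop]))
    analytic <- exp(-2 * pi^2 * sigma_px^2 * f^2)
    expect_lt(abs(measured - analytic) / analytic, 0.02)
  }
})

test_that("uniform images map through the transfer; checkerboards stay in the high band", {
  p <- bc_params()
  u <- apply_bc(ct_slice(matrix(33, 32, 32)), p)
  expect_lt(max(abs(u$pixels - bc_transfer(33, p))), 1e-9)
  expect_true(u$processed)

  n <- 64
  checker <- 2 * outer(1:n, 1:n, function(i, j) (i + j) %% 2) - 1
  s <- ct_slice(30 + 3 * checker, spacing = c(0.9, 0.9))
  out <- apply_bc(s, p)
  inner <- 17:48
  expect_lt(max(abs(out$pixels[inner, inner] -
                      (30 + 3 * checker[inner, inner]))), 1e-3)

  # halved high_weight halves the checkerboard amplitude
  out2 <- apply_bc(s, bc_params(high_weight = 0.5))
  expect_lt(max(abs(out2$pixels[inner, inner] -
                      (30 + 1.5 * checker[inner, inner]))), 1e-3)
})

test_that("a broad 4 HU step straddling the center is amplified at least 3x", {
  n <- 256
  px <- matrix(28, n, n)
  px[, (n / 2 + 1):n] <- 32
  s <- ct_slice(px, spacing = c(0.86, 0.86))
  out <- apply_bc(s)
  left <- mean(out$pixels[, 20:60])
  right <- mean(out$pixels[, 197:237])
  step <- right - left
  expect_gte(step, 3 * 4)
  expect_equal(step, 2 * 25 * tanh(0.4), tolerance = 0.05)
})

test_that("frequency selectivity spares white noise from the transfer gain", {
  set.seed(24)
  px <- matrix(rnorm(256^2, 30, 4), 256, 256)
  s <- ct_slice(px, spacing = c(0.86, 0.86))
  bcout <- apply_bc(s)$pixels
  plain <- bc_transfer(px)
  expect_lt(sd(bcout - mean(bcout)), 0.5 * sd(plain - mean(plain)))
})

test_that("two uniform blocks at center +/- 2 HU gain at least 3x contrast", {
  n <- 128
  px <- matrix(28, n, n)
  px[, (n / 2 + 1):n] <- 32
  s <- ct_slice(px, spacing = c(0.86, 0.86))
  out <- apply_bc(s)$pixels
  d <- mean(out[, 97:128]) - mean(out[, 1:32])
  expect_gte(d, 3 * 4)
})

test_that("re-applying BC still satisfies the band-complement identity", {
  set.seed(25)
  s <- ct_slice(matrix(rnorm(64^2, 30, 5), 64, 64), spacing = c(1, 1))
  once <- apply_bc(s)
  b <- decompose_bands(once)
  expect_lt(max(abs(b$low + b$high - once$pixels)), 1e-6)
  twice <- apply_bc(once)
  expect_false(isTRUE(all.equal(twice$pixels, once$pixels)))
})
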