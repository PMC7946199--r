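test_that("diffusion leaves constant images unchanged and conserves the mean", {
  con <- matrix(123.4, 64, 64)
  expect_equal(anisotropicDiffuse(con, diffusionConfig(n_iter = 30)), con,
               tolerance = 1e-14)
  g <- makeCompositePhantom(96, seed = 1) + noise_matrix(96, sd = 10, seed = 2)
  d <- anisotropicDiffuse(g, diffusionConfig(n_iter = 50))
  expect_equal(mean(d), mean(g), tolerance = 1e-9)
})

test_that("diffusion obeys the maximum principle", {
  g <- noise_matrix(64, sd = 40, seed = 5) + 100
  d <- anisotropicDiffuse(g, diffusionConfig(n_iter = 25))
  expect_gte(min(d), min(g))
  expect_lte(max(d), max(g))
})

test_that("diffusion smooths flat regions while keeping the edge, unlike a linear blur", {
  set.seed(8)
  clean <- matrix(50, 64, 64); clean[, 33:64] <- 200
  noisy <- clean + matrix(rnorm(64 * 64, sd = 10), 64, 64)
  d <- anisotropicDiffuse(noisy, diffusionConfig(n_iter = 20))
  flat <- d[, 5:28]
  expect_lte(var(c(flat)), 0.2 * var(c(noisy[, 5:28])))
  edge_grad <- max(abs(d[, 33] - d[, 32]))
  expect_gte(edge_grad, 0.7 * 150)
  # linear diffusion (conduction ~ 1) smooths as much but destroys the edge
  blur <- anisotropicDiffuse(noisy, diffusionConfig(kappa = 1e6, n_iter = 20))
  expect_lte(var(c(blur[, 5:28])), 0.2 * var(c(noisy[, 5:28])))
  expect_lt(max(abs(blur[, 33] - blur[, 32])), 0.7 * 150)
})

test_that("unstable diffusion steps are rejected", {
  expect_error(diffusionConfig(lam = 0.3), "stability")
})

test_that("the noise-level estimate is calibrated and scales linearly", {
  pure <- noise_matrix(256, sd = 25, seed = 10)
  est <- estimateSigma(pure)
  expect_lt(abs(est - 25), 2)
  est2 <- estimateSigma(2 * pure)
  expect_equal(est2 / est, 2, tolerance = 0.1)
  expect_identical(estimateSigma(matrix(7, 32, 32)), 0)
})

test_that("BM3D is near-identity on a clean image", {
  f <- makeCompositePhantom(128, seed = 1)
  out <- bm3dDenoise(f, bm3dConfig(sigma = 1))
  expect_true(all(is.finite(out)))
  expect_gte(psnr(f, out), 45)
})

test_that("BM3D removes Gaussian noise with a clear PSNR gain", {
  f <- makeCompositePhantom(128, seed = 1)
  g <- f + noise_matrix(128, sd = 25, seed = 3)
  out <- bm3dDenoise(g, bm3dConfig(sigma = 25))
  expect_gte(psnr(f, out) - psnr(f, g), 5)
  expect_identical(out, bm3dDenoise(g, bm3dConfig(sigma = 25)))  # deterministic
})

test_that("hard thresholding cannot alter content shared by a whole group", {
  # perfectly periodic image: every matched patch is identical, so all group
  # energy lies in the exempt stack-DC slice
  tex <- matrix(rep(c(0, 80), length.out = 64), 64, 64)
  out <- bm3dDenoise(tex, bm3dConfig(sigma = 50))
  expect_lt(max(abs(out - tex)), 0.05 * 80)
})

test_that("auto sigma on a constant image returns the input with a notice", {
  con <- matrix(50, 64, 64)
  expect_message(out <- bm3dDenoise(con, bm3dConfig(sigma = 0)), "unchanged")
  expect_identical(out, con)
})
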