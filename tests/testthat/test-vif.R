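test_that("subband blocks have the documented tiling arithmetic", {
  f <- makeCompositePhantom(96, seed = 1)
  sb <- subbandBlocks(f)
  expect_length(sb, 9)                      # 3 orientations x 3 scales
  # level-l subband of a 96-side image has side 96 / 2^l
  for (l in 1:3) {
    side <- 96 / 2^l
    nb <- (side %/% 3)^2
    expect_identical(dim(sb[[sprintf("s%d_d", l)]]), c(9L, as.integer(nb)))
  }
  expect_true(all(abs(subbandBlocks(matrix(42, 96, 96))$s1_h) < 1e-10))
  expect_error(subbandBlocks(matrix(0, 48, 48)), "72x72")
})

test_that("the wavelet decomposition conserves energy (Parseval)", {
  x <- noise_matrix(64, seed = 1)
  d <- VMDespeckle:::.dwt2(x, 3)
  e <- sum(vapply(d$details, function(m) sum(m^2), numeric(1))) +
    sum(d$approx^2)
  expect_equal(e, sum(x^2), tolerance = 1e-6)
})

test_that("GSM fit recovers a known block covariance", {
  d <- 9
  set.seed(42)
  A <- matrix(rnorm(d * d), d)
  Sigma0 <- crossprod(A) / d + diag(d)
  blocks <- t(chol(Sigma0)) %*% matrix(rnorm(d * 1e4), d)
  fit <- gsmFit(blocks)
  relerr <- norm(fit$C_U - Sigma0, "F") / norm(Sigma0, "F")
  expect_lt(relerr, 0.10)
  expect_equal(mean(fit$s2), 1, tolerance = 0.1)
})

test_that("GSM scale field behaves under degenerate and scaled inputs", {
  z <- matrix(0, 9, 50)
  expect_true(all(gsmFit(z)$s2 == 0))
  set.seed(7)
  b <- matrix(rnorm(9 * 2000), 9)
  f1 <- gsmFit(b)
  f2 <- gsmFit(2 * b)
  r <- mean(f2$s2) * sum(f2$lambda) / (mean(f1$s2) * sum(f1$lambda))
  expect_equal(r, 4, tolerance = 0.01)
})

test_that("distortion fit identifies gain and additive noise", {
  f <- makeCompositePhantom(96, seed = 2)
  rb <- subbandBlocks(f)$s1_d
  nz <- apply(rb, 2, var) > 1e-6
  idf <- distortionFit(rb, rb)
  expect_equal(idf$g[nz], rep(1, sum(nz)), tolerance = 1e-6)
  expect_lt(max(idf$sv2[nz]), 1e-8)
  att <- distortionFit(rb, 0.5 * rb)
  expect_equal(att$g[nz], rep(0.5, sum(nz)), tolerance = 1e-6)
  set.seed(3)
  noisy <- rb + matrix(rnorm(length(rb), sd = 10), nrow(rb))
  nf <- distortionFit(rb, noisy)
  expect_equal(mean(nf$sv2), 100, tolerance = 0.15)
})

test_that("vif is 1 for an identical image and fails on a constant reference", {
  f <- makeCompositePhantom(128, seed = 1)
  expect_equal(vif(f, f)$value, 1, tolerance = 1e-6)
  expect_error(vif(matrix(5, 128, 128), f), "no information")
})

test_that("vif decreases strictly with added noise and collapses for a constant test", {
  f <- makeCompositePhantom(128, seed = 1)
  v <- vapply(c(5, 10, 20), function(s)
    vif(f, f + noise_matrix(128, sd = s, seed = 4))$value, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v < 1 + 1e-3))
  expect_lt(vif(f, matrix(100, 128, 128))$value, 0.01)
})

test_that("vif is blind to offsets and rewards gain as contrast change", {
  f <- makeCompositePhantom(128, seed = 2)
  expect_equal(vif(f, f + 40)$value, 1, tolerance = 1e-9)
  expect_gte(vif(f, 1.5 * f + 10)$value, 1)  # contrast amplification
})

test_that("the vif value equals the ratio of its per-subband sums", {
  f <- makeCompositePhantom(96, seed = 3)
  g <- f + noise_matrix(96, sd = 8, seed = 5)
  sc <- vif(f, g)
  expect_identical(sc$value,
                   sum(sc$per_subband$numerator_bits) /
                     sum(sc$per_subband$denominator_bits))
})
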