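test_that("zero-noise speckle is the identity", {
  f <- makeCompositePhantom(64, seed = 1)
  expect_identical(addSpeckle(f, sigma = 0, seed = 3), f)
})

test_that("exponent 1 gives the pure multiplicative model", {
  f <- makeCompositePhantom(64, seed = 1)
  eta <- addSpeckle(matrix(1, 64, 64), sigma = 0.3, n_exponent = 1,
                    seed = 11) - 1
  g <- addSpeckle(f, sigma = 0.3, n_exponent = 1, seed = 11)
  expect_equal(g, f * (1 + eta), tolerance = 1e-12)
})

test_that("speckle variance follows the closed form Var(f^n eta) = f^(2n) sigma^2", {
  f <- matrix(100, 512, 512)
  g <- addSpeckle(f, sigma = 0.6, n_exponent = 0.5, seed = 2)
  expect_equal(var(c(g - f)), 100 * 0.36, tolerance = 0.05)
})

test_that("speckle residual is Gaussian with the model variance", {
  f <- makeCompositePhantom(350, seed = 2)
  sigma <- 0.4
  g <- addSpeckle(f, sigma = sigma, seed = 1)
  resid <- (g - f) / sqrt(f)
  ks <- suppressWarnings(ks.test(c(resid), "pnorm", sd = sigma))
  expect_gt(ks$p.value, 0.01)
})

test_that("invalid speckle inputs error", {
  f <- makeCompositePhantom(64, seed = 1)
  neg <- f; neg[1, 1] <- -5
  expect_error(addSpeckle(neg, sigma = 0.5), "negative")
  bad <- f; bad[2, 2] <- NA
  expect_error(addSpeckle(bad, sigma = 0.5), "finite")
  expect_error(addSpeckle(f, sigma = -1), "sigma")
})

test_that("log/exp transforms are an exact inverse pair", {
  f <- makeCompositePhantom(64, seed = 3) + 1
  expect_equal(max(abs(expTransform(logTransform(f)) - f)), 0,
               tolerance = 1e-12)
  expect_true(all(logTransform(matrix(1, 16, 16)) == 0))
  expect_equal(logTransform(matrix(exp(1), 16, 16)),
               matrix(1, 16, 16), tolerance = 1e-12)
  z <- matrix(0, 16, 16)
  expect_error(logTransform(z), "shift")
  expect_equal(expTransform(logTransform(z, shift = TRUE), shift = TRUE), z,
               tolerance = 1e-12)
})

test_that("composite phantom has the documented structure", {
  f <- makeCompositePhantom(302, seed = 1)
  expect_identical(dim(f), c(302L, 302L))
  expect_identical(f, makeCompositePhantom(302, seed = 1))
  expect_false(identical(f, makeCompositePhantom(302, seed = 2)))
  levels <- sort(unique(c(f)))
  expect_gte(length(levels), 3)
  expect_lte(min(levels), 40)
  expect_gte(max(levels), 220)
  # histogram modes: each constructed level occupies a real area
  counts <- table(c(f))
  expect_gte(sum(counts > 50), 3)
  shapes <- attr(f, "shapes")
  expect_true(any(vapply(shapes, `[[`, "", "kind") == "disk"))
  expect_error(makeCompositePhantom(32), "size")
})

test_that("organ phantom is deterministic with darker inclusions than capsule", {
  f <- makeOrganPhantom(256, seed = 4)
  expect_identical(dim(f), c(256L, 256L))
  expect_identical(f, makeOrganPhantom(256, seed = 4))
  lv <- attr(f, "levels")
  capsule <- f[abs(f - lv["capsule"]) < 1e-9]
  expect_gt(lv[["capsule"]], lv[["inclusion"]])
  # measured on the image, not just the metadata
  expect_gt(mean(f[f > 150]), mean(f[f > 60 & f < 80]))
})
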