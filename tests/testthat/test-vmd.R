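test_that("half-plane masks match brute-force enumeration on an 8x8 grid", {
  freqs <- (0:7) / 8
  freqs[freqs >= 0.5] <- freqs[freqs >= 0.5] - 1
  for (omega in list(c(0, 1), c(1, 0), c(0.3, -0.2), c(-0.1, 0.25))) {
    m <- halfplaneMask(c(8, 8), omega)
    oracle <- matrix(FALSE, 8, 8)
    for (i in 1:8) for (j in 1:8)
      oracle[i, j] <- freqs[j] * omega[1] + freqs[i] * omega[2] >= 0
    expect_identical(m, oracle, label = paste(omega, collapse = ","))
  }
})

test_that("opposite center frequencies give complementary masks off the boundary", {
  m1 <- halfplaneMask(c(16, 12), c(0.2, 0.1))
  m2 <- halfplaneMask(c(16, 12), c(-0.2, -0.1))
  g <- VMDespeckle:::.freq_grids(16, 12)
  boundary <- abs(g$FX * 0.2 + g$FY * 0.1) < 1e-12
  expect_true(all((m1 | m2)))
  expect_true(all(xor(m1[!boundary], m2[!boundary])))
  expect_true(all(m1[boundary] & m2[boundary]))
})

test_that("zero center frequency requires the DC convention", {
  expect_error(halfplaneMask(c(8, 8), c(0, 0)), "dc")
  m <- halfplaneMask(c(8, 8), c(0, 0), dc = TRUE)
  g <- VMDespeckle:::.freq_grids(8, 8)
  expect_identical(m, g$FX >= 0)
})

test_that("a constant image decomposes into a constant DC mode", {
  f <- matrix(77, 64, 64)
  ms <- vmdDecompose(f, vmdConfig(K = 1))
  expect_equal(max(abs(modes(ms)[[1]] - 77)), 0, tolerance = 1e-6)
  expect_equal(centerFrequencies(ms)[1, ], c(0, 0))
})

test_that("center frequencies of tones match the FFT-peak oracle within one bin", {
  # uniform narrow-band penalty: every mode, including mode 1, must lock
  # onto a single spectral line
  N <- 128
  f1 <- tone_image(N, fx = 8)
  ms1 <- vmdDecompose(f1, fast_vmd(K = 2, alpha = 2000))
  peak <- fft_peak(f1)
  expect_equal(peak, c(8 / N, 0))                 # oracle sanity
  om <- centerFrequencies(ms1)[2, ]
  expect_lt(max(abs(om - peak)), 1 / N)

  f2 <- 128 + 60 * cos(2 * pi * 6 * col(matrix(0, N, N)) / N) +
    60 * cos(2 * pi * 30 * (col(matrix(0, N, N)) + row(matrix(0, N, N))) / N)
  ms2 <- vmdDecompose(f2, fast_vmd(K = 3, alpha = 2000))
  om2 <- centerFrequencies(ms2)
  expect_lt(max(abs(om2[2, ] - c(6 / N, 0))), 1 / N)
  expect_lt(max(abs(om2[3, ] - c(30 / N, 30 / N))), 1 / N)
})

test_that("reconstruction with residual reproduces the input exactly", {
  g <- makeCompositePhantom(96, seed = 2) + noise_matrix(96, sd = 4, seed = 7)
  ms <- vmdDecompose(g, fast_vmd(K = 3))
  expect_equal(reconstruct(ms, include_residual = TRUE), g, tolerance = 1e-12)
  expect_identical(dim(reconstruct(ms)), dim(g))
})

test_that("dual ascent enforces near-exact reconstruction on a clean image", {
  N <- 128
  f <- tone_image(N, 6) + tone_image(N, 20, 20, amp = 40, dc = 0)
  ms <- vmdDecompose(f, vmdConfig(K = 3, tau = 0.5))
  relerr <- norm(f - reconstruct(ms), "F") / norm(f, "F")
  expect_lt(relerr, 0.01)
})

test_that("returned center frequencies are the centroids of the returned spectra", {
  g <- makeCompositePhantom(96, seed = 1) + noise_matrix(96, sd = 3, seed = 3)
  ms <- vmdDecompose(g, fast_vmd(K = 3))
  grids <- VMDespeckle:::.freq_grids(96, 96)
  for (k in seq_len(length(ms))) {
    p <- Mod(ms@spectra[[k]])^2
    cen <- c(sum(grids$FX * p), sum(grids$FY * p)) / sum(p)
    if (k == 1 && ms@config@dc_mode) next     # DC mode is pinned, not a centroid
    expect_equal(cen, unname(centerFrequencies(ms)[k, ]), tolerance = 1e-6)
  }
})

test_that("modes are ordered by center-frequency magnitude and energy is bounded", {
  g <- makeCompositePhantom(96, seed = 3) + noise_matrix(96, sd = 5, seed = 9)
  for (K in c(2, 4)) {
    ms <- vmdDecompose(g, fast_vmd(K = K))
    nrm <- sqrt(rowSums(centerFrequencies(ms)^2))
    expect_false(is.unsorted(nrm))
    energy <- sum(vapply(modes(ms), function(u) sum(u^2), numeric(1)))
    expect_lte(energy, 2 * sum(g^2))
  }
})

test_that("decomposition is deterministic", {
  g <- makeCompositePhantom(64, seed = 2) + noise_matrix(64, sd = 4, seed = 1)
  a <- vmdDecompose(g, fast_vmd(K = 3))
  b <- vmdDecompose(g, fast_vmd(K = 3))
  expect_identical(modes(a), modes(b))
  expect_identical(centerFrequencies(a), centerFrequencies(b))
})

test_that("infeasible mode counts are rejected", {
  f <- makeCompositePhantom(64, seed = 1)[1:48, 1:48]   # 24 resolvable bins
  expect_error(vmdDecompose(f, vmdConfig(K = 32)), "resolvable")
  expect_error(vmdConfig(K = 0), "K")
})
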