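# Small deterministic images used across tests.

# Horizontal/diagonal cosine gratings on an N x N grid; fx, fy in cycles
# per image (integer -> exactly on a DFT bin).
tone_image <- function(N, fx, fy = 0, amp = 50, dc = 128) {
  x <- matrix(rep(0:(N - 1), each = N), N, N)
  y <- t(x)
  dc + amp * cos(2 * pi * (fx * x + fy * y) / N)
}

# FFT-peak oracle: location of the strongest non-DC coefficient in the
# omega_x >= 0 half-plane, in cycles/pixel.
fft_peak <- function(img) {
  h <- nrow(img); w <- ncol(img)
  P <- Mod(stats::fft(img))^2
  fx <- (seq_len(w) - 1) / w; fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  fy <- (seq_len(h) - 1) / h; fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  FX <- matrix(fx, h, w, byrow = TRUE)
  FY <- matrix(fy, h, w)
  P[FX < 0] <- 0
  P[1, 1] <- 0
  i <- which.max(P)
  c(FX[i], FY[i])
}

noise_matrix <- function(n, sd = 1, seed = 1) {
  withr::with_seed(seed, matrix(stats::rnorm(n * n, sd = sd), n, n))
}

# Fast VMD configuration for small unit-test images.
fast_vmd <- function(K = 3, ...) vmdConfig(K = K, max_iter = 200L, ...)
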