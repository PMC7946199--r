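## Separable periodized Daubechies-2 wavelet transform (internal).
##
## Orthonormal 4-tap filters; for even-length signals the periodized
## transform conserves energy exactly (Parseval), which the GSM/VIF machinery
## relies on. Odd-sized inputs are padded by replicating the last row/column
## before each level.

.db2_lo <- local({
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
})
.db2_hi <- rev(.db2_lo) * c(1, -1, 1, -1)   # g[t] = (-1)^t h[L-1-t]

## One analysis step along rows of x (columns treated as signals):
## returns list(lo, hi), each nrow(x)/2 rows. nrow(x) must be even.
.dwt_step_cols <- function(x, lo = .db2_lo, hi = .db2_hi) {
  n <- nrow(x)
  half <- n %/% 2L
  a <- matrix(0, half, ncol(x))
  d <- matrix(0, half, ncol(x))
  base <- 2L * (seq_len(half) - 1L)
  for (t in 0:3) {
    idx <- (base + t) %% n + 1L
    a <- a + lo[t + 1L] * x[idx, , drop = FALSE]
    d <- d + hi[t + 1L] * x[idx, , drop = FALSE]
  }
  list(lo = a, hi = d)
}

.pad_even <- function(x) {
  if (nrow(x) %% 2L == 1L) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (ncol(x) %% 2L == 1L) x <- cbind(x, x[, ncol(x), drop = FALSE])
  x
}

## Full 2D multi-level decomposition. Returns list with `details`: a named
## list s<l>_h / s<l>_v / s<l>_d per level (h: horizontal detail = high-pass
## along x; v: vertical; d: diagonal), and `approx`: the final lowpass band.
.dwt2 <- function(x, n_scales) {
  details <- list()
  ll <- x
  for (l in seq_len(n_scales)) {
    ll <- .pad_even(ll)
    rowstep <- .dwt_step_cols(ll)                     # along y
    ## along x: transpose trick
    aa <- .dwt_step_cols(t(rowstep$lo))
    dd <- .dwt_step_cols(t(rowstep$hi))
    details[[sprintf("s%d_h", l)]] <- t(aa$hi)        # lo-y, hi-x
    details[[sprintf("s%d_v", l)]] <- t(dd$lo)        # hi-y, lo-x
    details[[sprintf("s%d_d", l)]] <- t(dd$hi)        # hi-y, hi-x
    ll <- t(aa$lo)
  }
  list(details = details, approx = ll)
}
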