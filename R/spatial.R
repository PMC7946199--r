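## Spatial-domain denoisers routed by frequency band: anisotropic diffusion
## for the low-frequency mode, two-stage BM3D for the high-frequency modes.

#' Perona-Malik anisotropic diffusion
#'
#' Explicit 4-neighbor diffusion
#' \eqn{I \leftarrow I + \lambda \sum_d c(|\nabla_d I|) \nabla_d I}
#' with zero-flux (Neumann) boundaries, where the conduction
#' \eqn{c(x) = \exp(-(x/\kappa)^2)} (or \eqn{1/(1+(x/\kappa)^2)}) shuts
#' diffusion down across gradients much larger than \code{kappa}: flat
#' regions are averaged while strong edges are preserved. The scheme obeys
#' a maximum principle (output range within input range) and conserves the
#' global mean.
#'
#' @param image numeric matrix.
#' @param config a [DiffusionConfig-class].
#' @return A numeric matrix of the same shape.
#' @examples
#' f <- makeCompositePhantom(size = 64, seed = 1)
#' g <- addSpeckle(f, sigma = 0.2, seed = 2)
#' d <- anisotropicDiffuse(g, diffusionConfig(n_iter = 10))
#' @export
anisotropicDiffuse <- function(image, config = diffusionConfig()) {
  .checkImage(image)
  validObject(config)
  cfun <- if (config@conduction == "exp") {
    function(d) exp(-(d / config@kappa)^2)
  } else {
    function(d) 1 / (1 + (d / config@kappa)^2)
  }
  I <- image
  h <- nrow(I); w <- ncol(I)
  for (it in seq_len(config@n_iter)) {
    ## neighbor differences with replicated edges => zero boundary flux
    dN <- rbind(I[1, , drop = FALSE], I[-h, , drop = FALSE]) - I
    dS <- rbind(I[-1, , drop = FALSE], I[h, , drop = FALSE]) - I
    dW <- cbind(I[, 1, drop = FALSE], I[, -w, drop = FALSE]) - I
    dE <- cbind(I[, -1, drop = FALSE], I[, w, drop = FALSE]) - I
    I <- I + config@lam * (cfun(abs(dN)) * dN + cfun(abs(dS)) * dS +
                           cfun(abs(dW)) * dW + cfun(abs(dE)) * dE)
  }
  I
}

#' Robust noise-level estimate
#'
#' Median absolute deviation of the finest-scale diagonal wavelet detail
#' coefficients, scaled by the Gaussian consistency constant:
#' \code{median(|HH1|) / 0.6745}.
#'
#' @param image numeric matrix, at least 16 x 16.
#' @return Estimated noise standard deviation (0 for a constant image).
#' @export
estimateSigma <- function(image) {
  .checkImage(image, min_side = 16L)
  hh <- .dwt2(image, 1L)$details$s1_d
  est <- stats::median(abs(hh)) / 0.6745
  # constant images leave only rounding dust in the detail band
  if (est < 1e-12 * max(1, max(abs(image)))) 0 else est
}

#' Two-stage BM3D collaborative filtering
#'
#' Stage 1 groups, for each reference patch on a \code{step} grid, up to
#' \code{max_match} most-similar patches from the surrounding search
#' window into a 3D stack (ordered by similarity), applies a 2D DCT per
#' patch and a 1D orthonormal Haar along the stack, zeroes 3D coefficients
#' below \code{lambda3d * sigma} (the stack-DC slice, holding the content
#' common to the whole group, is exempt), inverts, and aggregates all
#' overlapping patch estimates with weights \eqn{1/(\sigma^2 N_{kept})}.
#' Stage 2 re-matches on the stage-1 estimate, builds paired groups from
#' the estimate and the noisy input, applies empirical Wiener shrinkage
#' \eqn{W = B^2/(B^2+\sigma^2)} (B the stage-1 group coefficients) to the
#' noisy group, and aggregates with weights \eqn{1/(\sigma^2 \sum W^2)}.
#'
#' @param image numeric matrix on the [0,255] working scale.
#' @param config a [BM3DConfig-class]; with \code{sigma = 0} the noise
#'   level is estimated from the image by [estimateSigma()].
#' @return A numeric matrix of the same shape.
#' @export
bm3dDenoise <- function(image, config = bm3dConfig()) {
  .checkImage(image, min_side = config@patch)
  validObject(config)
  sigma <- config@sigma
  if (sigma == 0) {
    sigma <- estimateSigma(image)
    if (sigma == 0) {
      message("bm3dDenoise: estimated noise level is 0; returning input unchanged")
      return(image)
    }
  }
  bm3d_cpp(image, sigma, config@patch, config@step, config@search,
           config@max_match, config@tau_match[1], config@tau_match[2],
           config@lambda3d)
}
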