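## Full-reference quality metrics on the [0,255] scale.

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(255^2 / \mathrm{MSE})} with the mean squared error
#' over all pixels. Identical images give \code{Inf}.
#'
#' @param reference,test numeric matrices of equal shape.
#' @return PSNR in dB (\code{Inf} when MSE is 0).
#' @examples
#' f <- makeCompositePhantom(size = 64, seed = 1)
#' psnr(f, f + 1)   # 20*log10(255) = 48.1308 dB
#' @export
psnr <- function(reference, test) {
  .checkSameShape(reference, test)
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

## Sliding-window sums via integral images; result (h-win+1) x (w-win+1).
.box_sums <- function(M, win) {
  h <- nrow(M); w <- ncol(M)
  S <- rbind(0, apply(M, 2, cumsum))
  M2 <- S[(win + 1):(h + 1), , drop = FALSE] - S[1:(h - win + 1), , drop = FALSE]
  S2 <- cbind(0, t(apply(M2, 1, cumsum)))
  S2[, (win + 1):(w + 1), drop = FALSE] - S2[, 1:(w - win + 1), drop = FALSE]
}

#' Structural similarity index
#'
#' Mean over all sliding \code{window} x \code{window} positions (uniform
#' weights, stride 1) of
#' \deqn{\frac{(2\mu_f\mu_{\hat f}+c_1)(2\sigma_{f\hat f}+c_2)}
#'            {(\mu_f^2+\mu_{\hat f}^2+c_1)(\sigma_f^2+\sigma_{\hat f}^2+c_2)}}
#' with \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2} and window moments
#' taken with the 1/n convention. 1 for identical images, symmetric in its
#' arguments, bounded in [-1, 1].
#'
#' @param reference,test numeric matrices of equal shape.
#' @param window window side, at most the smaller image dimension.
#' @param k1,k2 stability constants.
#' @param L dynamic range of the pixel scale.
#' @return SSIM value.
#' @export
ssim <- function(reference, test, window = 8L, k1 = 0.01, k2 = 0.03, L = 255) {
  .checkSameShape(reference, test)
  if (window > min(dim(reference)))
    stop("window exceeds image size", call. = FALSE)
  n <- window^2
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  mu_f <- .box_sums(reference, window) / n
  mu_g <- .box_sums(test, window) / n
  var_f <- .box_sums(reference^2, window) / n - mu_f^2
  var_g <- .box_sums(test^2, window) / n - mu_g^2
  cov_fg <- .box_sums(reference * test, window) / n - mu_f * mu_g
  smap <- ((2 * mu_f * mu_g + c1) * (2 * cov_fg + c2)) /
    ((mu_f^2 + mu_g^2 + c1) * (var_f + var_g + c2))
  mean(smap)
}

#' @rdname psnr
#' @return \code{metricReport} returns a named numeric vector with
#'   \code{psnr_db}, \code{ssim} and \code{mse}.
#' @export
metricReport <- function(reference, test) {
  .checkSameShape(reference, test)
  c(psnr_db = psnr(reference, test), ssim = ssim(reference, test),
    mse = mean((reference - test)^2))
}
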