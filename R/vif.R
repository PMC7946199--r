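## Visual information fidelity under a Gaussian scale mixture source model.
##
## The reference image's wavelet detail coefficients are modeled per 3x3
## block as C = s U (U Gaussian with covariance C_U, s a positive scalar per
## block); the test image's coefficients as D = g C + V (deterministic gain
## plus additive Gaussian noise); and perception of either as passing
## through an additive-noise channel of variance sigma_n^2. VIF is the
## ratio of the mutual information the test and the reference each retain
## about the source, summed over all detail subbands.

#' Wavelet subband blocks of an image
#'
#' Decomposes the image with a 3-level (by default) orthogonal Daubechies-2
#' wavelet and tiles every detail subband (horizontal/vertical/diagonal per
#' scale) into non-overlapping 3x3 coefficient blocks. The approximation
#' band is not returned: the GSM source model applies to bandpass
#' coefficients only.
#'
#' @param image numeric matrix.
#' @param config a [VIFConfig-class].
#' @return Named list, one element per subband (\code{s1_h} ... ), each a
#'   9 x n matrix whose columns are vectorized blocks.
#' @export
subbandBlocks <- function(image, config = vifConfig()) {
  validObject(config)
  ## the deepest subband must tile into at least block^2 = 9 blocks for the
  ## GSM covariance fit, i.e. >= 3 blocks of side 3 per dimension
  min_side <- 2L^config@n_scales * config@block * config@block
  if (nrow(image) < min_side || ncol(image) < min_side)
    stop(sprintf("image must be at least %dx%d for %d scales of 3x3 blocks",
                 min_side, min_side, config@n_scales), call. = FALSE)
  .checkImage(image, min_side = min_side)
  dec <- .dwt2(image, config@n_scales)
  lapply(dec$details, .tile_blocks, b = config@block)
}

.tile_blocks <- function(sb, b) {
  nbr <- nrow(sb) %/% b
  nbc <- ncol(sb) %/% b
  sb <- sb[seq_len(nbr * b), seq_len(nbc * b), drop = FALSE]
  dim(sb) <- c(b, nbr, b * nbc)
  sb <- aperm(array(sb, c(b, nbr, b, nbc)), c(1, 3, 2, 4))
  dim(sb) <- c(b * b, nbr * nbc)
  sb
}

#' Fit the Gaussian scale mixture source model
#'
#' Estimates the block covariance \code{C_U} as the mean outer product of
#' mean-removed block vectors and, per block, the maximum-likelihood scale
#' \eqn{s_i^2 = c_i^T C_U^{-1} c_i / 9}, with \eqn{c_i} the raw block
#' vector: an all-zero block (a flat image region contributes no bandpass
#' energy) gets \eqn{s_i^2 = 0} and hence carries no information in either
#' channel. Eigenvalues of \code{C_U} are floored at \code{eps}.
#'
#' @param blocks 9 x n matrix of reference block vectors (n >= 9).
#' @param config a [VIFConfig-class].
#' @return List with \code{C_U} (9x9), \code{lambda} (its eigenvalues),
#'   \code{s2} (length-n block scales).
#' @export
gsmFit <- function(blocks, config = vifConfig()) {
  if (ncol(blocks) < nrow(blocks))
    stop("need at least as many blocks as block dimensions", call. = FALSE)
  d <- nrow(blocks)
  ctr <- blocks - rowMeans(blocks)
  C_U <- tcrossprod(ctr) / ncol(ctr)
  e <- eigen(C_U, symmetric = TRUE)
  lam <- pmax(e$values, config@eps)
  if (any(lam <= 0)) stop("singular block covariance", call. = FALSE)
  y <- crossprod(e$vectors, blocks)            # coordinates in the eigenbasis
  s2 <- pmax(colSums(y^2 / lam) / d, 0)
  list(C_U = e$vectors %*% (lam * t(e$vectors)), lambda = lam, s2 = s2)
}

#' Fit the gain-plus-noise distortion model per block
#'
#' For each reference/test block pair, a least-squares gain
#' \eqn{g_i = \mathrm{cov}(c_i, d_i)/(\mathrm{var}(c_i)+\epsilon)} (clamped
#' at 0) and residual noise variance
#' \eqn{\sigma^2_{v,i} = \mathrm{var}(d_i) - g_i\,\mathrm{cov}(c_i, d_i)}
#' (floored at \code{eps}), with moments taken over the 9 coefficients of
#' the block.
#'
#' @param ref_blocks,test_blocks 9 x n matrices with equal n.
#' @param config a [VIFConfig-class].
#' @return List with numeric vectors \code{g} and \code{sv2}.
#' @export
distortionFit <- function(ref_blocks, test_blocks, config = vifConfig()) {
  if (!identical(dim(ref_blocks), dim(test_blocks)))
    stop("block sets differ in shape", call. = FALSE)
  d <- nrow(ref_blocks)
  mc <- colMeans(ref_blocks); md <- colMeans(test_blocks)
  varc <- colMeans(ref_blocks^2) - mc^2
  vard <- colMeans(test_blocks^2) - md^2
  covcd <- colMeans(ref_blocks * test_blocks) - mc * md
  g <- pmax(covcd / (varc + config@eps), 0)
  sv2 <- pmax(vard - g * covcd, config@eps)
  list(g = g, sv2 = sv2)
}

#' Visual information fidelity of a test image against a reference
#'
#' Per subband and block, the information the perceived test image retains
#' about the source is
#' \eqn{\tfrac12 \sum_j \log_2(1 + g_i^2 s_i^2 \lambda_j /
#' (\sigma^2_{v,i} + \sigma_n^2))} and the information the perceived
#' reference retains is
#' \eqn{\tfrac12 \sum_j \log_2(1 + s_i^2 \lambda_j / \sigma_n^2)}, with
#' \eqn{\lambda_j} the eigenvalues of \code{C_U}. VIF is the ratio of the
#' two, summed over blocks and subbands; it is 1 for an undistorted copy
#' and decreases toward 0 as information is destroyed.
#'
#' @param reference,test numeric matrices of equal shape; \code{reference}
#'   must not be constant.
#' @param config a [VIFConfig-class].
#' @return A list with \code{value} and \code{per_subband} (data frame of
#'   numerator and denominator bits per subband).
#' @examples
#' f <- makeCompositePhantom(size = 96, seed = 1)
#' vif(f, f)$value
#' @export
vif <- function(reference, test, config = vifConfig()) {
  .checkSameShape(reference, test)
  rb <- subbandBlocks(reference, config)
  tb <- subbandBlocks(test, config)
  num <- den <- numeric(length(rb))
  for (j in seq_along(rb)) {
    gsm <- gsmFit(rb[[j]], config)
    dst <- distortionFit(rb[[j]], tb[[j]], config)
    ## outer sums: blocks i in rows, eigenvalues j in columns
    slam <- outer(gsm$s2, gsm$lambda)
    num[j] <- 0.5 * sum(log2(1 + (dst$g^2 / (dst$sv2 + config@sigma_n2)) * slam))
    den[j] <- 0.5 * sum(log2(1 + slam / config@sigma_n2))
  }
  if (sum(den) <= 0)
    stop("reference carries no information (constant image)", call. = FALSE)
  list(value = sum(num) / sum(den),
       per_subband = data.frame(subband = names(rb), numerator_bits = num,
                                denominator_bits = den))
}
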