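## S4 classes: configuration objects and result containers.

#' Configuration for 2D variational mode decomposition
#'
#' Parameters of the spectral ADMM that splits an image into \code{K}
#' band-limited sub-modes. See [vmdDecompose()] for the model.
#'
#' @slot K integer, number of modes (1--32).
#' @slot alpha numeric, bandwidth penalty (or penalties): larger values give
#'   narrower-band modes. A single value applies to every mode; a pair
#'   \code{c(low, high)} applies \code{low} to the first (lowest-frequency)
#'   mode and \code{high} to the rest, letting the low-frequency mode keep a
#'   wide band that captures the image structure while the remaining modes
#'   stay narrow; a length-\code{K} vector sets each mode's penalty.
#' @slot tau numeric, dual-ascent step of the reconstruction constraint
#'   \eqn{\sum_k u_k \approx f}. The default 2 enforces the constraint
#'   tightly, so essentially all input content (noise included) is carried
#'   by the modes and handed to the per-band denoisers; \code{tau = 0}
#'   drops the constraint and leaves unclaimed content in the residual.
#' @slot tol numeric, stopping tolerance on the summed relative change of the
#'   mode spectra between iterations.
#' @slot max_iter integer, iteration cap.
#' @slot dc_mode logical, pin the first mode's center frequency to (0,0).
#' @slot init character, \code{"uniform_grid"} (deterministic ring of center
#'   frequencies in the right half-plane), \code{"zeros"}, or \code{"random"}.
#' @slot seed integer, RNG seed used only when \code{init = "random"}.
#' @export
setClass("VMDConfig", representation(
  K = "integer", alpha = "numeric", tau = "numeric", tol = "numeric",
  max_iter = "integer", dc_mode = "logical", init = "character",
  seed = "integer"))

setValidity("VMDConfig", function(object) {
  msg <- character()
  if (object@K < 1L || object@K > 32L) msg <- c(msg, "K must be in [1, 32]")
  if (any(object@alpha <= 0)) msg <- c(msg, "alpha must be > 0")
  if (!length(object@alpha) %in% c(1L, 2L, object@K))
    msg <- c(msg, "alpha must have length 1, 2 (low, high) or K")
  if (object@tau < 0) msg <- c(msg, "tau must be >= 0")
  if (object@tol <= 0 || object@tol >= 1) msg <- c(msg, "tol must be in (0, 1)")
  if (object@max_iter < 1L) msg <- c(msg, "max_iter must be >= 1")
  if (!object@init %in% c("uniform_grid", "zeros", "random"))
    msg <- c(msg, "init must be 'uniform_grid', 'zeros' or 'random'")
  if (length(msg)) msg else TRUE
})

#' @rdname VMDConfig-class
#' @param K,alpha,tau,tol,max_iter,dc_mode,init,seed see slot documentation.
#' @return A validated \code{VMDConfig} object.
#' @examples
#' vmdConfig(K = 4)
#' @export
vmdConfig <- function(K = 4L, alpha = c(30, 2000), tau = 2, tol = 1e-6,
                      max_iter = 500L, dc_mode = TRUE,
                      init = "uniform_grid", seed = 1L) {
  new("VMDConfig", K = as.integer(K), alpha = as.numeric(alpha),
      tau = as.numeric(tau), tol = as.numeric(tol),
      max_iter = as.integer(max_iter), dc_mode = isTRUE(dc_mode),
      init = init, seed = as.integer(seed))
}

#' Configuration for the visual information fidelity index
#'
#' @slot n_scales integer, number of dyadic wavelet levels.
#' @slot block integer, side of the square coefficient blocks (the GSM model
#'   here is formulated on 3x3 blocks).
#' @slot sigma_n2 numeric, variance of the additive neural-noise channel of
#'   the visual-system model, on the squared wavelet-coefficient scale;
#'   0.4 follows the reference implementation of the block-GSM (wavelet
#'   domain) variant of the index.
#' @slot eps numeric, regularizer flooring eigenvalues and variances.
#' @export
setClass("VIFConfig", representation(
  n_scales = "integer", block = "integer", sigma_n2 = "numeric",
  eps = "numeric"))

setValidity("VIFConfig", function(object) {
  msg <- character()
  if (object@n_scales < 1L) msg <- c(msg, "n_scales must be >= 1")
  if (object@block != 3L) msg <- c(msg, "block size is fixed at 3")
  if (object@sigma_n2 <= 0) msg <- c(msg, "sigma_n2 must be > 0")
  if (object@eps <= 0) msg <- c(msg, "eps must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname VIFConfig-class
#' @param n_scales,block,sigma_n2,eps see slot documentation.
#' @return A validated \code{VIFConfig} object.
#' @export
vifConfig <- function(n_scales = 3L, block = 3L, sigma_n2 = 0.4, eps = 1e-10) {
  new("VIFConfig", n_scales = as.integer(n_scales), block = as.integer(block),
      sigma_n2 = as.numeric(sigma_n2), eps = as.numeric(eps))
}

#' Configuration for Perona-Malik anisotropic diffusion
#'
#' @slot kappa numeric, gradient scale of the conduction function, on the
#'   [0,255] intensity scale; gradients well above kappa stop diffusion.
#' @slot lam numeric, explicit Euler step weight, must be in (0, 0.25] for
#'   4-neighbor stability.
#' @slot n_iter integer, number of diffusion steps.
#' @slot conduction character, \code{"exp"} for \eqn{c(x)=\exp(-(x/\kappa)^2)}
#'   or \code{"rational"} for \eqn{c(x)=1/(1+(x/\kappa)^2)}.
#' @export
setClass("DiffusionConfig", representation(
  kappa = "numeric", lam = "numeric", n_iter = "integer",
  conduction = "character"))

setValidity("DiffusionConfig", function(object) {
  msg <- character()
  if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
  if (object@lam <= 0 || object@lam > 0.25)
    msg <- c(msg, "lam must be in (0, 0.25] (4-neighbor stability)")
  if (object@n_iter < 1L) msg <- c(msg, "n_iter must be >= 1")
  if (!object@conduction %in% c("exp", "rational"))
    msg <- c(msg, "conduction must be 'exp' or 'rational'")
  if (length(msg)) msg else TRUE
})

#' @rdname DiffusionConfig-class
#' @param kappa,lam,n_iter,conduction see slot documentation.
#' @return A validated \code{DiffusionConfig} object.
#' @export
diffusionConfig <- function(kappa = 30, lam = 0.25, n_iter = 20L,
                            conduction = "exp") {
  new("DiffusionConfig", kappa = as.numeric(kappa), lam = as.numeric(lam),
      n_iter = as.integer(n_iter), conduction = conduction)
}

#' Configuration for two-stage BM3D collaborative filtering
#'
#' @slot patch integer, side of the square patches.
#' @slot step integer, stride of the reference-patch grid; must not exceed
#'   \code{patch} so that every pixel is covered.
#' @slot search integer, odd side of the square search window centered on the
#'   reference patch.
#' @slot max_match integer, maximum patches per 3D group; a power of two (the
#'   stack transform is a dyadic Haar).
#' @slot tau_match numeric length 2, mean-squared-distance gates for stage-1
#'   and stage-2 matching, on the [0,255] intensity scale.
#' @slot lambda3d numeric, hard-threshold multiplier: stage-1 3D coefficients
#'   smaller than \code{lambda3d * sigma} are zeroed.
#' @slot sigma numeric, noise standard deviation; \code{0} means estimate it
#'   from the image with [estimateSigma()].
#' @export
setClass("BM3DConfig", representation(
  patch = "integer", step = "integer", search = "integer",
  max_match = "integer", tau_match = "numeric", lambda3d = "numeric",
  sigma = "numeric"))

setValidity("BM3DConfig", function(object) {
  msg <- character()
  if (object@patch < 2L) msg <- c(msg, "patch must be >= 2")
  if (object@step < 1L || object@step > object@patch)
    msg <- c(msg, "step must be in [1, patch] (full pixel coverage)")
  if (object@search < object@patch || object@search %% 2L == 0L)
    msg <- c(msg, "search must be odd and >= patch")
  if (object@max_match < 1L ||
      bitwAnd(object@max_match, object@max_match - 1L) != 0L)
    msg <- c(msg, "max_match must be a power of 2")
  if (length(object@tau_match) != 2L || any(object@tau_match <= 0))
    msg <- c(msg, "tau_match must be two positive gates (stage 1, stage 2)")
  if (object@lambda3d <= 0) msg <- c(msg, "lambda3d must be > 0")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname BM3DConfig-class
#' @param patch,step,search,max_match,tau_match,lambda3d,sigma see slot
#'   documentation.
#' @return A validated \code{BM3DConfig} object.
#' @export
bm3dConfig <- function(patch = 8L, step = 3L, search = 39L, max_match = 16L,
                       tau_match = c(2500, 400), lambda3d = 2.7, sigma = 0) {
  new("BM3DConfig", patch = as.integer(patch), step = as.integer(step),
      search = as.integer(search), max_match = as.integer(max_match),
      tau_match = as.numeric(tau_match), lambda3d = as.numeric(lambda3d),
      sigma = as.numeric(sigma))
}

#' Band-limited sub-modes of an image
#'
#' Result of [vmdDecompose()]: \code{K} sub-mode images ordered by increasing
#' center-frequency magnitude (mode 1 carries the low-frequency content),
#' their center frequencies, the half-plane analytic spectra the solver
#' converged to, and the convergence trace. The residual is defined as
#' \code{input - sum(modes)}, so summing all modes plus the residual
#' reproduces the input exactly.
#'
#' @slot modes list of numeric matrices, the sub-mode images \eqn{u_k}.
#' @slot omegas K x 2 matrix of center frequencies \eqn{\omega_k} in
#'   cycles/pixel, columns (x, y), each component in [-0.5, 0.5).
#' @slot spectra list of complex matrices, the converged half-plane spectra
#'   (zero outside each mode's half-plane \eqn{\Omega_k}).
#' @slot residual numeric matrix, \code{input - Reduce('+', modes)}.
#' @slot n_iter integer, iterations run.
#' @slot convergence_trace numeric, stopping statistic per iteration.
#' @slot config the \code{VMDConfig} used.
#' @export
setClass("ModeSet", representation(
  modes = "list", omegas = "matrix", spectra = "list", residual = "matrix",
  n_iter = "integer", convergence_trace = "numeric", config = "VMDConfig"))

setValidity("ModeSet", function(object) {
  msg <- character()
  K <- length(object@modes)
  if (K < 1L) msg <- c(msg, "at least one mode required")
  if (!identical(dim(object@omegas), c(K, 2L)))
    msg <- c(msg, "omegas must be K x 2")
  dims <- lapply(object@modes, dim)
  if (length(unique(dims)) != 1L) msg <- c(msg, "modes differ in shape")
  if (!identical(dim(object@residual), dims[[1]]))
    msg <- c(msg, "residual shape differs from modes")
  nrm <- sqrt(rowSums(object@omegas^2))
  if (is.unsorted(nrm, strictly = FALSE))
    msg <- c(msg, "modes must be sorted by increasing |omega|")
  if (length(msg)) msg else TRUE
})

#' Trace of the adaptive mode-count search
#'
#' Bookkeeping of [selectK()]: for every mode count tried, the sub-mode VIF
#' profile (sorted descending), the adjacent differences, how many fell at or
#' below the similarity threshold, and the action taken.
#'
#' @slot tried list; each element has \code{k}, \code{vif} (sorted
#'   descending), \code{delta} (adjacent differences, length k-1), \code{n}
#'   (count of differences at or below the threshold) and \code{action}
#'   (one of \code{"increase"}, \code{"decrease"}, \code{"stop"}).
#' @slot final_K integer, selected mode count.
#' @slot threshold numeric, VIF similarity threshold.
#' @slot warning character, non-empty when a bounds or cycle guard fired.
#' @export
setClass("KSelectTrace", representation(
  tried = "list", final_K = "integer", threshold = "numeric",
  warning = "character"))

setValidity("KSelectTrace", function(object) {
  msg <- character()
  if (object@final_K < 1L) msg <- c(msg, "final_K must be >= 1")
  for (e in object@tried) {
    if (length(e$delta) != e$k - 1L)
      msg <- c(msg, "delta length must be k - 1")
    if (!e$action %in% c("increase", "decrease", "stop"))
      msg <- c(msg, "unknown action")
  }
  if (length(msg)) msg else TRUE
})

#' Result of the frequency-division despeckling pipeline
#'
#' @slot denoised numeric matrix, the reconstructed image.
#' @slot final_K integer, mode count actually used.
#' @slot kselect_trace the [KSelectTrace-class] when \code{k = "auto"}, else
#'   \code{NULL}.
#' @slot per_mode_sigma numeric, noise level used by BM3D for each
#'   high-frequency mode (length \code{final_K - 1}).
#' @slot metrics_before,metrics_after named numeric (\code{psnr_db},
#'   \code{ssim}, \code{mse}) against a clean reference when one was given,
#'   else empty.
#' @slot timings named numeric, seconds per stage.
#' @export
setClass("DespeckleResult", representation(
  denoised = "matrix", final_K = "integer", kselect_trace = "ANY",
  per_mode_sigma = "numeric", metrics_before = "numeric",
  metrics_after = "numeric", timings = "numeric"))
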