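#' @rdname ModeSet-class
#' @param x,object a \code{ModeSet}.
#' @export
setGeneric("modes", function(x) standardGeneric("modes"))

#' @rdname ModeSet-class
#' @export
setGeneric("centerFrequencies", function(x) standardGeneric("centerFrequencies"))

#' Sum sub-modes back into an image
#'
#' Reconstruction is plain summation of the sub-mode images; with
#' \code{include_residual = TRUE} the decomposition residual is added as
#' well, reproducing the decomposed input to machine precision.
#'
#' @param x a [ModeSet-class].
#' @param include_residual logical, add \code{input - sum(modes)} back.
#' @return A numeric matrix.
#' @export
setGeneric("reconstruct", function(x, include_residual = FALSE)
  standardGeneric("reconstruct"))

#' @rdname DespeckleResult-class
#' @param x,object a \code{DespeckleResult}.
#' @export
setGeneric("denoised", function(x) standardGeneric("denoised"))

#' @rdname DespeckleResult-class
#' @export
setGeneric("finalK", function(x) standardGeneric("finalK"))

#' @rdname KSelectTrace-class
#' @param x,object a \code{KSelectTrace}.
#' @export
setGeneric("ksteps", function(x) standardGeneric("ksteps"))

#' @rdname ModeSet-class
#' @export
setMethod("modes", "ModeSet", function(x) x@modes)

#' @rdname ModeSet-class
#' @export
setMethod("centerFrequencies", "ModeSet", function(x) x@omegas)

#' @rdname ModeSet-class
#' @export
setMethod("length", "ModeSet", function(x) length(x@modes))

#' @rdname ModeSet-class
#' @export
setMethod("show", "ModeSet", function(object) {
  d <- dim(object@modes[[1]])
  cat(sprintf("ModeSet: %d modes of %dx%d (%d iterations)\n",
              length(object@modes), d[1], d[2], object@n_iter))
  nrm <- sqrt(rowSums(object@omegas^2))
  for (k in seq_along(object@modes))
    cat(sprintf("  mode %d: omega = (%+.4f, %+.4f) cyc/px, |omega| = %.4f\n",
                k, object@omegas[k, 1], object@omegas[k, 2], nrm[k]))
  invisible(NULL)
})

#' @rdname KSelectTrace-class
#' @export
setMethod("ksteps", "KSelectTrace", function(x) x@tried)

#' @rdname KSelectTrace-class
#' @export
setMethod("show", "KSelectTrace", function(object) {
  cat(sprintf("KSelectTrace: final K = %d (threshold %.4g)\n",
              object@final_K, object@threshold))
  for (e in object@tried)
    cat(sprintf("  K=%d: VIF [%s], n = %d -> %s\n", e$k,
                paste(sprintf("%.4f", e$vif), collapse = ", "),
                e$n, e$action))
  if (nzchar(object@warning)) cat("  warning:", object@warning, "\n")
  invisible(NULL)
})

#' @rdname DespeckleResult-class
#' @export
setMethod("denoised", "DespeckleResult", function(x) x@denoised)

#' @rdname DespeckleResult-class
#' @export
setMethod("finalK", "DespeckleResult", function(x) x@final_K)

#' @rdname DespeckleResult-class
#' @export
setMethod("show", "DespeckleResult", function(object) {
  d <- dim(object@denoised)
  cat(sprintf("DespeckleResult: %dx%d image, K = %d\n",
              d[1], d[2], object@final_K))
  if (length(object@per_mode_sigma))
    cat("  BM3D sigma per high-frequency mode:",
        paste(sprintf("%.2f", object@per_mode_sigma), collapse = ", "), "\n")
  if (length(object@metrics_after))
    cat(sprintf("  vs reference: PSNR %.2f dB, SSIM %.4f (noisy input: %.2f dB)\n",
                object@metrics_after["psnr_db"], object@metrics_after["ssim"],
                object@metrics_before["psnr_db"]))
  invisible(NULL)
})
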