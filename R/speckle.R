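## Speckle noise model and bundled test phantoms.
##
## The observed image follows g = f + f^n * eta with eta an i.i.d. zero-mean
## Gaussian field; n = 0.5 is the conventional exponent for ultrasound data
## and n = 1 gives the pure multiplicative model g = f * (1 + eta). All
## randomness is drawn from the Mersenne-Twister generator (normals by
## inversion), pinned explicitly so a seed reproduces bit-identical output
## on any platform.

.with_pinned_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

#' Corrupt an image with speckle noise
#'
#' Applies the signal-dependent noise model \eqn{g = f + f^n \eta} with
#' \eqn{\eta} i.i.d. zero-mean Gaussian of standard deviation \code{sigma}.
#' With \code{n_exponent = 1} this is the pure multiplicative model
#' \eqn{g = f(1+\eta)}; \code{n_exponent = 0.5} (the default) matches the
#' signal dependence of ultrasound speckle. The output is not clipped to
#' [0,255]; clipping is left to display time.
#'
#' @param image numeric matrix of non-negative intensities (the fractional
#'   power \eqn{f^n} is undefined for negative values).
#' @param sigma standard deviation of the Gaussian field, >= 0. Note the
#'   noise-level sweep reported for this method is parameterized by this
#'   standard deviation (the "noise variance 0.1--0.8" wording of the source
#'   literature is ambiguous; this package treats it as sigma).
#' @param n_exponent model exponent in [0, 1].
#' @param seed integer seed; a fixed seed reproduces the noise field exactly.
#' @return A numeric matrix of the same shape as \code{image}.
#' @examples
#' f <- makeCompositePhantom(size = 64, seed = 1)
#' g <- addSpeckle(f, sigma = 0.6, seed = 7)
#' @export
addSpeckle <- function(image, sigma, n_exponent = 0.5, seed = 1L) {
  .checkImage(image)
  if (any(image < 0))
    stop("negative intensities: f^n is undefined for fractional n", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single value >= 0", call. = FALSE)
  if (n_exponent < 0 || n_exponent > 1)
    stop("n_exponent must be in [0, 1]", call. = FALSE)
  if (sigma == 0) return(image)
  eta <- .with_pinned_seed(seed, matrix(rnorm(length(image), sd = sigma),
                                        nrow(image), ncol(image)))
  image + image^n_exponent * eta
}

#' Logarithmic and exponential intensity transforms
#'
#' Element-wise natural log and its inverse, provided as opt-in utilities
#' for working in the log domain where multiplicative noise becomes
#' additive. \code{expTransform(logTransform(f))} returns \code{f} to
#' machine precision (with matching \code{shift}).
#'
#' @param image numeric matrix; for \code{logTransform} all pixels must be
#'   positive unless \code{shift = TRUE}.
#' @param shift logical; add 1 before the log (and subtract 1 after the
#'   exp), allowing zero-valued pixels.
#' @return A numeric matrix of the same shape.
#' @export
logTransform <- function(image, shift = FALSE) {
  .checkImage(image)
  x <- if (shift) image + 1 else image
  if (any(x <= 0))
    stop("nonpositive pixels: use shift = TRUE or rescale first", call. = FALSE)
  log(x)
}

#' @rdname logTransform
#' @export
expTransform <- function(image, shift = FALSE) {
  .checkImage(image)
  if (shift) exp(image) - 1 else exp(image)
}

## Rasterize helpers on relative [0,1] coordinates; XX varies along columns
## (x), YY along rows (y).
.rel_grid <- function(size) {
  x <- (seq_len(size) - 0.5) / size
  list(XX = matrix(x, size, size, byrow = TRUE),
       YY = matrix(x, size, size, byrow = FALSE))
}

.in_polygon <- function(XX, YY, vx, vy) {
  n <- length(vx)
  inside <- matrix(FALSE, nrow(XX), ncol(XX))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > YY) != (vy[j] > YY)) &
      (XX < (vx[j] - vx[i]) * (YY - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Composite geometric test phantom
#'
#' A deterministic piecewise-constant 302x302-class image assembled from a
#' filled disk, an annular arc, and straight-edged polygons with corners on
#' a uniform background, with gray levels spanning [40, 220]. It bundles in
#' one frame the features that matter for judging a despeckler: flat
#' regions, curved and straight edges, corners, and strong level contrasts.
#' The seed jitters shape placement and levels by a few percent so
#' independent replicates can be generated; the layout itself is fixed.
#'
#' @param size image side in pixels, >= 64 (default 302).
#' @param seed integer seed controlling the placement jitter.
#' @return A numeric matrix with attribute \code{shapes}: a list describing
#'   each painted shape (kind, gray level) plus the background level, in
#'   painting order.
#' @examples
#' f <- makeCompositePhantom(size = 128, seed = 1)
#' range(f)
#' @export
makeCompositePhantom <- function(size = 302L, seed = 1L) {
  size <- as.integer(size)
  if (size < 64L) stop("size must be >= 64", call. = FALSE)
  jit <- .with_pinned_seed(seed, runif(12, -0.02, 0.02))
  g <- .rel_grid(size)
  XX <- g$XX; YY <- g$YY
  img <- matrix(60, size, size)
  shapes <- list(list(kind = "background", level = 60))
  paint <- function(mask, kind, level) {
    img[mask] <<- level
    shapes[[length(shapes) + 1L]] <<- list(kind = kind, level = level)
  }
  ## filled disk, bright
  cx <- 0.32 + jit[1]; cy <- 0.30 + jit[2]
  paint((XX - cx)^2 + (YY - cy)^2 <= 0.16^2, "disk", 220)
  ## annular arc, 250 degrees of a ring
  ax <- 0.70 + jit[3]; ay <- 0.66 + jit[4]
  r2 <- (XX - ax)^2 + (YY - ay)^2
  ang <- atan2(YY - ay, XX - ax)
  paint(r2 >= 0.17^2 & r2 <= 0.235^2 & ang > -2.6 & ang < 1.8, "arc", 160)
  ## rectangle, dark
  paint(XX >= 0.55 + jit[5] & XX <= 0.88 + jit[6] &
          YY >= 0.10 + jit[7] & YY <= 0.30 + jit[8], "rectangle", 40)
  ## triangle
  paint(.in_polygon(XX, YY, c(0.10, 0.44, 0.22) + jit[9],
                    c(0.62, 0.58, 0.93) + jit[10]), "triangle", 130)
  ## small square with corners inside the arc region
  paint(XX >= 0.63 + jit[11] & XX <= 0.76 + jit[11] &
          YY >= 0.58 + jit[12] & YY <= 0.71 + jit[12], "square", 200)
  attr(img, "shapes") <- shapes
  img
}

#' Smooth organ-like test phantom
#'
#' A synthetic stand-in for an ultrasound organ section: an elliptical organ
#' with a bright capsule rim, darker (hypoechoic) interior inclusions, and
#' fine multiplicative texture over the parenchyma. Entirely generated in
#' code; it emulates the gross geometry of an organ scan, not its acoustic
#' physics.
#'
#' @param size image side in pixels, >= 64.
#' @param seed integer seed (texture field and inclusion placement).
#' @return A numeric matrix with attribute \code{levels}: named background,
#'   capsule, interior and inclusion gray levels.
#' @export
makeOrganPhantom <- function(size = 256L, seed = 1L) {
  size <- as.integer(size)
  if (size < 64L) stop("size must be >= 64", call. = FALSE)
  g <- .rel_grid(size)
  XX <- g$XX; YY <- g$YY
  rng <- .with_pinned_seed(seed, list(
    tex = matrix(rnorm(size * size), size, size),
    incl = runif(6, -0.08, 0.08)))
  ## elliptical radius, 1 at the organ boundary
  re <- sqrt(((XX - 0.5) / 0.38)^2 + ((YY - 0.52) / 0.30)^2)
  img <- matrix(30, size, size)
  img[re <= 1] <- 190                       # capsule
  interior <- re <= 0.82
  img[interior] <- 120
  for (i in 1:2) {                          # hypoechoic inclusions
    icx <- 0.40 + (i - 1) * 0.22 + rng$incl[i]
    icy <- 0.50 + (i - 1) * 0.06 + rng$incl[i + 2]
    img[((XX - icx) / 0.07)^2 + ((YY - icy) / 0.09)^2 <= 1 & interior] <- 70
  }
  ## fine multiplicative texture on the parenchyma: 3x3 box-smoothed noise
  sm <- rng$tex
  sm <- (sm +
    rbind(sm[1, , drop = FALSE], sm[-size, ]) +
    rbind(sm[-1, ], sm[size, , drop = FALSE])) / 3
  sm <- (sm +
    cbind(sm[, 1, drop = FALSE], sm[, -size]) +
    cbind(sm[, -1], sm[, size, drop = FALSE])) / 3
  img[interior] <- img[interior] * (1 + 0.06 * sm[interior])
  attr(img, "levels") <- c(background = 30, capsule = 190,
                           interior = 120, inclusion = 70)
  img
}
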