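## Adaptive choice of the 2D-VMD mode count from sub-mode VIF profiles.
##
## Over-decomposition splits one band across near-duplicate modes; their
## VIF scores against the input then nearly coincide. The search walks K up
## until some adjacent pair of sorted VIF scores falls within the
## similarity threshold, then adjusts so that exactly one such pair exists
## at K, and returns K - 1 (the largest count with no duplicated mode).

#' VIF profile of a decomposition
#'
#' Decomposes the image into \code{K} modes and scores each sub-mode
#' against the (noisy) input image with [vif()]; the input is the
#' reference, since mode similarity is judged by how much input information
#' each mode shares. Values are returned sorted descending.
#'
#' @param noisy numeric matrix, the image being decomposed.
#' @param K integer >= 2, mode count to try.
#' @param vmd_config a [VMDConfig-class]; its \code{K} slot is overridden.
#' @param vif_config a [VIFConfig-class].
#' @return Numeric vector of length \code{K}, sorted descending.
#' @export
vifProfile <- function(noisy, K, vmd_config = vmdConfig(),
                       vif_config = vifConfig()) {
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  cfg <- vmd_config
  cfg@K <- as.integer(K)
  ms <- vmdDecompose(noisy, cfg)
  vals <- vapply(modes(ms), function(u) vif(noisy, u, vif_config)$value,
                 numeric(1))
  sort(vals, decreasing = TRUE)
}

## Flowchart engine, independent of how profiles are produced.
## get_profile(K) must return the descending-sorted VIF vector for K modes.
## Returns list(final_K, tried, warning).
.k_search <- function(get_profile, k_init, threshold, k_min, k_max) {
  k_init <- as.integer(k_init); k_min <- as.integer(k_min)
  k_max <- as.integer(k_max)
  if (k_min > k_init || k_init > k_max)
    stop("need k_min <= k_init <= k_max", call. = FALSE)
  K <- k_init
  tried <- list()
  seen_states <- character()
  profiles <- new.env(parent = emptyenv())   # K -> list(vif, delta, n)
  warn <- ""

  eval_K <- function(K) {
    key <- as.character(K)
    if (!is.null(profiles[[key]])) return(profiles[[key]])
    v <- get_profile(K)
    delta <- -diff(v)                        # descending sort => delta >= 0
    profiles[[key]] <- list(vif = v, delta = delta,
                            n = sum(delta <= threshold))
    profiles[[key]]
  }
  best_K <- function() {
    ks <- sort(as.integer(ls(profiles)))
    ok <- ks[vapply(ks, function(k) profiles[[as.character(k)]]$n >= 1L,
                    logical(1))]
    if (!length(ok)) NA_integer_ else ok[1]
  }
  record <- function(K, p, action)
    tried[[length(tried) + 1L]] <<- list(k = K, vif = p$vif, delta = p$delta,
                                         n = p$n, action = action)
  finish <- function(final_K)
    list(final_K = max(as.integer(final_K), 1L), tried = tried, warning = warn)

  repeat {
    p <- eval_K(K)
    action <- if (p$n == 0L) "increase" else if (p$n > 1L) "decrease" else "stop"
    state <- paste0(K, ":", action)
    if (action == "stop") {
      record(K, p, "stop")
      return(finish(K - 1L))
    }
    if (state %in% seen_states) {            # cycle guard
      record(K, p, action)
      bk <- best_K()
      if (is.na(bk))
        stop("no similar-mode pair found in the explored K range", call. = FALSE)
      warn <- sprintf("cycle at K=%d; returning smallest K with a similar pair minus 1", K)
      return(finish(bk - 1L))
    }
    seen_states <- c(seen_states, state)
    record(K, p, action)
    K_next <- if (action == "increase") K + 1L else K - 1L
    if (K_next > k_max || K_next < k_min) {  # bounds guard
      bk <- best_K()
      if (is.na(bk))
        stop("no similar-mode pair found up to k_max", call. = FALSE)
      warn <- sprintf("bound reached at K=%d; returning best-so-far", K)
      return(finish(bk - 1L))
    }
    K <- K_next
  }
}

#' Select the mode count adaptively
#'
#' Implements the VIF-difference flowchart: at the current \code{K},
#' compute the descending-sorted sub-mode VIF profile and the adjacent
#' differences \eqn{\delta_j = v_j - v_{j+1}}. If no \eqn{\delta} is at or
#' below \code{threshold}, increase K; if more than one is, decrease K; if
#' exactly one is, stop and return \code{K - 1}. A cycle guard resolves the
#' oscillating case (no similar pair at K, several at K+1) by returning the
#' smallest visited K that had a similar pair, minus one; bounds guards
#' clamp at \code{k_min}/\code{k_max} and return the best K seen so far
#' with a warning recorded in the trace.
#'
#' @param noisy numeric matrix.
#' @param vmd_config a [VMDConfig-class] (its \code{K} is overridden).
#' @param k_init starting mode count.
#' @param threshold VIF similarity threshold (default 0.001).
#' @param k_min,k_max search bounds.
#' @param vif_config a [VIFConfig-class].
#' @return List with \code{final_K} (integer) and \code{trace}
#'   (a [KSelectTrace-class]).
#' @export
selectK <- function(noisy, vmd_config = vmdConfig(), k_init = 3L,
                    threshold = 0.001, k_min = 2L, k_max = 12L,
                    vif_config = vifConfig()) {
  res <- .k_search(function(K) vifProfile(noisy, K, vmd_config, vif_config),
                   k_init, threshold, k_min, k_max)
  list(final_K = res$final_K,
       trace = new("KSelectTrace", tried = res$tried,
                   final_K = as.integer(res$final_K),
                   threshold = threshold, warning = res$warning))
}
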