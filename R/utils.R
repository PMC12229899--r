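# Internal helpers shared across the pipeline.

#' Gaussian smoothing of a vector
#'
#' NA-aware Gaussian kernel smoothing. Kernel mass falling on NA entries (or
#' outside the vector, for non-circular smoothing) is renormalized away, so
#' unoccupied spatial bins do not drag estimates toward zero.
#'
#' @param x numeric vector (may contain NA).
#' @param sd kernel standard deviation in samples/bins. `sd = 0` returns `x`.
#' @param circular logical; wrap the kernel around the ends (use for binned
#'   maps on the circularized track, not for time series).
#' @return smoothed numeric vector, same length as `x`.
#' @keywords internal
smooth_gaussian <- function(x, sd, circular = FALSE) {
  n <- length(x)
  if (sd <= 0 || n < 2L) return(x)
  half <- min(n - 1L, max(1L, ceiling(4 * sd)))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  xm <- x
  ok <- !is.na(x)
  xm[!ok] <- 0
  if (circular) {
    idx <- c((n - half + 1L):n, 1:n, 1:half)
    xx <- xm[idx]
    ww <- as.numeric(ok)[idx]
    num <- stats::filter(xx, k, sides = 2)[(half + 1L):(half + n)]
    den <- stats::filter(ww, k, sides = 2)[(half + 1L):(half + n)]
  } else {
    num <- as.numeric(stats::filter(c(numeric(half), xm, numeric(half)), k,
                                    sides = 2))[(half + 1L):(half + n)]
    den <- as.numeric(stats::filter(c(numeric(half), as.numeric(ok), numeric(half)), k,
                                    sides = 2))[(half + 1L):(half + n)]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Row-wise smoothing of a trials x bins matrix.
smooth_rows <- function(m, sd, circular = TRUE) {
  if (sd <= 0) return(m)
  t(apply(m, 1L, smooth_gaussian, sd = sd, circular = circular))
}

#' Derive a reproducible child seed
#'
#' Stable 32-bit FNV-1a hash of a root seed and a label, so that independent
#' pipeline stages (or neurons) get decoupled RNG streams: inserting a stage
#' or a neuron does not shift the randomness of the others.
#'
#' @param seed integer root seed.
#' @param label character tag for the consumer (stage or neuron id).
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, label) {
  h <- 17
  for (b in utf8ToInt(paste0(seed, "/", label))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Running min/max with a centered, edge-truncated window. Interior indices
# (full-width windows) use the O(n) aligned-block prefix/suffix trick; the
# short truncated windows at either edge are evaluated directly.
running_extreme <- function(x, window, fun = min) {
  n <- length(x)
  window <- as.integer(window)
  if (window <= 1L) return(x)
  if (window >= 2L * n) return(rep(fun(x), n))
  halfL <- (window - 1L) %/% 2L
  halfR <- window - 1L - halfL
  w <- window
  out <- numeric(n)
  first_full <- halfL + 1L
  last_full <- n - halfR
  if (last_full >= first_full) {
    nb <- ceiling(n / w)
    padval <- if (identical(fun, min)) Inf else -Inf
    xp <- c(x, rep(padval, nb * w - n))
    blocks <- matrix(xp, nrow = w)
    cmf <- if (identical(fun, min)) cummin else cummax
    pref <- as.numeric(apply(blocks, 2L, cmf))
    suff <- as.numeric(apply(blocks[w:1, , drop = FALSE], 2L, cmf)[w:1, , drop = FALSE])
    i <- first_full:last_full
    lo <- i - halfL
    hi <- i + halfR
    cmb <- if (identical(fun, min)) pmin else pmax
    out[i] <- cmb(suff[lo], pref[hi])
  }
  for (i in seq_len(min(halfL, n))) out[i] <- fun(x[1:min(i + halfR, n)])
  if (last_full < n) {
    for (i in (max(last_full + 1L, 1L)):n) out[i] <- fun(x[max(i - halfL, 1L):n])
  }
  out
}

# Polynomial hash of a serialized R object, as a hex string (config stamping).
object_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 17
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
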