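# Trial warping on the position-bin axis. A warp is a monotone
# nondecreasing piecewise-linear map w: [0,1] -> [0,1], stored as knot
# points (xs, ys); evaluation interpolates and clips to the axis range.

warp_eval <- function(warp, x) {
  y <- stats::approx(warp$xs, warp$ys, xout = x, rule = 2, ties = "ordered")$y
  pmin(pmax(y, 0), 1)
}

warp_profile <- function(profile, warp) {
  nb <- length(profile)
  u <- (seq_len(nb) - 1) / (nb - 1)
  xw <- warp_eval(warp, u) * (nb - 1) + 1
  stats::approx(seq_len(nb), profile, xout = xw, rule = 2)$y
}

identity_warp <- function() list(xs = c(0, 1), ys = c(0, 1))

#' Fit a time-warp model to trial speed profiles
#'
#' Aligns trials (rows) to a common template by per-trial monotone
#' piecewise-linear warps of the position-bin axis, by alternating
#' optimization: the template is the mean of the warped trials, and each
#' trial's warp parameters are refined by coordinate descent over a
#' discretized grid (21 candidates per parameter, 10 random restarts).
#' Model families of increasing complexity - shift, linear, piecewise with
#' 1-3 knots - are fit as a warm-started nested chain: each family starts
#' from the previous family's warps and only accepts improvements, so the
#' mean squared error against the template is nonincreasing along the
#' chain. Rewarded and omission trials are fit jointly.
#'
#' @param speed trials x bins matrix of speed profiles (non-finite rows are
#'   excluded and flagged).
#' @param model_type one of "shift", "linear", "piecewise-1", "piecewise-2",
#'   "piecewise-3".
#' @param n_iter alternating-optimization iterations per family (2).
#' @param n_restarts random restarts per trial for piecewise families (10).
#' @param n_grid grid candidates per parameter (21).
#' @param seed RNG seed for restarts.
#' @return object of class `rr_warp`: `warps` (per-trial knot lists),
#'   `template`, `mse` (overall), `mse_per_trial`, `model_type`,
#'   `excluded_trials`.
#' @export
fit_timewarp <- function(speed, model_type = c("shift", "linear",
                                               "piecewise-1", "piecewise-2",
                                               "piecewise-3"),
                         n_iter = 2, n_restarts = 10, n_grid = 21,
                         seed = 1L) {
  model_type <- match.arg(model_type)
  speed <- as.matrix(speed)
  finite_row <- apply(speed, 1L, function(r) all(is.finite(r)))
  excluded <- which(!finite_row)
  X <- speed[finite_row, , drop = FALSE]
  if (nrow(X) < 5L) stop("need at least 5 finite trials")
  n_tr <- nrow(X)
  set.seed(seed)

  chain <- c("shift", "linear", "piecewise-1", "piecewise-2", "piecewise-3")
  chain <- chain[seq_len(match(model_type, chain))]
  warps <- replicate(n_tr, identity_warp(), simplify = FALSE)
  template <- colMeans(X)
  trial_mse <- function(i, w) mean((warp_profile(X[i, ], w) - template)^2)

  grid21 <- function(lo, hi) seq(lo, hi, length.out = n_grid)

  propose_stage <- function(stage, i, incumbent) {
    best <- incumbent
    best_mse <- trial_mse(i, best)
    try_warp <- function(w) {
      m <- trial_mse(i, w)
      if (m < best_mse) { best <<- w; best_mse <<- m }
    }
    if (stage == "shift") {
      for (s in grid21(-0.5, 0.5))
        try_warp(list(xs = c(0, 1), ys = c(s, 1 + s)))
      # refine around the best shift
      s0 <- best$ys[1]
      for (s in grid21(s0 - 0.05, s0 + 0.05))
        try_warp(list(xs = c(0, 1), ys = c(s, 1 + s)))
    } else if (stage == "linear") {
      a <- 1; b <- 0
      for (sweep in 1:2) {
        for (aa in grid21(0.5, 2)) try_warp(list(xs = c(0, 1), ys = c(b, aa + b)))
        ab <- best$ys; a <- ab[2] - ab[1]; b <- ab[1]
        for (bb in grid21(-0.5, 0.5)) try_warp(list(xs = c(0, 1), ys = c(bb, a + bb)))
        ab <- best$ys; a <- ab[2] - ab[1]; b <- ab[1]
      }
    } else {
      k <- as.integer(sub("piecewise-", "", stage))
      xs <- seq(0, 1, length.out = k + 2L)
      starts <- list(warp_eval(best, xs))
      for (r in seq_len(n_restarts))
        starts[[r + 1L]] <- sort(stats::runif(k + 2L, -0.2, 1.2))
      for (ys0 in starts) {
        ys <- ys0
        for (sweep in 1:2) {
          for (j in seq_along(ys)) {
            lo <- if (j == 1L) -0.5 else ys[j - 1L]
            hi <- if (j == length(ys)) 1.5 else ys[j + 1L]
            best_j <- ys[j]; best_jm <- trial_mse(i, list(xs = xs, ys = ys))
            for (yy in grid21(lo, hi)) {
              ys[j] <- yy
              m <- trial_mse(i, list(xs = xs, ys = ys))
              if (m < best_jm) { best_j <- yy; best_jm <- m }
            }
            ys[j] <- best_j
          }
        }
        try_warp(list(xs = xs, ys = ys))
      }
    }
    best
  }

  for (stage in chain) {
    for (it in seq_len(n_iter)) {
      for (i in seq_len(n_tr))
        warps[[i]] <- propose_stage(stage, i, warps[[i]])
      template <- colMeans(do.call(rbind, lapply(seq_len(n_tr), function(i)
        warp_profile(X[i, ], warps[[i]]))))
    }
  }
  W <- do.call(rbind, lapply(seq_len(n_tr), function(i)
    warp_profile(X[i, ], warps[[i]])))
  out <- list(warps = warps, template = template,
              mse = mean((W - matrix(template, n_tr, ncol(X),
                                     byrow = TRUE))^2),
              mse_per_trial = rowMeans((W - matrix(template, n_tr, ncol(X),
                                                   byrow = TRUE))^2),
              model_type = model_type, excluded_trials = excluded,
              trial_rows = which(finite_row))
  class(out) <- "rr_warp"
  out
}

#' @exportS3Method base::print
print.rr_warp <- function(x, ...) {
  cat("Time-warp model (", x$model_type, "):", length(x$warps),
      "trials, MSE =", format(x$mse, digits = 4), "\n")
  invisible(x)
}

#' Apply fitted warps to neural activity
#'
#' Resamples each trial's neural spatial profile through that trial's warp
#' (linear interpolation). The transform is determined entirely by the
#' behavioral (speed) fit and is blind to the neural content.
#'
#' @param model an `rr_warp` fit.
#' @param neural trials x bins matrix or trials x bins x neurons array;
#'   trial rows must correspond to the rows the model was fit on.
#' @return warped array of the same shape.
#' @export
apply_warp <- function(model, neural) {
  stopifnot(inherits(model, "rr_warp"))
  warp_mat <- function(M) {
    stopifnot(nrow(M) == length(model$warps))
    t(sapply(seq_len(nrow(M)), function(i)
      warp_profile(M[i, ], model$warps[[i]])))
  }
  if (is.matrix(neural)) return(warp_mat(neural))
  stopifnot(length(dim(neural)) == 3L)
  out <- neural
  for (j in seq_len(dim(neural)[3])) out[, , j] <- warp_mat(neural[, , j])
  out
}

#' Reward-versus-omission index
#'
#' RO = sum_j (rbar_j - obar_j) / sum_j (rbar_j + obar_j), over position
#' bins j from the reward-zone start to the track end, where rbar_j and
#' obar_j are the mean (warped) activity in bin j across rewarded and
#' omission trials. 1 means exclusive firing on rewarded trials, -1
#' exclusive preference for omissions, 0 equal firing. Eligibility: at
#' least `min_omissions` omission trials in the set, and (when a peak bin
#' is supplied) a spatial peak between the zone start and the track end.
#'
#' @param activity trials x bins matrix (typically warp-transformed
#'   deconvolved activity for one cell).
#' @param rewarded logical per trial (FALSE = omission).
#' @param zone_start_bin first included bin (1-based).
#' @param peak_bin optional spatial peak bin for the eligibility check.
#' @param min_omissions minimum omission trials (3).
#' @return list: `ro`, `eligible`, `n_omission`.
#' @export
reward_omission_index <- function(activity, rewarded, zone_start_bin,
                                  peak_bin = NULL, min_omissions = 3) {
  stopifnot(nrow(activity) == length(rewarded))
  nb <- ncol(activity)
  n_om <- sum(!rewarded)
  eligible <- n_om >= min_omissions &&
    (is.null(peak_bin) || (peak_bin >= zone_start_bin && peak_bin <= nb))
  bins <- zone_start_bin:nb
  rbar <- colMeans(activity[rewarded, bins, drop = FALSE], na.rm = TRUE)
  obar <- colMeans(activity[!rewarded, bins, drop = FALSE], na.rm = TRUE)
  rbar[is.nan(rbar)] <- 0; obar[is.nan(obar)] <- 0
  den <- sum(rbar + obar)
  ro <- if (den == 0) NaN else sum(rbar - obar) / den
  list(ro = ro, eligible = eligible, n_omission = n_om)
}
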