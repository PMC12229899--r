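#' Fit a circular-linear decoder of phase from population activity
#'
#' Linear ridge maps from activity to the unit-circle targets (cos y, sin y)
#' with an atan2 readout. The decode score of a sample is cos(y - yhat): 1
#' is perfect prediction, 0 chance.
#'
#' @param X samples x neurons activity matrix.
#' @param y phases in radians.
#' @param lambda ridge penalty (1e-3); stabilizes rank-deficient activity.
#' @return object of class `rr_decoder` with the weight matrix (intercept
#'   in the first row).
#' @export
fit_circular_decoder <- function(X, y, lambda = 1e-3) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) >= 2L, nrow(X) >= 100L)
  Xa <- cbind(1, X)
  G <- crossprod(Xa) + diag(c(0, rep(lambda, ncol(X))))
  W <- solve(G, crossprod(Xa, cbind(cos(y), sin(y))))
  structure(list(W = W), class = "rr_decoder")
}

#' @rdname fit_circular_decoder
#' @param object an `rr_decoder`.
#' @param newdata samples x neurons matrix.
#' @param ... unused.
#' @return predicted phases in radians.
#' @export
predict.rr_decoder <- function(object, newdata, ...) {
  P <- cbind(1, as.matrix(newdata)) %*% object$W
  atan2(P[, 2], P[, 1])
}

decode_score <- function(y, yhat) cos(y - yhat)

#' Reward-relative position decoding protocol with shuffle z-scoring
#'
#' Decodes the animal's reward-relative phase from deconvolved activity
#' (speed > 2 cm/s frames), after downsampling to equalize occupancy across
#' the 45 reward-relative phase bins. Modes: "within_before" runs tenfold
#' cross-validation inside the pre-switch trials; "before_after" trains on
#' the pre-switch trials and tests on the last 30 post-switch trials
#' (matching the pre-switch trial count). Chance is estimated by refitting
#' on 100 shuffled datasets in which each neuron's time series is
#' independently circularly shifted by at least one sample; the session
#' score is z-scored against the shuffle scores, overall and per phase bin.
#'
#' @param session an `rr_session`.
#' @param neurons neuron indices of the subpopulation to decode from.
#' @param mode "within_before" or "before_after".
#' @param n_folds cross-validation folds (10).
#' @param n_shuffles shuffles (100).
#' @param speed_min speed filter (2 cm/s).
#' @param seed RNG seed.
#' @return list of class `rr_decode`: `score` (mean over samples and folds),
#'   `shuffle_scores`, `z`, `z_per_bin`, `n_samples`.
#' @export
decode_protocol <- function(session, neurons,
                            mode = c("within_before", "before_after"),
                            n_folds = 10, n_shuffles = 100, speed_min = 2,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (length(neurons) == 0L) stop("empty subpopulation")
  cfg <- session$config
  if (is.null(seed)) seed <- derive_seed(cfg$seed, paste0("decode-", mode))
  fr <- session$frames
  nb <- cfg$n_bins
  zone_phase <- to_periodic(session$trials$zone_start_cm, cfg$track_length_cm)
  ok <- !is.na(fr$position_cm) & !fr$teleport & fr$speed_cms >= speed_min
  phase <- align_to_reward(to_periodic(fr$position_cm, cfg$track_length_cm),
                           zone_phase[fr$trial])

  sets <- default_trial_sets(session)
  pre_tr <- sets$pre
  post_tr <- sets$post
  post_tr <- post_tr[seq.int(max(1L, length(post_tr) - length(pre_tr) + 1L),
                             length(post_tr))]   # last trials, count-matched

  set.seed(seed)
  ds_bin_idx <- function(idx) {
    b <- floor((phase[idx] + pi) / (2 * pi / nb)) + 1L
    b[b > nb] <- nb
    cnt <- table(factor(b, levels = seq_len(nb)))
    m <- min(cnt[cnt > 0])
    keep <- unlist(lapply(which(cnt > 0), function(bb) {
      cand <- idx[b == bb]
      if (length(cand) > m) sample(cand, m) else cand
    }), use.names = FALSE)
    sort(keep)
  }
  idx_pre <- ds_bin_idx(which(ok & fr$trial %in% pre_tr))
  idx_post <- ds_bin_idx(which(ok & fr$trial %in% post_tr))

  n_all <- nrow(fr)
  ev <- session$events[, neurons, drop = FALSE]
  act_at <- function(idx, shifts = NULL) {
    if (is.null(shifts)) return(ev[idx, , drop = FALSE])
    out <- matrix(0, length(idx), ncol(ev))
    for (j in seq_len(ncol(ev)))
      out[, j] <- ev[((idx - 1L - shifts[j]) %% n_all) + 1L, j]
    out
  }
  folds <- sample(rep_len(seq_len(n_folds), length(idx_pre)))

  run_once <- function(shifts) {
    if (mode == "within_before") {
      sc <- numeric(0); ph <- numeric(0)
      for (f in seq_len(n_folds)) {
        tr <- idx_pre[folds != f]; te <- idx_pre[folds == f]
        dec <- fit_circular_decoder(act_at(tr, shifts), phase[tr])
        yh <- predict(dec, act_at(te, shifts))
        sc <- c(sc, decode_score(phase[te], yh)); ph <- c(ph, phase[te])
      }
      list(scores = sc, phases = ph)
    } else {
      dec <- fit_circular_decoder(act_at(idx_pre, shifts), phase[idx_pre])
      yh <- predict(dec, act_at(idx_post, shifts))
      list(scores = decode_score(phase[idx_post], yh), phases = phase[idx_post])
    }
  }

  real <- run_once(NULL)
  shuffle_scores <- numeric(n_shuffles)
  shuffle_bin <- matrix(NA_real_, n_shuffles, nb)
  bin_of <- function(ph) pmin(floor((ph + pi) / (2 * pi / nb)) + 1L, nb)
  for (s in seq_len(n_shuffles)) {
    shifts <- sample.int(n_all - 1L, ncol(ev), replace = TRUE)
    r <- run_once(shifts)
    shuffle_scores[s] <- mean(r$scores)
    shuffle_bin[s, ] <- tapply(r$scores, factor(bin_of(r$phases),
                                                levels = seq_len(nb)), mean)
  }
  real_bin <- tapply(real$scores, factor(bin_of(real$phases),
                                         levels = seq_len(nb)), mean)
  z <- (mean(real$scores) - mean(shuffle_scores)) / stats::sd(shuffle_scores)
  mu_b <- colMeans(shuffle_bin, na.rm = TRUE)
  sd_b <- apply(shuffle_bin, 2L, stats::sd, na.rm = TRUE)
  out <- list(score = mean(real$scores), shuffle_scores = shuffle_scores,
              z = z, z_per_bin = as.numeric((real_bin - mu_b) / sd_b),
              n_samples = length(real$scores), mode = mode)
  class(out) <- "rr_decode"
  out
}

#' @exportS3Method base::print
print.rr_decode <- function(x, ...) {
  cat(sprintf("Decode (%s): score %.3f, shuffle %.3f +/- %.3f, z = %.2f\n",
              x$mode, x$score, mean(x$shuffle_scores),
              stats::sd(x$shuffle_scores), x$z))
  invisible(x)
}
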