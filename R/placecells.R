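#' Spatial information in bits
#'
#' SI = sum_i p_i (f_i / f) log2(f_i / f), where p_i is the occupancy
#' probability of bin i, f_i the trial-averaged activity in bin i and
#' f = sum_i f_i p_i the overall mean rate. Bins with f_i = 0 contribute 0;
#' a silent cell (f = 0) has SI defined as 0. Deconvolved activity is the
#' intended input, since it removes the asymmetric calcium-kernel smoothing.
#'
#' @param tpm trials x bins activity matrix (see [bin_by_position()]), or a
#'   precomputed tuning vector f_i.
#' @param occupancy occupancy: a trials x bins count matrix (per-trial
#'   probabilities are averaged across trials), or a probability vector
#'   summing to 1.
#' @return SI in bits (nonnegative up to floating error).
#' @export
spatial_information <- function(tpm, occupancy) {
  f_i <- if (is.matrix(tpm)) colMeans(tpm, na.rm = TRUE) else as.numeric(tpm)
  f_i[is.nan(f_i)] <- 0
  p <- occupancy_prob(occupancy, length(f_i))
  f <- sum(f_i * p)
  if (f <= 0) return(0)
  pos <- f_i > 0 & p > 0
  sum(p[pos] * (f_i[pos] / f) * log2(f_i[pos] / f))
}

occupancy_prob <- function(occupancy, n_bins) {
  if (is.matrix(occupancy)) {
    tot <- rowSums(occupancy)
    pr <- occupancy / ifelse(tot == 0, 1, tot)
    p <- colMeans(pr)
  } else {
    p <- as.numeric(occupancy)
  }
  stopifnot(length(p) == n_bins)
  p / sum(p)
}

#' Shuffle null distribution of spatial information for one neuron
#'
#' Builds the null by circularly shifting the neuron's activity relative to
#' position independently within each trial, by a uniform offset between
#' ~1 s (ceiling of the frame rate, in samples) and the trial length, then
#' recomputing SI from the shuffled trial-averaged tuning.
#'
#' @param trace per-frame activity (deconvolved events).
#' @param position_cm,trial,speed_cms,teleport per-frame behavior series.
#' @param n_shuffles number of shuffles (100).
#' @param frame_rate_hz sampling rate (sets the ~1 s minimum offset).
#' @param n_bins,track_length_cm,speed_min binning parameters.
#' @param seed RNG seed for the offsets.
#' @return list with `si` (true SI) and `null` (vector of shuffle SIs).
#' @export
si_significance <- function(trace, position_cm, trial, speed_cms = NULL,
                            teleport = NULL, n_shuffles = 100,
                            frame_rate_hz = 15.5, n_bins = 45,
                            track_length_cm = 450, speed_min = 2,
                            seed = 1L) {
  if (length(unique(trial)) < 2L) stop("need at least 2 trials")
  prep <- si_prepare(position_cm, trial, speed_cms, teleport, n_bins,
                     track_length_cm, speed_min)
  set.seed(seed)
  si <- si_from_activity(matrix(trace[prep$frames], ncol = 1L), prep)
  shuf <- si_shuffled(as.numeric(trace[prep$frames]), prep, n_shuffles,
                      frame_rate_hz)
  list(si = as.numeric(si), null = shuf)
}

# Precompute binning/segment structure over included frames of a trial set.
si_prepare <- function(position_cm, trial, speed_cms, teleport, n_bins,
                       track_length_cm, speed_min, p_occ = NULL) {
  include <- !is.na(position_cm)
  if (!is.null(teleport)) include <- include & !teleport
  if (!is.null(speed_cms)) include <- include & speed_cms >= speed_min
  frames <- which(include)
  tr <- trial[frames]
  trials <- sort(unique(tr))
  tr_i <- match(tr, trials)
  b <- floor((position_cm[frames] %% track_length_cm) /
               (track_length_cm / n_bins)) + 1L
  key <- (tr_i - 1L) * n_bins + b
  ukey <- sort(unique(key))
  cnt <- as.numeric(rowsum(rep(1, length(key)), key))
  binof <- (ukey - 1L) %% n_bins + 1L
  trials_per_bin <- as.numeric(table(factor(binof, levels = seq_len(n_bins))))
  # segment bookkeeping for within-trial circular shifts (frames are in
  # time order within each trial)
  lens <- as.integer(table(factor(tr_i, levels = seq_along(trials))))
  seg_len <- lens[tr_i]
  seg_start <- (c(0L, cumsum(lens))[tr_i] + 1L)
  pos_in_seg <- seq_along(frames) - seg_start
  if (is.null(p_occ)) {
    occ <- matrix(0, length(trials), n_bins)
    occ[cbind((ukey - 1L) %/% n_bins + 1L, (ukey - 1L) %% n_bins + 1L)] <- cnt
    p_occ <- occupancy_prob(occ, n_bins)
  }
  list(frames = frames, key = key, ukey = ukey, cnt = cnt, binof = binof,
       trials_per_bin = trials_per_bin, n_bins = n_bins, tr_i = tr_i,
       lens = lens, n_trials = length(trials), seg_len = seg_len,
       seg_start = seg_start, pos_in_seg = pos_in_seg, p = p_occ)
}

# SI for each column of an activity matrix (included frames x k).
si_from_activity <- function(act, prep) {
  sums <- rowsum(act, prep$key)
  means <- sums / prep$cnt
  f_mat <- rowsum(means, prep$binof) /
    prep$trials_per_bin[sort(unique(prep$binof))]
  p <- prep$p[sort(unique(prep$binof))]
  f <- colSums(f_mat * p)
  ratio <- sweep(f_mat, 2L, ifelse(f > 0, f, 1), "/")
  terms <- p * ratio * ifelse(ratio > 0, log2(pmax(ratio, .Machine$double.xmin)), 0)
  terms[ratio <= 0] <- 0
  si <- colSums(terms)
  si[f <= 0] <- 0
  si
}

# Null SIs from within-trial circular shifts of the activity.
si_shuffled <- function(act_vec, prep, n_shuffles, frame_rate_hz) {
  n <- length(act_vec)
  min_off <- ceiling(frame_rate_hz)
  off_tr <- matrix(0L, prep$n_trials, n_shuffles)
  for (tt in seq_len(prep$n_trials)) {
    len <- prep$lens[tt]
    lo <- min(min_off, max(1L, len - 1L))
    off_tr[tt, ] <- if (len <= 1L) 0L else
      lo - 1L + sample.int(len - lo, n_shuffles, replace = TRUE)
  }
  OFF <- off_tr[prep$tr_i, , drop = FALSE]
  IDX <- prep$seg_start + (prep$pos_in_seg + OFF) %% prep$seg_len
  ACT <- matrix(act_vec[IDX], n, n_shuffles)
  as.numeric(si_from_activity(ACT, prep))
}

#' Identify place cells by spatial information with a pooled shuffle null
#'
#' Computes SI per neuron per trial set (pre- vs post-switch; halves of the
#' session when no switch occurred) on deconvolved activity, builds the
#' circular-shuffle null per cell, pools null SIs across all cells within
#' the session, and calls a cell significant in a trial set when its true SI
#' exceeds the pooled 95th percentile. A place cell is significant in either
#' trial set. Spatial peaks come from the unsmoothed trial-averaged binned
#' dF/F (ties broken toward the lowest bin index).
#'
#' @param session an `rr_session`.
#' @param n_shuffles shuffles per cell per trial set (100).
#' @param trial_sets optional list of two integer vectors of trial ids;
#'   defaults to pre/post switch.
#' @param speed_min speed filter in cm/s (2).
#' @param seed shuffle RNG seed; defaults to a stream derived from the
#'   session seed.
#' @return data.frame (class `rr_placecells`) with per-neuron `si_pre`,
#'   `si_post`, `sig_pre`, `sig_post`, `place_cell`, `peak_pre`, `peak_post`
#'   (bin indices); pooled thresholds in attribute `thresholds`.
#' @export
find_place_cells <- function(session, n_shuffles = 100, trial_sets = NULL,
                             speed_min = 2, seed = NULL) {
  stopifnot(inherits(session, "rr_session"))
  cfg <- session$config
  if (is.null(trial_sets)) trial_sets <- default_trial_sets(session)
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "si-shuffle")
  fr <- session$frames
  n_neu <- ncol(session$events)

  # whole-session occupancy probability (speed-filtered)
  occ_all <- occupancy_matrix(fr$position_cm, fr$trial, fr$speed_cms,
                              fr$teleport, cfg$n_bins, cfg$track_length_cm,
                              speed_min)
  p_all <- occupancy_prob(occ_all, cfg$n_bins)

  res <- data.frame(neuron = seq_len(n_neu))
  thresholds <- numeric(2)
  set.seed(seed)
  for (s in 1:2) {
    in_set <- fr$trial %in% trial_sets[[s]]
    prep <- si_prepare(ifelse(in_set, fr$position_cm, NA_real_), fr$trial,
                       fr$speed_cms, fr$teleport, cfg$n_bins,
                       cfg$track_length_cm, speed_min, p_occ = p_all)
    ev <- session$events[prep$frames, , drop = FALSE]
    si_true <- si_from_activity(ev, prep)
    null_all <- matrix(0, n_shuffles, n_neu)
    for (i in seq_len(n_neu)) {
      null_all[, i] <- si_shuffled(ev[, i], prep, n_shuffles,
                                   cfg$frame_rate_hz)
    }
    thr <- stats::quantile(null_all, 0.95, names = FALSE)
    thresholds[s] <- thr
    # spatial peaks: unsmoothed trial-averaged binned dF/F
    dff_sums <- rowsum(session$dff[prep$frames, , drop = FALSE], prep$key)
    dff_means <- dff_sums / prep$cnt
    f_dff <- rowsum(dff_means, prep$binof) /
      prep$trials_per_bin[sort(unique(prep$binof))]
    full <- matrix(NA_real_, cfg$n_bins, n_neu)
    full[sort(unique(prep$binof)), ] <- f_dff
    peaks <- apply(full, 2L, function(v) which.max(v))
    lbl <- if (s == 1) "pre" else "post"
    res[[paste0("si_", lbl)]] <- as.numeric(si_true)
    res[[paste0("sig_", lbl)]] <- as.numeric(si_true) > thr
    res[[paste0("peak_", lbl)]] <- as.integer(peaks)
  }
  res$place_cell <- res$sig_pre | res$sig_post
  attr(res, "thresholds") <- thresholds
  attr(res, "trial_sets") <- trial_sets
  class(res) <- c("rr_placecells", "data.frame")
  res
}

default_trial_sets <- function(session) {
  n <- session$config$n_trials
  sw <- session$config$switch_trial
  if (!is.null(sw) && sw < n) list(pre = seq_len(sw), post = (sw + 1L):n)
  else list(pre = seq_len(n %/% 2L), post = (n %/% 2L + 1L):n)
}

#' Spatial firing peak of a tuning profile
#'
#' Argmax bin of the trial-averaged, unsmoothed binned dF/F; no restriction
#' to field boundaries, so multi-field cells get a single peak. Ties break
#' to the lowest bin index.
#'
#' @param tpm trials x bins matrix (or an already trial-averaged vector).
#' @return integer bin index.
#' @export
spatial_peak <- function(tpm) {
  v <- if (is.matrix(tpm)) colMeans(tpm, na.rm = TRUE) else as.numeric(tpm)
  if (all(is.na(v) | is.nan(v))) stop("all bins are NaN")
  which.max(v)
}

#' @exportS3Method base::print
print.rr_placecells <- function(x, ...) {
  cat("Place-cell identification:", nrow(x), "neurons;",
      sum(x$place_cell), "place cells (",
      sum(x$sig_pre), "sig pre,", sum(x$sig_post), "sig post )\n")
  invisible(x)
}
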