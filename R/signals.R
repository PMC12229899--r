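#' Compute dF/F with a per-trial maximin baseline
#'
#' Baseline fluorescence is estimated within each trial independently by a
#' maximin procedure (rolling minimum followed by rolling maximum, centered
#' 20-s windows, truncated at trial edges), which accounts for slow
#' photobleaching and keeps the teleport periods out of the baseline.
#' dF/F = (F - baseline) / |baseline|, then smoothed with a 2-sample
#' (~0.129 s at 15.5 Hz) s.d. Gaussian within each trial.
#'
#' @param fluorescence numeric per-frame trace.
#' @param trial integer per-frame trial index (partitions the series).
#' @param frame_rate_hz sampling rate.
#' @param window_s maximin window length in seconds (20).
#' @param smooth_sd_samples Gaussian smoothing s.d. in samples (2).
#' @return numeric dF/F trace; frames whose baseline is exactly 0 are NA and
#'   their count is attached as attribute `n_zero_baseline`.
#' @export
compute_dff <- function(fluorescence, trial, frame_rate_hz = 15.5,
                        window_s = 20, smooth_sd_samples = 2) {
  stopifnot(length(fluorescence) == length(trial), all(is.finite(fluorescence)))
  w <- max(1L, round(window_s * frame_rate_hz))
  out <- numeric(length(fluorescence))
  n_zero <- 0L
  for (tr in unique(trial)) {
    idx <- which(trial == tr)
    f <- fluorescence[idx]
    base <- running_extreme(running_extreme(f, w, min), w, max)
    d <- rep(NA_real_, length(f))
    nz <- base != 0
    d[nz] <- (f[nz] - base[nz]) / abs(base[nz])
    n_zero <- n_zero + sum(!nz)
    out[idx] <- smooth_gaussian(d, smooth_sd_samples, circular = FALSE)
  }
  attr(out, "n_zero_baseline") <- n_zero
  out
}

#' Bin a per-frame trace into a trials x position-bins matrix
#'
#' The 450-cm track is divided into equal half-open bins [lo, hi); position
#' at the track end wraps to bin 1. The entry for (trial, bin) is the mean
#' of included samples, which is equivalent to occupancy normalization
#' within a trial. Frames moving slower than `speed_min`, teleport frames
#' and frames without a valid position are excluded; bins a trial never
#' occupied are NaN, not zero.
#'
#' @param trace per-frame signal (dF/F or deconvolved events).
#' @param position_cm per-frame position.
#' @param trial per-frame trial index.
#' @param speed_cms per-frame running speed; NULL disables the speed filter.
#' @param teleport per-frame logical teleport flag; NULL treated as all FALSE.
#' @param n_bins number of spatial bins (45).
#' @param track_length_cm track length (450).
#' @param speed_min minimum speed in cm/s for inclusion (2).
#' @return trials x bins matrix with attributes `bin_edges` and `trials`.
#' @export
bin_by_position <- function(trace, position_cm, trial, speed_cms = NULL,
                            teleport = NULL, n_bins = 45,
                            track_length_cm = 450, speed_min = 2) {
  include <- !is.na(position_cm) & !is.na(trace)
  if (!is.null(teleport)) include <- include & !teleport
  if (!is.null(speed_cms)) include <- include & speed_cms >= speed_min
  trials <- sort(unique(trial))
  n_tr <- length(trials)
  out <- matrix(NaN, n_tr, n_bins)
  if (any(include)) {
    tr_i <- match(trial[include], trials)
    b <- floor((position_cm[include] %% track_length_cm) /
                 (track_length_cm / n_bins)) + 1L
    key <- (tr_i - 1L) * n_bins + b
    sums <- rowsum(trace[include], key)
    cnts <- rowsum(rep(1, sum(include)), key)
    k <- as.integer(rownames(sums))
    out[cbind((k - 1L) %/% n_bins + 1L, (k - 1L) %% n_bins + 1L)] <- sums / cnts
  }
  attr(out, "bin_edges") <- seq(0, track_length_cm, length.out = n_bins + 1L)
  attr(out, "trials") <- trials
  out
}

#' Per-trial occupancy counts per spatial bin
#'
#' @inheritParams bin_by_position
#' @return trials x bins matrix of included sample counts.
#' @export
occupancy_matrix <- function(position_cm, trial, speed_cms = NULL,
                             teleport = NULL, n_bins = 45,
                             track_length_cm = 450, speed_min = 2) {
  bin_by_position_counts(position_cm, trial, speed_cms, teleport,
                         n_bins, track_length_cm, speed_min)
}

bin_by_position_counts <- function(position_cm, trial, speed_cms = NULL,
                                   teleport = NULL, n_bins = 45,
                                   track_length_cm = 450, speed_min = 2) {
  include <- !is.na(position_cm)
  if (!is.null(teleport)) include <- include & !teleport
  if (!is.null(speed_cms)) include <- include & speed_cms >= speed_min
  trials <- sort(unique(trial))
  out <- matrix(0, length(trials), n_bins)
  if (any(include)) {
    tr_i <- match(trial[include], trials)
    b <- floor((position_cm[include] %% track_length_cm) /
                 (track_length_cm / n_bins)) + 1L
    key <- (tr_i - 1L) * n_bins + b
    cnts <- rowsum(rep(1, sum(include)), key)
    k <- as.integer(rownames(cnts))
    out[cbind((k - 1L) %/% n_bins + 1L, (k - 1L) %% n_bins + 1L)] <- cnts
  }
  attr(out, "trials") <- trials
  out
}

#' Trial-by-trial correlation matrix
#'
#' Each trial's spatial profile is smoothed along the position axis (20 cm
#' s.d. for single cells, 10 cm s.d. for population vectors by convention),
#' z-scored across the position (or position x neuron) axis, and correlated
#' across trials: C = A A' / (m - 1) for a single cell with m bins, or
#' / (mn - 1) for a population of n neurons with profiles concatenated.
#' Unoccupied (NaN) bins are handled pairwise-complete.
#'
#' @param A trials x bins matrix, or trials x bins x neurons array.
#' @param smooth_sd_cm Gaussian smoothing s.d. in cm; default 20 for a
#'   single cell, 10 for a population tensor.
#' @param bin_width_cm spatial bin width (10).
#' @return symmetric trials x trials correlation matrix; trials with zero
#'   variance give NA rows/columns.
#' @export
trial_correlation_matrix <- function(A, smooth_sd_cm = NULL, bin_width_cm = 10) {
  if (is.matrix(A)) {
    if (is.null(smooth_sd_cm)) smooth_sd_cm <- 20
    if (nrow(A) < 2L) stop("need at least 2 trials")
    Z <- smooth_rows(A, smooth_sd_cm / bin_width_cm, circular = TRUE)
  } else if (length(dim(A)) == 3L) {
    if (is.null(smooth_sd_cm)) smooth_sd_cm <- 10
    if (dim(A)[1] < 2L) stop("need at least 2 trials")
    sm <- apply(A, 3L, function(m)
      smooth_rows(m, smooth_sd_cm / bin_width_cm, circular = TRUE))
    Z <- matrix(sm, nrow = dim(A)[1])    # trials x (bins*neurons)
  } else stop("A must be a matrix or a 3-d array")
  suppressWarnings(stats::cor(t(Z), use = "pairwise.complete.obs"))
}

#' Flag putative interneurons by speed correlation
#'
#' Neurons whose dF/F trace has Pearson correlation > 0.5 with running speed
#' are flagged for exclusion (continuously active, speed-coupled cells).
#' Constant traces have undefined correlation and are kept but flagged.
#'
#' @param dff frames x neurons dF/F matrix (or a vector for one neuron).
#' @param speed_cms per-frame running speed.
#' @return data.frame with `neuron`, `r` (correlation), `keep` and
#'   `undefined` columns.
#' @export
exclude_putative_interneurons <- function(dff, speed_cms) {
  dff <- as.matrix(dff)
  stopifnot(nrow(dff) == length(speed_cms))
  r <- suppressWarnings(as.numeric(stats::cor(dff, speed_cms,
                                              use = "pairwise.complete.obs")))
  data.frame(neuron = seq_len(ncol(dff)), r = r,
             keep = is.na(r) | r <= 0.5, undefined = is.na(r))
}
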