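#' Population activity tensor for a session
#'
#' Spatially binned activity for every neuron: trials x bins x neurons,
#' occupancy-normalized within trials, with the standard 2 cm/s speed filter.
#'
#' @param session an `rr_session`.
#' @param signal "dff" or "events".
#' @param smooth_sd_cm optional Gaussian smoothing s.d. along the position
#'   axis, in cm (0 = unsmoothed).
#' @param speed_min speed filter in cm/s.
#' @return trials x bins x neurons array.
#' @export
population_tensor <- function(session, signal = c("dff", "events"),
                              smooth_sd_cm = 0, speed_min = 2) {
  signal <- match.arg(signal)
  cfg <- session$config
  fr <- session$frames
  sig <- if (signal == "dff") session$dff else session$events
  include <- !is.na(fr$position_cm) & !fr$teleport & fr$speed_cms >= speed_min
  trials <- sort(unique(fr$trial))
  n_tr <- length(trials)
  nb <- cfg$n_bins
  tr_i <- match(fr$trial[include], trials)
  b <- floor((fr$position_cm[include] %% cfg$track_length_cm) /
               (cfg$track_length_cm / nb)) + 1L
  key <- (tr_i - 1L) * nb + b
  sums <- rowsum(sig[include, , drop = FALSE], key)
  cnts <- as.numeric(rowsum(rep(1, length(key)), key))
  ukey <- as.integer(rownames(sums))
  A <- array(NaN, c(n_tr, nb, ncol(sig)))
  row <- (ukey - 1L) %/% nb + 1L
  col <- (ukey - 1L) %% nb + 1L
  for (j in seq_len(ncol(sig)))
    A[cbind(row, col, j)] <- sums[, j] / cnts
  if (smooth_sd_cm > 0) {
    sdb <- smooth_sd_cm / (cfg$track_length_cm / nb)
    for (j in seq_len(ncol(sig))) A[, , j] <- smooth_rows(A[, , j], sdb)
  }
  A
}

bin_phase <- function(bin, n_bins = 45, track_length_cm = 450) {
  to_periodic((bin - 0.5) * track_length_cm / n_bins, track_length_cm)
}

# rotate a bins-long profile so that entry 1 sits at the zone-start bin:
# reward-aligned profile j holds activity at (zone_bin + j - 1) mod n.
align_bins_to_zone <- function(v, zone_bin, n_bins = 45) {
  v[((seq_len(n_bins) - 1L + zone_bin - 1L) %% n_bins) + 1L]
}

#' Reward-relative remapping criteria for a single cell
#'
#' Criterion 1: the cell's spatial peaks, expressed relative to the active
#' reward-zone start in periodic coordinates, lie within ~0.698 rad (50 cm)
#' of each other before versus after the switch. Criterion 2: the circular
#' cross-correlogram of the reward-aligned, trial-averaged binned dF/F (pre
#' vs post) has a peak that exceeds the upper 97.5% of a null built by
#' circularly shifting each post-switch trial by a uniform 1-45 bins (500
#' shuffles), with the peak lag within 5 bins (~50 cm) of zero. A cell is RR
#' if it is a place cell and passes both.
#'
#' @param pre_mat,post_mat trials x bins binned dF/F for the two trial sets
#'   (track coordinates, unsmoothed).
#' @param zone_bin_pre,zone_bin_post 1-based bin index of the zone start in
#'   each set.
#' @param peak_pre,peak_post spatial peak bins (track coordinates).
#' @param n_shuffles cross-correlogram shuffles (500).
#' @param max_lag_bins maximum acceptable |peak lag| (5).
#' @return list: `is_rr_candidate` (criterion 1), `xcorr_pass`, `is_rr`,
#'   `rel_peak_diff` (rad), `xcorr_peak`, `xcorr_lag`, `xcorr_null_975`.
#' @export
rr_cell_criteria <- function(pre_mat, post_mat, zone_bin_pre, zone_bin_post,
                             peak_pre, peak_post, n_shuffles = 500,
                             max_lag_bins = 5) {
  nb <- ncol(pre_mat)
  rel_pre <- wrap_pi(bin_phase(peak_pre, nb) - bin_phase(zone_bin_pre, nb))
  rel_post <- wrap_pi(bin_phase(peak_post, nb) - bin_phase(zone_bin_post, nb))
  diff <- wrap_pi(rel_post - rel_pre)
  crit1 <- abs(diff) <= 0.698132

  pre_curve <- align_bins_to_zone(colMeans(pre_mat, na.rm = TRUE),
                                  zone_bin_pre, nb)
  P <- t(apply(post_mat, 1L, align_bins_to_zone, zone_bin = zone_bin_post,
               n_bins = nb))
  post_curve <- colMeans(P, na.rm = TRUE)

  lags <- seq_len(nb) - 1L - (nb %/% 2L)          # -22 .. 22 for nb = 45
  shift_mat <- sapply(lags, function(l)
    post_curve[((seq_len(nb) - 1L - l) %% nb) + 1L])
  xc <- suppressWarnings(as.numeric(
    stats::cor(shift_mat, pre_curve, use = "pairwise.complete.obs")))
  if (all(is.na(xc))) {
    return(list(is_rr_candidate = crit1, xcorr_pass = FALSE, is_rr = FALSE,
                rel_peak_diff = diff, xcorr_peak = NA_real_,
                xcorr_lag = NA_integer_, xcorr_null_975 = NA_real_))
  }
  peak_i <- which.max(xc)
  xcorr_peak <- xc[peak_i]
  xcorr_lag <- lags[peak_i]

  # null: per-trial circular shifts of the post-switch activity
  n_post <- nrow(P)
  S3 <- matrix(NA_real_, n_post * nb, nb)    # row (t, o): trial t shifted o
  for (o in seq_len(nb)) {
    S3[(seq_len(n_post) - 1L) * nb + o, ] <-
      P[, ((seq_len(nb) - 1L - o) %% nb) + 1L, drop = FALSE]
  }
  offs <- matrix(sample.int(nb, n_post * n_shuffles, replace = TRUE),
                 n_post, n_shuffles)
  null_peaks <- numeric(n_shuffles)
  base_rows <- (seq_len(n_post) - 1L) * nb
  pre_shifts <- sapply(lags, function(l)
    pre_curve[((seq_len(nb) - 1L + l) %% nb) + 1L])
  for (s in seq_len(n_shuffles)) {
    curve <- colMeans(S3[base_rows + offs[, s], , drop = FALSE], na.rm = TRUE)
    cc <- suppressWarnings(as.numeric(
      stats::cor(pre_shifts, curve, use = "pairwise.complete.obs")))
    null_peaks[s] <- if (all(is.na(cc))) -Inf else max(cc, na.rm = TRUE)
  }
  thr <- stats::quantile(null_peaks, 0.975, names = FALSE, na.rm = TRUE)
  xcorr_pass <- is.finite(xcorr_peak) && xcorr_peak > thr &&
    abs(xcorr_lag) <= max_lag_bins
  list(is_rr_candidate = crit1, xcorr_pass = xcorr_pass,
       is_rr = crit1 && xcorr_pass, rel_peak_diff = diff,
       xcorr_peak = xcorr_peak, xcorr_lag = xcorr_lag, xcorr_null_975 = thr)
}

#' Classify remapping categories across a reward switch
#'
#' Applies the remapping taxonomy to every neuron. TR: significant SI in
#' both trial sets with track peaks within 50 cm. RR: place cell (either
#' set) passing both reward-relative criteria (see [rr_cell_criteria()]).
#' remap_near_reward: significant both, peaks within 50 cm of the active
#' zone start in each set. remap_far_from_reward: significant both, not TR,
#' peak beyond 50 cm from at least one zone start. disappearing: significant
#' before only, with mean post dF/F below the 50th percentile of per-trial
#' mean pre dF/F; appearing: significant after only, with mean post dF/F
#' above the pre mean + 1 s.d. Appearing/disappearing cells that satisfy the
#' RR criteria are reassigned RR (precedence RR > remap near/far >
#' appearing/disappearing).
#'
#' @param session an `rr_session`.
#' @param pc place-cell table from [find_place_cells()].
#' @param n_shuffles_xcorr shuffles for the RR cross-correlogram null (500).
#' @param seed RNG seed for the shuffles.
#' @return data.frame (class `rr_remapping`) with per-neuron `category` and
#'   the supporting statistics.
#' @export
classify_remapping <- function(session, pc, n_shuffles_xcorr = 500,
                               seed = NULL) {
  stopifnot(inherits(session, "rr_session"))
  cfg <- session$config
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "rr-xcorr")
  sets <- attr(pc, "trial_sets")
  if (is.null(sets)) sets <- default_trial_sets(session)
  nb <- cfg$n_bins
  bw <- cfg$track_length_cm / nb
  zs_pre <- session$trials$zone_start_cm[sets[[1]][1]]
  zs_post <- session$trials$zone_start_cm[sets[[2]][length(sets[[2]])]]
  zone_bin_pre <- floor(zs_pre / bw) + 1L
  zone_bin_post <- floor(zs_post / bw) + 1L

  A <- population_tensor(session, "dff", smooth_sd_cm = 0)
  trials <- sort(unique(session$frames$trial))
  pre_rows <- match(sets[[1]], trials)
  post_rows <- match(sets[[2]], trials)

  n_neu <- nrow(pc)
  out <- data.frame(neuron = pc$neuron, category = "unclassified",
                    rel_peak_diff = NA_real_, xcorr_peak = NA_real_,
                    xcorr_lag = NA_integer_, xcorr_pass = NA,
                    stringsAsFactors = FALSE)
  set.seed(seed)
  peak_cm <- function(bin) (bin - 0.5) * bw
  for (i in seq_len(n_neu)) {
    if (!pc$place_cell[i]) { out$category[i] <- "nonplace"; next }
    pre_mat <- A[pre_rows, , i]
    post_mat <- A[post_rows, , i]
    pk_pre <- pc$peak_pre[i]; pk_post <- pc$peak_post[i]
    track_dist <- circ_dist_cm(peak_cm(pk_pre), peak_cm(pk_post),
                               cfg$track_length_cm)
    if (pc$sig_pre[i] && pc$sig_post[i] && track_dist <= 50) {
      out$category[i] <- "TR"
      next
    }
    rr <- rr_cell_criteria(pre_mat, post_mat, zone_bin_pre, zone_bin_post,
                           pk_pre, pk_post, n_shuffles_xcorr)
    out$rel_peak_diff[i] <- rr$rel_peak_diff
    out$xcorr_peak[i] <- rr$xcorr_peak
    out$xcorr_lag[i] <- rr$xcorr_lag
    out$xcorr_pass[i] <- rr$xcorr_pass
    if (rr$is_rr) { out$category[i] <- "RR"; next }
    if (pc$sig_pre[i] && pc$sig_post[i]) {
      near_pre <- circ_dist_cm(peak_cm(pk_pre), zs_pre, cfg$track_length_cm) <= 50
      near_post <- circ_dist_cm(peak_cm(pk_post), zs_post, cfg$track_length_cm) <= 50
      out$category[i] <- if (near_pre && near_post) "remap_near_reward"
                         else "remap_far_from_reward"
    } else if (pc$sig_pre[i]) {
      pre_trial_means <- rowMeans(pre_mat, na.rm = TRUE)
      post_mean <- mean(post_mat, na.rm = TRUE)
      out$category[i] <- if (post_mean <
                             stats::quantile(pre_trial_means, 0.5, na.rm = TRUE))
        "disappearing" else "unclassified"
    } else {
      pre_trial_means <- rowMeans(pre_mat, na.rm = TRUE)
      post_mean <- mean(post_mat, na.rm = TRUE)
      out$category[i] <- if (post_mean > mean(pre_trial_means, na.rm = TRUE) +
                             stats::sd(pre_trial_means, na.rm = TRUE))
        "appearing" else "unclassified"
    }
  }
  attr(out, "zone_bins") <- c(pre = zone_bin_pre, post = zone_bin_post)
  class(out) <- c("rr_remapping", "data.frame")
  out
}

#' @exportS3Method base::print
print.rr_remapping <- function(x, ...) {
  tab <- table(x$category)
  cat("Remapping classification (", nrow(x), " neurons ):\n")
  for (nm in names(tab)) cat(sprintf("  %-22s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Population-level test of reward-relative remapping against chance
#'
#' Restricted to cells with significant SI in both trial sets, with putative
#' TR cells (track peaks within ~0.698 rad) removed and optionally cells
#' whose peaks fall within an exclusion radius of the zone starts. The
#' statistic is the wrapped difference of reward-relative peaks (after minus
#' before). The null keeps each cell's pre-switch peak and circularly
#' permutes its post-switch binned activity by a uniform 0-44 bins (which
#' shifts the post peak by the same offset), 1000 times. Reports the
#' observed histogram (2 pi / 45 bins), the per-bin 95th-percentile shuffle
#' band, and the above-chance fraction: (observed count within |diff| <=
#' 0.698 rad minus the mean shuffle count in that window) / number of place
#' cells, significant when the observed count exceeds the 95th percentile of
#' the shuffle window counts.
#'
#' @param session an `rr_session`.
#' @param pc place-cell table from [find_place_cells()].
#' @param n_shuffles permutations (1000).
#' @param exclusion_radius_cm exclude cells with peaks within this distance
#'   of both zone starts (0 = keep all).
#' @param seed RNG seed.
#' @return list of class `rr_poptest`: `diffs`, `hist_obs`, `band_95`,
#'   `above_chance_fraction`, `significant`, `n_eligible`, `n_place`,
#'   `low_n`.
#' @export
rr_population_test <- function(session, pc, n_shuffles = 1000,
                               exclusion_radius_cm = 0, seed = NULL) {
  cfg <- session$config
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "rr-poptest")
  sets <- attr(pc, "trial_sets")
  if (is.null(sets)) sets <- default_trial_sets(session)
  nb <- cfg$n_bins
  bw <- cfg$track_length_cm / nb
  zs_pre <- session$trials$zone_start_cm[sets[[1]][1]]
  zs_post <- session$trials$zone_start_cm[sets[[2]][length(sets[[2]])]]

  elig <- pc$sig_pre & pc$sig_post
  peak_cm_pre <- (pc$peak_pre - 0.5) * bw
  peak_cm_post <- (pc$peak_post - 0.5) * bw
  track_dist <- circ_dist_cm(peak_cm_pre, peak_cm_post, cfg$track_length_cm)
  elig <- elig & track_dist > 50           # remove putative TR cells
  if (exclusion_radius_cm > 0) {
    near_pre <- circ_dist_cm(peak_cm_pre, zs_pre, cfg$track_length_cm) <=
      exclusion_radius_cm
    near_post <- circ_dist_cm(peak_cm_post, zs_post, cfg$track_length_cm) <=
      exclusion_radius_cm
    elig <- elig & !(near_pre & near_post)
  }
  idx <- which(elig)
  n_elig <- length(idx)
  n_place <- sum(pc$place_cell)

  rel_pre <- wrap_pi(to_periodic(peak_cm_pre[idx], cfg$track_length_cm) -
                       to_periodic(zs_pre, cfg$track_length_cm))
  rel_post <- wrap_pi(to_periodic(peak_cm_post[idx], cfg$track_length_cm) -
                        to_periodic(zs_post, cfg$track_length_cm))
  diffs <- wrap_pi(rel_post - rel_pre)

  breaks <- seq(-pi, pi, length.out = nb + 1L)
  hist_obs <- graphics::hist(diffs, breaks = breaks, plot = FALSE)$counts
  window <- abs(diffs) <= 0.698132
  obs_count <- sum(window)

  set.seed(seed)
  dphi <- 2 * pi / nb
  null_counts <- matrix(0L, n_shuffles, nb)
  null_window <- integer(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    o <- sample.int(nb, n_elig, replace = TRUE) - 1L
    nd <- wrap_pi(diffs + o * dphi)
    null_counts[s, ] <- graphics::hist(nd, breaks = breaks, plot = FALSE)$counts
    null_window[s] <- sum(abs(nd) <= 0.698132)
  }
  band <- apply(null_counts, 2L, stats::quantile, probs = 0.95, names = FALSE)
  frac <- (obs_count - mean(null_window)) / max(n_place, 1L)
  out <- list(diffs = diffs, hist_obs = hist_obs, band_95 = band,
              above_chance_fraction = frac,
              significant = obs_count > stats::quantile(null_window, 0.95,
                                                        names = FALSE),
              n_eligible = n_elig, n_place = n_place, low_n = n_elig < 10L)
  class(out) <- "rr_poptest"
  out
}

#' @exportS3Method base::print
print.rr_poptest <- function(x, ...) {
  cat("RR population test:", x$n_eligible, "eligible cells of",
      x$n_place, "place cells\n")
  cat(sprintf("  above-chance fraction %.3f (%ssignificant)%s\n",
              x$above_chance_fraction, if (x$significant) "" else "not ",
              if (x$low_n) " [low n]" else ""))
  invisible(x)
}

#' Teleport-distance control for reward-relative cells
#'
#' For each cell, the trial-wise spatial peak error (circular distance, in
#' cm, between the single-trial peak and the trial-set mean peak) is
#' Spearman-correlated with the distance run in the teleport period that
#' preceded the trial. A cell anchored to distance run since the last reward
#' shows a positive correlation; a cell anchored to the reward zone does
#' not.
#'
#' @param session an `rr_session`.
#' @param neurons neuron indices to test.
#' @param trial_set integer vector of trials (a pre- or post-switch set).
#' @return data.frame with `neuron`, `rho`, `p`.
#' @export
teleport_distance_control <- function(session, neurons, trial_set) {
  cfg <- session$config
  A <- population_tensor(session, "dff", smooth_sd_cm = 0)
  trials <- sort(unique(session$frames$trial))
  rows <- match(trial_set, trials)
  bw <- cfg$track_length_cm / cfg$n_bins
  res <- lapply(neurons, function(i) {
    M <- A[rows, , i, drop = TRUE]
    pk <- apply(M, 1L, function(v)
      if (all(is.na(v))) NA_integer_ else which.max(v))
    mean_pk <- spatial_peak(M)
    err <- circ_dist_cm((pk - 0.5) * bw, (mean_pk - 0.5) * bw,
                        cfg$track_length_cm)
    # teleport distance at the END of the previous trial
    prev <- trial_set - 1L
    telep <- ifelse(prev >= 1L, session$trials$teleport_dist_cm[pmax(prev, 1L)],
                    NA_real_)
    ok <- !is.na(err) & !is.na(telep)
    if (sum(ok) < 3L || stats::sd(err[ok]) == 0 || stats::sd(telep[ok]) == 0)
      return(data.frame(neuron = i, rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(telep[ok], err[ok],
                                           method = "spearman"))
    data.frame(neuron = i, rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}
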