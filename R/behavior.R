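#' Flag trials with erroneous lick detection
#'
#' A damaged lick circuit produces sustained counts; trials in which more
#' than 30% of frames carry a cumulative lick count greater than 2 (a
#' sustained rate of 20 Hz or more at ~15.5 Hz sampling) are removed from
#' licking analyses.
#'
#' @param lick_count per-frame integer lick counts.
#' @param trial per-frame trial index.
#' @return logical vector per trial (TRUE = keep), named by trial id.
#' @export
remove_erroneous_lick_trials <- function(lick_count, trial) {
  frac <- tapply(lick_count > 2, trial, mean)
  keep <- stats::setNames(as.vector(frac <= 0.30), names(frac))
  keep[order(as.numeric(names(keep)))]
}

#' Spatially binned lick rate per trial
#'
#' Lick counts are binarized, binned at the neural resolution (10 cm) and
#' divided by the time occupancy of each bin, giving licks/s. Trials failing
#' the erroneous-lick filter are NaN rows.
#'
#' @param lick per-frame binary licks (or counts; binarized internally).
#' @param position_cm,trial per-frame position and trial index.
#' @param teleport optional per-frame teleport flag.
#' @param frame_rate_hz sampling rate (15.5).
#' @param n_bins,track_length_cm spatial binning (45 bins over 450 cm).
#' @param drop_erroneous apply [remove_erroneous_lick_trials()] on the raw
#'   counts first (TRUE).
#' @return trials x bins matrix of lick rates (licks/s); zero-occupancy bins
#'   are NaN.
#' @export
lick_rate_map <- function(lick, position_cm, trial, teleport = NULL,
                          frame_rate_hz = 15.5, n_bins = 45,
                          track_length_cm = 450, drop_erroneous = TRUE) {
  lick_bin <- as.numeric(lick > 0)
  counts <- bin_by_position_counts(position_cm, trial, NULL, teleport,
                                   n_bins, track_length_cm)
  # mean licks per sample * samples per second = licks per second
  m <- bin_by_position(lick_bin, position_cm, trial, NULL, teleport,
                       n_bins, track_length_cm)
  rate <- m * frame_rate_hz
  rate[counts == 0] <- NaN
  if (drop_erroneous) {
    keep <- remove_erroneous_lick_trials(lick, trial)
    rate[!keep, ] <- NaN
  }
  attr(rate, "trials") <- sort(unique(trial))
  rate
}

#' Anticipatory lick ratio
#'
#' (Lick_in - Lick_out) / (Lick_in + Lick_out), where Lick_in is the mean
#' lick rate in the 50-cm anticipatory window just before the reward-zone
#' start and Lick_out is the mean rate outside that window and outside the
#' reward zone itself (consummatory licks in the zone are excluded
#' entirely). 1 means licking only in the anticipatory window, -1 only
#' elsewhere, 0 spatially indiscriminate licking.
#'
#' @param lickmap trials x bins lick-rate matrix from [lick_rate_map()].
#' @param zone_start_cm reward-zone start per trial (recycled if scalar).
#' @param zone_length_cm reward-zone length (50).
#' @param anticip_cm anticipatory window length before the zone (50).
#' @param block_size trials per block for the time course (10); blocks never
#'   straddle `switch_trial`, and a final partial block is kept if it has at
#'   least 5 trials.
#' @param switch_trial optional last trial of the pre-switch set.
#' @param track_length_cm track length (450).
#' @return data.frame with `block`, `first_trial`, `last_trial`, `ratio`.
#' @export
anticipatory_lick_ratio <- function(lickmap, zone_start_cm,
                                    zone_length_cm = 50, anticip_cm = 50,
                                    block_size = 10, switch_trial = NULL,
                                    track_length_cm = 450) {
  n_tr <- nrow(lickmap)
  n_bins <- ncol(lickmap)
  zone_start_cm <- rep_len(zone_start_cm, n_tr)
  bw <- track_length_cm / n_bins
  centers <- (seq_len(n_bins) - 0.5) * bw

  trial_ratio_parts <- function(rows) {
    lin <- numeric(0); lout <- numeric(0)
    for (t in rows) {
      zs <- zone_start_cm[t]
      d <- (centers - zs) %% track_length_cm        # cm past zone start
      in_zone <- d < zone_length_cm
      in_ant <- !in_zone & ((zs - centers) %% track_length_cm) <= anticip_cm &
        ((zs - centers) %% track_length_cm) > 0
      lin <- c(lin, lickmap[t, in_ant])
      lout <- c(lout, lickmap[t, !in_ant & !in_zone])
    }
    c(mean(lin, na.rm = TRUE), mean(lout, na.rm = TRUE))
  }

  seg_bounds <- if (is.null(switch_trial) || switch_trial >= n_tr)
    list(seq_len(n_tr)) else
      list(seq_len(switch_trial), (switch_trial + 1L):n_tr)
  blocks <- list()
  for (seg in seg_bounds) {
    starts <- seq(seg[1], seg[length(seg)], by = block_size)
    for (s in starts) {
      e <- min(s + block_size - 1L, seg[length(seg)])
      if (e - s + 1L >= 5L || e - s + 1L == block_size)
        blocks[[length(blocks) + 1L]] <- s:e
    }
  }
  res <- lapply(seq_along(blocks), function(i) {
    p <- trial_ratio_parts(blocks[[i]])
    denom <- p[1] + p[2]
    data.frame(block = i, first_trial = blocks[[i]][1],
               last_trial = blocks[[i]][length(blocks[[i]])],
               ratio = if (is.na(denom) || denom == 0) NA_real_
                       else (p[1] - p[2]) / denom)
  })
  do.call(rbind, res)
}

#' Spatially binned mean running speed per trial
#'
#' @param speed_cms,position_cm,trial per-frame series.
#' @param teleport optional per-frame teleport flag.
#' @param bin_width_cm spatial bin width (2 cm for fine speed profiles; use
#'   10 to match the neural binning).
#' @param track_length_cm track length.
#' @return trials x bins matrix of mean speed; unoccupied bins NaN.
#' @export
speed_map <- function(speed_cms, position_cm, trial, teleport = NULL,
                      bin_width_cm = 2, track_length_cm = 450) {
  n_bins <- round(track_length_cm / bin_width_cm)
  bin_by_position(speed_cms, position_cm, trial, NULL, teleport,
                  n_bins, track_length_cm)
}
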