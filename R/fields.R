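#' Detect individual place fields
#'
#' Candidate fields are contiguous regions of at least 20 cm in which the
#' trial-averaged, 10-cm-s.d.-smoothed deconvolved activity exceeds 20% of
#' its maximum. A field is kept only if the cell is significantly active
#' within the field bounds on at least `min_active_trials` (8 of 30) trials,
#' where significantly active means the trial's in-field activity exceeds
#' the mean + 1 s.d. of the pooled in-field samples across the trial set
#' (silent traversals fall below it). Fields overlapping the
#' first or last bin are flagged (`edge_overlap`) for exclusion from width
#' and rate analyses. Width is the distance between the first and last bin
#' crossing the threshold.
#'
#' @param tpm trials x bins matrix of unsmoothed binned deconvolved events
#'   for one trial set (typically 30 trials).
#' @param bin_width_cm spatial bin width (10).
#' @param smooth_sd_cm smoothing of the trial-averaged profile (10).
#' @param threshold_frac fraction of maximum defining field bounds (0.2).
#' @param min_width_cm minimum field width (20).
#' @param min_active_trials minimum significantly active trials (8).
#' @return data.frame (possibly 0-row) with `start_bin`, `end_bin`,
#'   `width_cm`, `in_field_rate`, `n_active_trials`, `edge_overlap`.
#' @export
detect_fields <- function(tpm, bin_width_cm = 10, smooth_sd_cm = 10,
                          threshold_frac = 0.2, min_width_cm = 20,
                          min_active_trials = 8) {
  avg <- colMeans(tpm, na.rm = TRUE)
  avg[is.nan(avg)] <- 0
  sm <- smooth_gaussian(avg, smooth_sd_cm / bin_width_cm, circular = TRUE)
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0),
                      width_cm = numeric(0), in_field_rate = numeric(0),
                      n_active_trials = integer(0), edge_overlap = logical(0))
  if (all(sm <= 0)) return(empty)
  thr <- threshold_frac * max(sm)
  above <- sm > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- empty
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    if ((e - s) * bin_width_cm < min_width_cm) next
    # significantly active trial: raw in-field activity exceeds the mean +
    # 1 s.d. of the pooled in-field samples across the trial set
    infield <- tpm[, s:e, drop = FALSE]
    pool <- infield[is.finite(infield)]
    act_thr <- mean(pool) + stats::sd(pool)
    v <- apply(infield, 1L, function(x)
      if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
    n_active <- sum(v > act_thr)
    if (n_active < min_active_trials) next
    out <- rbind(out, data.frame(
      start_bin = s, end_bin = e, width_cm = (e - s) * bin_width_cm,
      in_field_rate = mean(tpm[, s:e], na.rm = TRUE),
      n_active_trials = n_active,
      edge_overlap = s == 1L || e == ncol(tpm)))
  }
  out
}

#' Formation lap of a place field
#'
#' Within the field bounds extended by 10 cm on each side, a trial is
#' active when its binned activity exceeds the mean + 1 s.d. of the pooled
#' in-window samples across the trial set. The formation lap is the first
#' active trial inside the first
#' five-trial window containing at least three active trials; NA if no such
#' window exists.
#'
#' @param tpm trials x bins binned activity for the post-switch set.
#' @param start_bin,end_bin field bounds (bins).
#' @param pad_bins bounds extension (1 bin = 10 cm).
#' @return 1-based trial index within the set, or NA.
#' @export
formation_lap <- function(tpm, start_bin, end_bin, pad_bins = 1L) {
  nb <- ncol(tpm)
  s <- max(1L, start_bin - pad_bins)
  e <- min(nb, end_bin + pad_bins)
  inwin <- tpm[, s:e, drop = FALSE]
  pool <- inwin[is.finite(inwin)]
  thr <- mean(pool) + stats::sd(pool)
  v <- apply(inwin, 1L, function(x)
    if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
  active <- v > thr
  n <- length(active)
  if (n < 5L) return(NA_integer_)
  for (w in seq_len(n - 4L)) {
    win <- active[w:(w + 4L)]
    if (sum(win) >= 3L) return(w + which(win)[1] - 1L)
  }
  NA_integer_
}

#' Center-of-mass shift of a field from formation to late session
#'
#' The field center of mass is computed at full resolution from raw
#' (un-binned) activity-weighted positions within the field bounds. The
#' shift is COM(mean of the last 30 trials) - COM(formation lap); negative
#' values are backward shifts (toward earlier track positions).
#'
#' @param activity per-frame deconvolved activity.
#' @param position_cm,trial per-frame position and trial index.
#' @param bounds_cm numeric length-2 field bounds in cm.
#' @param formation_trial trial id of the formation lap.
#' @param last_trials trial ids of the final trials (typically last 30).
#' @return shift in cm (NA if either COM is undefined).
#' @export
field_shift <- function(activity, position_cm, trial, bounds_cm,
                        formation_trial, last_trials) {
  com <- function(tr_ids) {
    sel <- trial %in% tr_ids & !is.na(position_cm) &
      position_cm >= bounds_cm[1] & position_cm <= bounds_cm[2]
    w <- activity[sel]
    if (sum(w) <= 0) return(NA_real_)
    sum(w * position_cm[sel]) / sum(w)
  }
  com(last_trials) - com(formation_trial)
}

#' Coordination of remapping between the two fields of two-field cells
#'
#' For cells with exactly two fields before and after the switch, the
#' between-field offset (circular difference between the two field centers)
#' is compared before vs after with the circular-circular correlation:
#' rigidly translating both fields preserves the offset (rho near 1), while
#' independent per-field remapping destroys it (rho near 0).
#'
#' @param offsets_before,offsets_after between-field offsets in radians,
#'   one per qualifying cell.
#' @param min_cells minimum number of cells (5).
#' @return list: `rho`, `n_cells`, `low_n`.
#' @export
two_field_coordination <- function(offsets_before, offsets_after,
                                   min_cells = 5) {
  n <- sum(!is.na(offsets_before) & !is.na(offsets_after))
  low_n <- n < min_cells
  rho <- if (low_n) NA_real_ else circ_circ_corr(offsets_before, offsets_after)
  list(rho = rho, n_cells = n, low_n = low_n)
}
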