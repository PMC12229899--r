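#' Simulation configuration for a reward-switch session
#'
#' Describes a virtual-reality hidden-reward-zone session: a 450-cm circular
#' track with three possible 50-cm reward zones (starts at 80, 200, 320 cm),
#' one active zone per trial, a zone switch after 30 trials, and ~15% random
#' reward omissions. The simulated population mixes ground-truth tuning
#' classes: track-relative (TR) cells anchored to track position,
#' reward-relative (RR) cells anchored to a phase relative to the zone start
#' (with an over-representation of anchors just after the reward), appearing
#' and disappearing cells, randomly remapping cells, untuned cells and
#' optionally speed-coupled cells (putative interneurons).
#'
#' @param track_length_cm track length (450).
#' @param n_bins number of 10-cm spatial bins (45).
#' @param zone_starts_cm named vector of possible reward-zone starts.
#' @param zone_length_cm reward-zone length (50).
#' @param n_trials trials in the session (80).
#' @param switch_trial last trial of the pre-switch set (30).
#' @param zone_sequence two zone ids, active before and after the switch.
#' @param omission_prob probability a trial's reward is withheld (0.15).
#' @param frame_rate_hz imaging/behavior sampling rate (15.5).
#' @param population named list of per-class neuron counts; classes are
#'   `TR`, `RR`, `appearing`, `disappearing`, `random_remap`, `untuned`,
#'   `speed_coupled`.
#' @param field_sd_cm Gaussian field s.d. in cm (12).
#' @param amplitude_hz peak in-field event rate in events/s (3).
#' @param baseline_hz out-of-field event rate (0.05).
#' @param untuned_hz event rate of untuned cells (0.4).
#' @param jitter_sd_cm per-trial field-center jitter s.d. (10).
#' @param gain_sd per-trial log-normal gain s.d. (0.25).
#' @param rr_post_bias fraction of RR anchors drawn from a wrapped-normal
#'   bump centered 0.35 rad (~25 cm) after the zone start (0.5); the rest
#'   are uniform on the circle.
#' @param lick_lag_trials behavioral adaptation lag: for this many trials
#'   after the switch, anticipatory licking and slowing still target the old
#'   zone (the animal searches the previous reward location) while reward
#'   delivery follows the new zone immediately (2).
#' @param tau_s calcium-kernel decay time constant in seconds (0.7).
#' @param dff_noise_sd Gaussian noise s.d. added to the simulated dF/F.
#' @param seed integer RNG seed; behavior uses one stream, each neuron a
#'   derived sub-stream, so adding neurons does not perturb behavior.
#' @return an object of class `rr_sim_config`.
#' @export
sim_config <- function(track_length_cm = 450, n_bins = 45,
                       zone_starts_cm = c(A = 80, B = 200, C = 320),
                       zone_length_cm = 50,
                       n_trials = 80, switch_trial = 30,
                       zone_sequence = c("A", "B"),
                       omission_prob = 0.15, frame_rate_hz = 15.5,
                       population = c(TR = 110, RR = 110, appearing = 30,
                                      disappearing = 30, random_remap = 40,
                                      untuned = 80, speed_coupled = 0),
                       field_sd_cm = 12, amplitude_hz = 3, baseline_hz = 0.05,
                       untuned_hz = 0.4, jitter_sd_cm = 10, gain_sd = 0.25,
                       rr_post_bias = 0.5, lick_lag_trials = 2,
                       tau_s = 0.7, dff_noise_sd = 0.05,
                       seed = 1L) {
  known <- c("TR", "RR", "appearing", "disappearing", "random_remap",
             "untuned", "speed_coupled")
  bad <- setdiff(names(population), known)
  if (length(bad) > 0L)
    stop("unknown tuning class in population spec: ", paste(bad, collapse = ", "))
  if (any(zone_starts_cm + zone_length_cm > track_length_cm))
    stop("reward zone extends past the track end")
  if (omission_prob < 0 || omission_prob >= 1)
    stop("omission_prob must be in [0, 1)")
  if (switch_trial >= n_trials)
    stop("switch_trial must be smaller than n_trials")
  if (!all(zone_sequence %in% names(zone_starts_cm)))
    stop("zone_sequence entries must name zones in zone_starts_cm")
  cfg <- list(track_length_cm = track_length_cm, n_bins = n_bins,
              zone_starts_cm = zone_starts_cm, zone_length_cm = zone_length_cm,
              n_trials = n_trials, switch_trial = switch_trial,
              zone_sequence = zone_sequence, omission_prob = omission_prob,
              frame_rate_hz = frame_rate_hz, population = population,
              field_sd_cm = field_sd_cm, amplitude_hz = amplitude_hz,
              baseline_hz = baseline_hz, untuned_hz = untuned_hz,
              jitter_sd_cm = jitter_sd_cm, gain_sd = gain_sd,
              rr_post_bias = rr_post_bias,
              lick_lag_trials = lick_lag_trials, tau_s = tau_s,
              dff_noise_sd = dff_noise_sd, seed = as.integer(seed))
  class(cfg) <- "rr_sim_config"
  cfg
}

#' Simulate a reward-switch session with ground truth
#'
#' Generates behavior (position, speed, licks, teleport periods, reward
#' deliveries and omissions) and per-neuron activity. Behavior shows an
#' anticipatory lick ramp over the 50 cm before the active zone and slowing
#' around it; licking and slowing move with the zone after the switch.
#' Deconvolved event rates are Poisson given each cell's tuning; dF/F is the
#' event train convolved with an exponential calcium kernel plus Gaussian
#' noise.
#'
#' @param config an `rr_sim_config`.
#' @return a list of class `rr_session` with elements `frames` (data.frame:
#'   time_s, trial, position_cm, speed_cms, lick, teleport), `trials`
#'   (data.frame: trial, zone, zone_start_cm, rewarded, omission,
#'   reward_pos_cm, teleport_dist_cm), `events` and `dff` (frames x neurons
#'   matrices), `ground_truth` (data.frame: neuron, class, anchor_cm,
#'   anchor_phase, field_sd_cm, amplitude_hz) and `config`.
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "rr_sim_config"))
  cfg <- config
  fs <- cfg$frame_rate_hz
  L <- cfg$track_length_cm

  ## ---- behavior stream ----
  set.seed(cfg$seed)
  n_tr <- cfg$n_trials
  zone_id <- ifelse(seq_len(n_tr) <= cfg$switch_trial,
                    cfg$zone_sequence[1], cfg$zone_sequence[2])
  zone_start <- cfg$zone_starts_cm[zone_id]
  # behavior (licking/slowing) tracks the zone with a short adaptation lag
  behav_zone_start <- cfg$zone_starts_cm[
    zone_id[pmax(seq_len(n_tr) - cfg$lick_lag_trials, 1L)]]
  omission <- stats::runif(n_tr) < cfg$omission_prob
  rewarded <- !omission
  reward_pos <- ifelse(rewarded, zone_start + stats::runif(n_tr, 2, 12), NA_real_)
  base_speed <- stats::runif(n_tr, 42, 55)

  frames <- vector("list", n_tr)
  teleport_dist <- numeric(n_tr)
  for (t in seq_len(n_tr)) {
    zs <- zone_start[t]            # true zone: reward delivery
    bzs <- behav_zone_start[t]     # behavioral target: licking and slowing
    pos <- numeric(0); spd <- numeric(0)
    p <- 0; e <- 0
    repeat {
      slow <- 1 - 0.7 * exp(-0.5 * ((p - (bzs + 10)) / 30)^2)
      e <- 0.8 * e + stats::rnorm(1, 0, 2)
      v <- max(3, base_speed[t] * slow + e)
      pos <- c(pos, p); spd <- c(spd, v)
      p <- p + v / fs
      if (p >= L) break
    }
    nf <- length(pos)
    # licking: low baseline, anticipatory ramp over the 50 cm before the
    # zone, consummatory burst after delivery (search licking on omissions)
    rate <- rep(0.2, nf)
    ant <- pos >= (bzs - 50) & pos < bzs
    rate[ant] <- 0.2 + 8 * (pos[ant] - (bzs - 50)) / 50
    inzone <- pos >= bzs & pos < (bzs + cfg$zone_length_cm)
    rate[inzone] <- 8
    if (rewarded[t]) {
      cons <- pos >= reward_pos[t] & pos < (reward_pos[t] + 30)
      rate[cons] <- 10
      rate[pos >= (reward_pos[t] + 30)] <- 0.3
    } else {
      rate[pos >= (zs + cfg$zone_length_cm)] <- 0.8
    }
    lick <- stats::rbinom(nf, 1L, pmin(rate / fs, 1))
    # teleport period: gray corridor, position invalid; longer after omissions
    tel_s <- if (omission[t]) stats::runif(1, 5, 10) else stats::runif(1, 1, 5)
    n_tel <- max(1L, round(tel_s * fs))
    tel_spd <- pmax(3, base_speed[t] * stats::runif(1, 0.5, 0.9) +
                      stats::rnorm(n_tel, 0, 2))
    teleport_dist[t] <- sum(tel_spd) / fs
    frames[[t]] <- data.frame(
      trial = t,
      position_cm = c(pos, rep(NA_real_, n_tel)),
      speed_cms = c(spd, tel_spd),
      lick = c(lick, stats::rbinom(n_tel, 1L, pmin(0.3 / fs, 1))),
      teleport = c(rep(FALSE, nf), rep(TRUE, n_tel)))
  }
  frames <- do.call(rbind, frames)
  frames$time_s <- seq_len(nrow(frames)) / fs
  frames <- frames[, c("time_s", "trial", "position_cm", "speed_cms",
                       "lick", "teleport")]
  trials <- data.frame(trial = seq_len(n_tr), zone = zone_id,
                       zone_start_cm = as.numeric(zone_start),
                       rewarded = rewarded, omission = omission,
                       reward_pos_cm = reward_pos,
                       teleport_dist_cm = teleport_dist)

  ## ---- neurons: one derived RNG sub-stream each ----
  pop <- cfg$population[cfg$population > 0]
  classes <- rep(names(pop), times = pop)
  n_neu <- length(classes)
  nf_all <- nrow(frames)
  events <- matrix(0, nf_all, n_neu)
  dff <- matrix(0, nf_all, n_neu)
  gt <- data.frame(neuron = seq_len(n_neu), class = classes,
                   anchor_cm = NA_real_, anchor_phase = NA_real_,
                   anchor_cm_post = NA_real_,
                   field_sd_cm = cfg$field_sd_cm,
                   amplitude_hz = NA_real_, stringsAsFactors = FALSE)
  zone_phase <- to_periodic(trials$zone_start_cm, L)
  trial_of_frame <- frames$trial
  pos_f <- frames$position_cm
  valid <- !frames$teleport & !is.na(pos_f)
  decay <- exp(-1 / (cfg$tau_s * fs))

  for (i in seq_len(n_neu)) {
    set.seed(derive_seed(cfg$seed, paste0("neuron-", i)))
    cl <- classes[i]
    amp <- cfg$amplitude_hz * stats::rlnorm(1, 0, 0.2)
    gt$amplitude_hz[i] <- amp
    gains <- stats::rlnorm(n_tr, 0, cfg$gain_sd)
    jit <- stats::rnorm(n_tr, 0, cfg$jitter_sd_cm)
    center <- rep(NA_real_, n_tr)
    if (cl == "TR") {
      a <- stats::runif(1, 0, L)
      gt$anchor_cm[i] <- a
      center <- (a + jit) %% L
    } else if (cl == "RR") {
      ph <- if (stats::runif(1) < cfg$rr_post_bias)
        wrap_pi(stats::rnorm(1, 0.35, 0.5)) else stats::runif(1, -pi, pi)
      gt$anchor_phase[i] <- ph
      center <- (from_periodic(wrap_pi(ph + zone_phase), L) + jit) %% L
    } else if (cl == "appearing") {
      a <- stats::runif(1, 0, L)
      gt$anchor_cm[i] <- a
      center <- (a + jit) %% L
      gains[seq_len(cfg$switch_trial)] <- 0
    } else if (cl == "disappearing") {
      a <- stats::runif(1, 0, L)
      gt$anchor_cm[i] <- a
      center <- (a + jit) %% L
      gains[(cfg$switch_trial + 1L):n_tr] <- 0
    } else if (cl == "random_remap") {
      a1 <- stats::runif(1, 0, L); a2 <- stats::runif(1, 0, L)
      gt$anchor_cm[i] <- a1; gt$anchor_cm_post[i] <- a2
      center <- (ifelse(seq_len(n_tr) <= cfg$switch_trial, a1, a2) + jit) %% L
    }
    rate <- rep(cfg$baseline_hz, nf_all)
    if (cl == "untuned") {
      rate <- rep(cfg$untuned_hz, nf_all)
    } else if (cl == "speed_coupled") {
      rate <- 0.15 * frames$speed_cms
    } else {
      d <- circ_dist_cm(pos_f[valid], center[trial_of_frame[valid]], L)
      rate[valid] <- cfg$baseline_hz +
        amp * gains[trial_of_frame[valid]] * exp(-0.5 * (d / cfg$field_sd_cm)^2)
    }
    ev <- stats::rpois(nf_all, rate / fs)
    events[, i] <- ev
    dff[, i] <- as.numeric(stats::filter(ev * 0.6, decay, method = "recursive")) +
      stats::rnorm(nf_all, 0, cfg$dff_noise_sd)
  }

  out <- list(frames = frames, trials = trials, events = events, dff = dff,
              ground_truth = gt, config = cfg)
  class(out) <- "rr_session"
  out
}

#' @exportS3Method base::print
print.rr_session <- function(x, ...) {
  cat("Reward-switch session:", nrow(x$trials), "trials,",
      ncol(x$events), "neurons,", nrow(x$frames), "frames @",
      x$config$frame_rate_hz, "Hz\n")
  cat("  zones:", x$config$zone_sequence[1], "->", x$config$zone_sequence[2],
      "(switch after trial", paste0(x$config$switch_trial, ");"),
      sum(x$trials$omission), "omission trials\n")
  cat("  classes:", paste(names(table(x$ground_truth$class)),
                          table(x$ground_truth$class),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Expected tuning curve of a simulated neuron
#'
#' Evaluates the ground-truth tuning as expected event rate per spatial bin
#' for a given active reward zone. RR cells place a circular Gaussian bump at
#' anchor phase + zone phase; TR (and appearing/disappearing) cells at their
#' fixed track anchor; untuned cells are flat. The curve is normalized to
#' integrate (sum over bins) to the cell's amplitude.
#'
#' @param gt a ground-truth data.frame from [simulate_session()].
#' @param neuron neuron index.
#' @param zone_start_cm active reward-zone start in cm.
#' @param config the `rr_sim_config` used for the simulation.
#' @param post logical; for randomly remapping cells use the post-switch anchor.
#' @return numeric vector of length `config$n_bins`.
#' @export
tuning_curve <- function(gt, neuron, zone_start_cm, config, post = FALSE) {
  if (!neuron %in% gt$neuron) stop("no such neuron: ", neuron)
  row <- gt[gt$neuron == neuron, ]
  L <- config$track_length_cm
  centers <- (seq_len(config$n_bins) - 0.5) * L / config$n_bins
  flat <- rep(1, config$n_bins)
  cl <- row$class
  if (cl %in% c("untuned", "speed_coupled")) {
    curve <- flat
  } else {
    anchor <- if (cl == "RR") {
      from_periodic(wrap_pi(row$anchor_phase + to_periodic(zone_start_cm, L)), L)
    } else if (cl == "random_remap" && post) {
      row$anchor_cm_post
    } else {
      row$anchor_cm
    }
    d <- circ_dist_cm(centers, anchor, L)
    curve <- exp(-0.5 * (d / row$field_sd_cm)^2)
  }
  curve / sum(curve) * row$amplitude_hz
}
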