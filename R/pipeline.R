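#' Write / read a session as a plain-text container
#'
#' Serializes an `rr_session` to a directory of TSV files (`frames.tsv`,
#' `trials.tsv`, `events.tsv`, `dff.tsv`, `ground_truth.tsv`,
#' `config.tsv`), a portable text format that round-trips the session.
#'
#' @param session an `rr_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "rr_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(path, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(session$frames, "frames.tsv")
  wt(session$trials, "trials.tsv")
  wt(as.data.frame(session$events), "events.tsv")
  wt(as.data.frame(session$dff), "dff.tsv")
  wt(session$ground_truth, "ground_truth.tsv")
  cfg <- session$config
  cfg_flat <- data.frame(
    key = names(unlist(cfg)),
    value = as.character(unlist(cfg)), stringsAsFactors = FALSE)
  wt(cfg_flat, "config.tsv")
  invisible(path)
}

#' @rdname write_session
#' @param path directory written by [write_session()].
#' @export
read_session <- function(path) {
  rd <- function(f) utils::read.table(file.path(path, f), sep = "\t",
                                      header = TRUE, stringsAsFactors = FALSE)
  cfg_flat <- rd("config.tsv")
  kv <- stats::setNames(cfg_flat$value, cfg_flat$key)
  num <- function(k) as.numeric(kv[[k]])
  zs <- kv[grep("^zone_starts_cm", names(kv))]
  names(zs) <- sub("zone_starts_cm\\.", "", names(zs))
  cfg <- sim_config(
    track_length_cm = num("track_length_cm"), n_bins = num("n_bins"),
    zone_starts_cm = stats::setNames(as.numeric(zs), names(zs)),
    zone_length_cm = num("zone_length_cm"), n_trials = num("n_trials"),
    switch_trial = num("switch_trial"),
    zone_sequence = as.character(kv[grep("^zone_sequence", names(kv))]),
    omission_prob = num("omission_prob"),
    frame_rate_hz = num("frame_rate_hz"),
    population = {
      pk <- grep("^population\\.", names(kv))
      stats::setNames(as.numeric(kv[pk]),
                      sub("population\\.", "", names(kv)[pk]))
    },
    field_sd_cm = num("field_sd_cm"), amplitude_hz = num("amplitude_hz"),
    baseline_hz = num("baseline_hz"), untuned_hz = num("untuned_hz"),
    jitter_sd_cm = num("jitter_sd_cm"), gain_sd = num("gain_sd"),
    rr_post_bias = num("rr_post_bias"), tau_s = num("tau_s"),
    dff_noise_sd = num("dff_noise_sd"), seed = num("seed"))
  out <- list(frames = rd("frames.tsv"), trials = rd("trials.tsv"),
              events = as.matrix(rd("events.tsv")),
              dff = as.matrix(rd("dff.tsv")),
              ground_truth = rd("ground_truth.tsv"), config = cfg)
  dimnames(out$events) <- NULL
  dimnames(out$dff) <- NULL
  class(out) <- "rr_session"
  out
}

#' Run the analysis pipeline on a (simulated) session
#'
#' Executes the requested stages in dependency order with per-stage seeds
#' derived from one root seed (so inserting a stage does not perturb the
#' randomness of the others), and returns a manifest of stage outputs
#' stamped with the configuration hash and seed. Stages: `simulate`,
#' `behavior`, `placecells`, `remapping`, `sequences`, `decoding`,
#' `switch_timing`.
#'
#' @param config an `rr_sim_config` (used by the `simulate` stage), or an
#'   existing `rr_session` via the `session` argument.
#' @param stages character vector of stage names (default all).
#' @param session optional existing `rr_session`; skips simulation.
#' @param seed root seed; defaults to the config seed.
#' @param n_shuffles_si,n_shuffles_xcorr shuffle counts forwarded to the
#'   respective stages.
#' @return list of class `rr_manifest`: stage outputs plus `config_hash`
#'   and `seed`.
#' @export
run_pipeline <- function(config = sim_config(), stages = NULL,
                         session = NULL, seed = NULL,
                         n_shuffles_si = 100, n_shuffles_xcorr = 500) {
  all_stages <- c("simulate", "behavior", "placecells", "remapping",
                  "sequences", "decoding", "switch_timing")
  if (is.null(stages)) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) stop("unknown stage: ", paste(bad, collapse = ", "))
  if (is.null(seed)) seed <- config$seed
  man <- list(seed = seed, config_hash = object_hash(config))
  if ("simulate" %in% stages && is.null(session)) {
    session <- simulate_session(config)
    man$session <- session
  }
  if (is.null(session)) stop("stages beyond 'simulate' need a session")
  cfg <- session$config
  fr <- session$frames
  if ("behavior" %in% stages) {
    lm <- lick_rate_map(fr$lick, fr$position_cm, fr$trial, fr$teleport,
                        cfg$frame_rate_hz, cfg$n_bins, cfg$track_length_cm)
    man$behavior <- list(
      lick_map = lm,
      lick_ratio = anticipatory_lick_ratio(
        lm, session$trials$zone_start_cm, cfg$zone_length_cm,
        switch_trial = cfg$switch_trial,
        track_length_cm = cfg$track_length_cm))
  }
  pc <- NULL
  if (any(c("placecells", "remapping", "sequences", "decoding",
            "switch_timing") %in% stages)) {
    pc <- find_place_cells(session, n_shuffles = n_shuffles_si,
                           seed = derive_seed(seed, "placecells"))
    if ("placecells" %in% stages) man$placecells <- pc
  }
  rm_tab <- NULL
  if (any(c("remapping", "sequences", "decoding", "switch_timing") %in% stages)) {
    rm_tab <- classify_remapping(session, pc,
                                 n_shuffles_xcorr = n_shuffles_xcorr,
                                 seed = derive_seed(seed, "remapping"))
    if ("remapping" %in% stages) {
      man$remapping <- rm_tab
      man$rr_population <- rr_population_test(
        session, pc, seed = derive_seed(seed, "poptest"))
    }
  }
  if ("sequences" %in% stages) {
    rr_cells <- rm_tab$neuron[rm_tab$category == "RR"]
    man$sequences <- if (length(rr_cells) >= 2L)
      cross_validated_sequence(session, rr_cells,
                               seed = derive_seed(seed, "sequences"))
    else NULL
  }
  if ("decoding" %in% stages) {
    rr_cells <- rm_tab$neuron[rm_tab$category == "RR"]
    man$decoding <- if (length(rr_cells) >= 2L)
      decode_protocol(session, rr_cells, mode = "before_after",
                      seed = derive_seed(seed, "decoding"))
    else NULL
  }
  if ("switch_timing" %in% stages) {
    rr_cells <- rm_tab$neuron[rm_tab$category == "RR"]
    man$switch_timing <- if (length(rr_cells) >= 2L)
      lag_table(session, rr_cells, seed = derive_seed(seed, "switch-timing"))
    else NULL
  }
  class(man) <- "rr_manifest"
  man
}

#' @exportS3Method base::print
print.rr_manifest <- function(x, ...) {
  cat("Pipeline manifest (config", x$config_hash, ", seed", x$seed, "):\n")
  cat("  stages:", paste(setdiff(names(x), c("seed", "config_hash")),
                         collapse = ", "), "\n")
  invisible(x)
}
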