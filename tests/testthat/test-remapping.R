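# toy trials x bins matrix with a circular Gaussian bump per trial
bump_mat <- function(n_trials, center_bin, nb = 45, sd_bins = 2, amp = 1) {
  centers <- seq_len(nb)
  d <- abs(centers - center_bin)
  d <- pmin(d, nb - d)
  matrix(rep(amp * exp(-0.5 * (d / sd_bins)^2), n_trials), n_trials, nb,
         byrow = TRUE)
}

test_that("RR criteria pass reward-stable cells and fail 10-bin shifts", {
  set.seed(5)
  zb_pre <- 9; zb_post <- 21            # zones A and B
  noisy <- function(m) m + matrix(abs(rnorm(length(m), 0, 0.03)), nrow(m))
  # reward-aligned stable: bump 4 bins after each zone start
  pre <- noisy(bump_mat(30, zb_pre + 4))
  post <- noisy(bump_mat(30, zb_post + 4))
  rr <- rr_cell_criteria(pre, post, zb_pre, zb_post,
                         peak_pre = zb_pre + 4, peak_post = zb_post + 4,
                         n_shuffles = 200)
  expect_true(rr$is_rr_candidate)
  expect_true(rr$xcorr_pass)
  expect_equal(rr$xcorr_lag, 0)
  expect_equal(rr$rel_peak_diff, 0)
  # post bump 10 bins beyond the reward-relative position: lag > 5, fails
  post10 <- noisy(bump_mat(30, zb_post + 14))
  rr10 <- rr_cell_criteria(pre, post10, zb_pre, zb_post,
                           peak_pre = zb_pre + 4, peak_post = zb_post + 14,
                           n_shuffles = 200)
  expect_false(rr10$is_rr_candidate)
  expect_gt(abs(rr10$xcorr_lag), 5)
  expect_false(rr10$is_rr)
  # flat degenerate tuning fails criterion 2 without erroring
  flat <- matrix(1, 30, 45)
  rrf <- rr_cell_criteria(flat, flat, zb_pre, zb_post, 1, 1, n_shuffles = 50)
  expect_false(rrf$xcorr_pass)
})

test_that("classification recovers the simulated taxonomy", {
  s <- small_switch_session()
  pc <- cached_place_cells(s, "small-101")
  rm <- classify_remapping(s, pc, n_shuffles_xcorr = 200)
  gt <- s$ground_truth
  expect_gt(mean(rm$category[gt$class == "RR"] == "RR"), 0.85)
  expect_gt(mean(rm$category[gt$class == "TR"] == "TR"), 0.7)
  expect_lt(mean(rm$category[gt$class == "TR"] == "RR"), 0.1)
  expect_true(all(rm$category[gt$class == "untuned"] %in%
                    c("nonplace", "unclassified")))
  # a cell silent after the switch with pre significance disappears
  dis <- gt$class == "disappearing" & pc$sig_pre & !pc$sig_post
  if (any(dis))
    expect_true(all(rm$category[dis] %in%
                      c("disappearing", "unclassified", "RR")))
})

test_that("reward-proximal remappers are labeled remap_near_reward", {
  # build a session whose RR cells anchor right at the zone start
  cfg <- sim_config(population = c(RR = 10, untuned = 2), n_trials = 40,
                    switch_trial = 20, rr_post_bias = 1, jitter_sd_cm = 4,
                    seed = 77)
  s <- simulate_session(cfg)
  # force anchors near +10 cm by filtering to cells that landed close
  pc <- find_place_cells(s, n_shuffles = 40)
  rm <- classify_remapping(s, pc, n_shuffles_xcorr = 100)
  gt <- s$ground_truth
  near <- which(gt$class == "RR" & abs(gt$anchor_phase) < 0.35 & pc$place_cell)
  # reward-anchored cells are captured by RR (which takes precedence over
  # remap_near_reward), or by remap_near_reward if the correlogram fails
  expect_true(all(rm$category[near] %in% c("RR", "remap_near_reward")))
  expect_gt(mean(rm$category[near] == "RR"), 0.7)
})

test_that("population test sees a spike at zero for a pure RR population", {
  s <- small_switch_session()
  pc <- cached_place_cells(s, "small-101")
  pt <- rr_population_test(s, pc, n_shuffles = 300)
  gt <- s$ground_truth
  expect_true(pt$significant)
  expect_gt(pt$above_chance_fraction, 0.1)
  # the observed histogram is peaked near zero difference
  mid <- which(abs(seq(-pi + pi / 45, pi - pi / 45, length.out = 45)) <= 0.7)
  expect_gt(sum(pt$hist_obs[mid]), 0.6 * sum(pt$hist_obs))
})

test_that("population test fraction is invariant to zone relabeling", {
  cfg1 <- sim_config(population = c(TR = 10, RR = 10), n_trials = 40,
                     switch_trial = 20, zone_sequence = c("A", "B"),
                     seed = 15)
  s1 <- simulate_session(cfg1)
  pc1 <- find_place_cells(s1, n_shuffles = 40)
  p1 <- rr_population_test(s1, pc1, n_shuffles = 200, seed = 3)
  # same geometry, zones renamed C->A (same 120-cm shift B->C vs A->B)
  cfg2 <- sim_config(population = c(TR = 10, RR = 10), n_trials = 40,
                     switch_trial = 20, zone_sequence = c("B", "C"),
                     seed = 15)
  s2 <- simulate_session(cfg2)
  pc2 <- find_place_cells(s2, n_shuffles = 40)
  p2 <- rr_population_test(s2, pc2, n_shuffles = 200, seed = 3)
  expect_equal(p1$n_eligible > 0, p2$n_eligible > 0)
  expect_lt(abs(p1$above_chance_fraction - p2$above_chance_fraction), 0.25)
})

test_that("growing exclusion radius shrinks the eligible set to zero", {
  s <- small_switch_session()
  pc <- cached_place_cells(s, "small-101")
  radii <- c(0, 50, 100, 225)
  ns <- vapply(radii, function(r)
    rr_population_test(s, pc, n_shuffles = 20, exclusion_radius_cm = r)$n_eligible,
    numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_equal(ns[4], 0)
})

test_that("teleport control separates distance- from reward-anchored cells", {
  # construct a session, then overwrite one cell's activity so it fires a
  # fixed distance after the previous teleport (distance-anchored)
  s <- simulate_session(sim_config(population = c(RR = 2), n_trials = 40,
                                   switch_trial = 20, jitter_sd_cm = 2,
                                   seed = 19))
  fr <- s$frames
  set.seed(8)
  dist_anchor <- 120
  ev <- numeric(nrow(fr))
  for (t in seq_len(40)) {
    prev_d <- if (t == 1) 100 else s$trials$teleport_dist_cm[t - 1]
    center <- (dist_anchor - prev_d) %% 450
    sel <- fr$trial == t & !fr$teleport
    d <- circ_dist_cm(fr$position_cm[sel], center)
    ev[sel] <- rpois(sum(sel), 0.35 * exp(-0.5 * (d / 12)^2))
  }
  s$events[, 1] <- ev
  s$dff[, 1] <- as.numeric(stats::filter(ev * 0.6, exp(-1 / (0.7 * 15.5)),
                                         method = "recursive"))
  res <- teleport_distance_control(s, neurons = 1:2, trial_set = 1:20)
  expect_gt(res$rho[1], 0.3)
  expect_lt(res$p[1], 0.05)
  # the true reward-anchored cell shows no such correlation
  expect_true(is.na(res$rho[2]) || abs(res$rho[2]) < 0.4)
  # constant peak error is undefined
  s2 <- s
  s2$events[, 2] <- 0
  s2$dff[, 2] <- 0
  res2 <- teleport_distance_control(s2, neurons = 2, trial_set = 1:20)
  expect_true(is.na(res2$rho))
})
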