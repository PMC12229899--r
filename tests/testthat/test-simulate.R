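test_that("config validation rejects impossible task setups", {
  expect_error(sim_config(population = c(ghost_cells = 5)), "unknown tuning")
  expect_error(sim_config(omission_prob = 1.2), "omission_prob")
  expect_error(sim_config(switch_trial = 80, n_trials = 80), "switch_trial")
  expect_error(sim_config(zone_starts_cm = c(A = 420)), "past the track end")
})

test_that("omission_prob = 0 gives all-rewarded trials", {
  s <- simulate_session(sim_config(population = c(untuned = 1),
                                   n_trials = 12, switch_trial = 6,
                                   omission_prob = 0, seed = 5))
  expect_true(all(s$trials$rewarded))
  expect_false(any(s$trials$omission))
  # rewarded XOR omission on every trial
  expect_true(all(xor(s$trials$rewarded, s$trials$omission)))
})

test_that("simulation is bit-identical for a fixed seed", {
  cfg <- sim_config(population = c(TR = 3, RR = 3), n_trials = 10,
                    switch_trial = 5, seed = 1)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$dff, s2$dff)
  expect_identical(s1$trials, s2$trials)
})

test_that("adding neurons does not perturb behavior or earlier neurons", {
  a <- simulate_session(sim_config(population = c(TR = 3), n_trials = 8,
                                   switch_trial = 4, seed = 9))
  b <- simulate_session(sim_config(population = c(TR = 5), n_trials = 8,
                                   switch_trial = 4, seed = 9))
  expect_identical(a$frames, b$frames)
  expect_identical(a$events[, 1:3], b$events[, 1:3])
})

test_that("omission fraction matches the binomial rate", {
  # binomial oracle: phat within 3 s.e. of p over many trials
  s <- simulate_session(sim_config(population = c(untuned = 1),
                                   n_trials = 2000, switch_trial = 1000,
                                   omission_prob = 0.15, seed = 21))
  p <- 0.15
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(mean(s$trials$omission) - p), 3 * se)
})

test_that("session invariants hold: position range, zone per trial", {
  s <- small_switch_session()
  pos <- s$frames$position_cm[!s$frames$teleport]
  expect_true(all(pos >= 0 & pos < 450))
  expect_true(all(is.na(s$frames$position_cm[s$frames$teleport])))
  expect_equal(unique(s$trials$zone_start_cm[1:30]), 80)
  expect_equal(unique(s$trials$zone_start_cm[31:60]), 200)
  expect_true(all(s$events >= 0))
})

test_that("simulated lick rate peaks in the anticipatory-plus-zone span", {
  s <- small_switch_session()
  fr <- s$frames
  pre <- !fr$teleport & fr$trial <= 30
  h <- hist(fr$position_cm[pre & fr$lick == 1],
            breaks = seq(0, 450, 10), plot = FALSE)$counts
  # zone A: anticipatory window 30-80 cm, zone 80-130 cm -> bins 4..13
  expect_true(which.max(h) %in% 4:13)
  expect_gt(sum(h[4:13]), 0.6 * sum(h))
})

test_that("tuning curves follow their class geometry", {
  s <- small_switch_session()
  gt <- s$ground_truth
  cfg <- s$config
  rr_n <- gt$neuron[gt$class == "RR"][1]
  tr_n <- gt$neuron[gt$class == "TR"][1]
  un_n <- gt$neuron[gt$class == "untuned"][1]
  # TR: identical curves whatever the zone
  expect_equal(tuning_curve(gt, tr_n, 80, cfg), tuning_curve(gt, tr_n, 320, cfg))
  # RR: argmax moves by exactly the zone shift (zones are bin-aligned)
  cA <- tuning_curve(gt, rr_n, 80, cfg)
  cC <- tuning_curve(gt, rr_n, 320, cfg)
  shift_bins <- (320 - 80) / 10
  expect_equal(which.max(cC),
               ((which.max(cA) - 1 + shift_bins) %% 45) + 1)
  # untuned: flat; all curves integrate to the amplitude
  cu <- tuning_curve(gt, un_n, 80, cfg)
  expect_equal(max(cu), min(cu))
  expect_equal(sum(cA), gt$amplitude_hz[rr_n])
  expect_error(tuning_curve(gt, 10000, 80, cfg), "no such neuron")
})

test_that("teleport periods are longer after omission trials", {
  s <- simulate_session(sim_config(population = c(untuned = 1),
                                   n_trials = 400, switch_trial = 200,
                                   seed = 33))
  fr <- s$frames
  tel_s <- tapply(fr$teleport, fr$trial, sum) / s$config$frame_rate_hz
  om <- s$trials$omission
  expect_gt(min(tel_s[om]), max(1, min(tel_s[!om])))
  expect_true(all(tel_s[om] >= 5 - 0.2 & tel_s[om] <= 10 + 0.2))
  expect_true(all(tel_s[!om] >= 1 - 0.2 & tel_s[!om] <= 5 + 0.2))
})
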