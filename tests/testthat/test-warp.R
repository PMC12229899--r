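speed_profile <- function(shift_bins = 0, nb = 45) {
  x <- seq_len(nb)
  40 - 25 * exp(-0.5 * ((x - 18 - shift_bins) / 4)^2)
}

test_that("identical trials are aligned by identity warps at MSE ~ 0", {
  m <- matrix(rep(speed_profile(), 8), 8, 45, byrow = TRUE)
  fit <- fit_timewarp(m, "shift")
  expect_lt(fit$mse, 1e-6)
  w <- apply_warp(fit, m)
  expect_equal(w, m, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(fit_timewarp(m[1:3, ], "shift"), "5 finite trials")
})

test_that("shift model recovers constructed offsets", {
  shifts <- c(-3, -1, 0, 0, 1, 2, 3, -2)
  m <- t(sapply(shifts, speed_profile))
  fit <- fit_timewarp(m, "shift", seed = 2)
  expect_lt(fit$mse, 0.5)
  # recovered per-trial shifts (warp intercepts) track the true offsets
  rec <- vapply(fit$warps, function(w) w$ys[1], numeric(1)) * 44
  expect_gt(cor(rec, shifts), 0.95)
})

test_that("MSE is nonincreasing along the nested model chain", {
  set.seed(3)
  m <- t(sapply(runif(10, -3, 3), speed_profile))
  m <- m + matrix(rnorm(length(m), 0, 0.8), nrow(m))
  types <- c("shift", "linear", "piecewise-1", "piecewise-2", "piecewise-3")
  mses <- vapply(types, function(ty) fit_timewarp(m, ty, seed = 5)$mse,
                 numeric(1))
  expect_true(all(diff(mses) <= 1e-8))
})

test_that("apply_warp moves a bump by the trial's warp and round-trips", {
  nb <- 45
  fit <- fit_timewarp(matrix(rep(speed_profile(), 6), 6, nb, byrow = TRUE),
                      "shift")
  # hand-built shift warp: +4 bins on trial 1
  s <- 4 / (nb - 1)
  fit$warps[[1]] <- list(xs = c(0, 1), ys = c(s, 1 + s))
  bump <- exp(-0.5 * ((seq_len(nb) - 30) / 2)^2)
  neural <- matrix(rep(bump, 6), 6, nb, byrow = TRUE)
  w <- apply_warp(fit, neural)
  expect_equal(which.max(w[1, ]), 26)    # sampled 4 bins later = moved back
  expect_equal(w[2, ], bump, ignore_attr = TRUE)
  # inverse warp restores the profile away from the clipped edges
  fit$warps[[2]] <- list(xs = c(0, 1), ys = c(-s, 1 - s))
  roundtrip <- apply_warp(fit, rbind(w[1, ], w[1, ], w[3:6, ]))[2, ]
  expect_equal(roundtrip[8:38], bump[8:38], tolerance = 1e-6)
  # 3-d tensors warp per neuron
  arr <- array(rep(neural, 2), c(6, nb, 2))
  wa <- apply_warp(fit, arr)
  expect_equal(wa[, , 1], wa[, , 2])
})

test_that("RO index hits its degenerate values and scale invariance", {
  rewarded <- c(rep(TRUE, 6), rep(FALSE, 4))
  act_r <- matrix(0, 10, 45)
  act_r[rewarded, 20:45] <- 2
  ro1 <- reward_omission_index(act_r, rewarded, zone_start_bin = 9)
  expect_equal(ro1$ro, 1)
  act_o <- matrix(0, 10, 45)
  act_o[!rewarded, 20:45] <- 3
  expect_equal(reward_omission_index(act_o, rewarded, 9)$ro, -1)
  act_eq <- matrix(1, 10, 45)
  expect_equal(reward_omission_index(act_eq, rewarded, 9)$ro, 0)
  # positive scaling leaves the index unchanged
  set.seed(6)
  act <- matrix(rexp(450), 10, 45)
  expect_equal(reward_omission_index(act, rewarded, 9)$ro,
               reward_omission_index(5 * act, rewarded, 9)$ro)
  # zero activity in the included bins -> NaN
  expect_true(is.nan(reward_omission_index(matrix(0, 10, 45), rewarded, 9)$ro))
})

test_that("RO eligibility needs 3 omissions and a post-zone peak", {
  act <- matrix(1, 10, 45)
  few_om <- c(rep(TRUE, 8), FALSE, FALSE)
  expect_false(reward_omission_index(act, few_om, 9)$eligible)
  ok <- c(rep(TRUE, 7), rep(FALSE, 3))
  expect_true(reward_omission_index(act, ok, 9, peak_bin = 20)$eligible)
  expect_false(reward_omission_index(act, ok, 9, peak_bin = 5)$eligible)
})

test_that("warped and raw RO indices agree on a simulated trial set", {
  s <- small_switch_session()
  A <- population_tensor(s, "events")
  A[!is.finite(A)] <- 0
  gt <- s$ground_truth
  rewarded <- s$trials$rewarded[1:30]
  if (sum(!rewarded) >= 3) {
    sm <- speed_map(s$frames$speed_cms, s$frames$position_cm,
                    s$frames$trial, s$frames$teleport, bin_width_cm = 10)
    sm[!is.finite(sm)] <- mean(sm, na.rm = TRUE)
    fit <- fit_timewarp(sm[1:30, ], "linear", seed = 4)
    cells <- which(gt$class %in% c("TR", "RR"))[1:8]
    ro_raw <- vapply(cells, function(i)
      reward_omission_index(A[1:30, , i], rewarded, 9)$ro, numeric(1))
    wA <- apply_warp(fit, A[1:30, , cells])
    ro_w <- vapply(seq_along(cells), function(k)
      reward_omission_index(wA[, , k], rewarded, 9)$ro, numeric(1))
    ok <- is.finite(ro_raw) & is.finite(ro_w)
    expect_gt(cor(ro_raw[ok], ro_w[ok]), 0.7)
  }
})
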