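test_that("dF/F of a constant positive trace is zero", {
  f <- rep(5, 400)
  d <- compute_dff(f, rep(1, 400))
  expect_equal(as.numeric(d), rep(0, 400), tolerance = 1e-12)
})

test_that("maximin baseline matches a hand computation on a toy trace", {
  # 30 samples, window of 7 samples: brute-force rolling min then max with
  # centered truncated windows
  set.seed(1)
  f <- 10 + cumsum(rnorm(30))
  w <- 7
  half_l <- (w - 1) %/% 2
  half_r <- w - 1 - half_l
  roll <- function(x, fun) sapply(seq_along(x), function(i)
    fun(x[max(1, i - half_l):min(length(x), i + half_r)]))
  base <- roll(roll(f, min), max)
  d_expected <- (f - base) / abs(base)
  d <- compute_dff(f, rep(1, 30), frame_rate_hz = w / 20,
                   smooth_sd_samples = 0)
  expect_equal(as.numeric(d), d_expected)
})

test_that("a short step transient rises then returns toward baseline", {
  f <- rep(2, 620)
  f[300:320] <- 6          # shorter than the 20 s window at 15.5 Hz
  d <- compute_dff(f, rep(1, 620))
  expect_gt(max(d[300:320]), 1)
  expect_lt(abs(d[100]), 0.05)
  expect_lt(abs(d[600]), 0.05)
})

test_that("baselines are computed independently per trial", {
  f <- c(rep(2, 300), rep(8, 300))
  trial <- rep(1:2, each = 300)
  d <- compute_dff(f, trial)
  # both trials are constant at their own baseline -> dF/F 0 in both
  expect_equal(as.numeric(d), rep(0, 600), tolerance = 1e-12)
  # zero baseline guarded, not divided
  dz <- compute_dff(rep(0, 100), rep(1, 100))
  expect_true(all(is.na(dz)))
  expect_equal(attr(dz, "n_zero_baseline"), 100L)
})

test_that("spatial binning averages included samples and NaNs empty bins", {
  # 2 trials x 3 bins toy, hand-computed means
  pos <- c(5, 8, 15, 25, 5, 15, 16, 25)
  trial <- c(1, 1, 1, 1, 2, 2, 2, 2)
  trace <- c(1, 3, 10, 4, 7, 2, 4, 6)
  m <- bin_by_position(trace, pos, trial, n_bins = 3, track_length_cm = 30)
  expect_equal(m[1, ], c(mean(c(1, 3)), 10, 4))
  expect_equal(m[2, ], c(7, mean(c(2, 4)), 6))
  # empty bin is NaN, not zero
  m2 <- bin_by_position(c(1, 2), c(5, 25), c(1, 1), n_bins = 3,
                        track_length_cm = 30)
  expect_true(is.nan(m2[1, 2]))
  # position at the track end wraps to bin 1
  m3 <- bin_by_position(9, 30, 1, n_bins = 3, track_length_cm = 30)
  expect_equal(m3[1, 1], 9)
})

test_that("slow frames are excluded by the speed filter", {
  pos <- c(5, 15, 25)
  sp <- c(1, 1, 1)
  m <- bin_by_position(c(4, 5, 6), pos, rep(1, 3), speed_cms = sp,
                       n_bins = 3, track_length_cm = 30)
  expect_true(all(is.nan(m)))
  m2 <- bin_by_position(c(4, 5, 6), pos, rep(1, 3), speed_cms = c(3, 1, 3),
                        n_bins = 3, track_length_cm = 30)
  expect_equal(m2[1, ], c(4, NaN, 6))
})

test_that("binning is invariant to upsampling a piecewise-constant trace", {
  pos <- seq(0.5, 449.5, by = 1)
  trace <- sin(pos / 450 * 2 * pi) + 2
  m1 <- bin_by_position(trace, pos, rep(1, length(pos)))
  up <- rep(seq_along(pos), each = 4)
  m2 <- bin_by_position(trace[up], pos[up], rep(1, length(up)))
  expect_equal(m1, m2)
})

test_that("trial correlation matrix equals pairwise Pearson correlations", {
  set.seed(11)
  A <- matrix(rnorm(4 * 45, 2), 4, 45)
  C <- trial_correlation_matrix(A, smooth_sd_cm = 0)
  brute <- matrix(1, 4, 4)
  for (i in 1:4) for (j in 1:4) brute[i, j] <- cor(A[i, ], A[j, ])
  expect_equal(C, brute, ignore_attr = TRUE)
  expect_equal(diag(C), rep(1, 4), ignore_attr = TRUE)
  # identical trials correlate at 1, sign-flipped profiles at -1
  B <- rbind(A[1, ], A[1, ], 2 * mean(A[1, ]) - A[1, ])
  C2 <- trial_correlation_matrix(B, smooth_sd_cm = 0)
  expect_equal(C2[1, 2], 1)
  expect_equal(C2[1, 3], -1)
})

test_that("correlation matrix is symmetric and equivariant to trial order", {
  set.seed(12)
  A <- matrix(rnorm(6 * 45), 6, 45)
  C <- trial_correlation_matrix(A)
  expect_equal(C, t(C))
  perm <- c(3, 1, 6, 2, 5, 4)
  Cp <- trial_correlation_matrix(A[perm, ])
  expect_equal(Cp, C[perm, perm], ignore_attr = TRUE)
  expect_error(trial_correlation_matrix(A[1, , drop = FALSE]), "2 trials")
})

test_that("population tensors correlate over concatenated neuron profiles", {
  set.seed(13)
  A <- array(rnorm(4 * 45 * 3), c(4, 45, 3))
  C <- trial_correlation_matrix(A, smooth_sd_cm = 0)
  flat <- matrix(A, nrow = 4)
  expect_equal(C[1, 2], cor(flat[1, ], flat[2, ]))
})

test_that("speed-coupled traces are flagged as putative interneurons", {
  set.seed(14)
  speed <- abs(rnorm(3000, 30, 10))
  tab <- exclude_putative_interneurons(
    cbind(speed,                          # r = 1: excluded
          rnorm(3000),                    # white noise: kept
          rep(1, 3000)),                  # constant: undefined, kept + flag
    speed)
  expect_equal(tab$keep, c(FALSE, TRUE, TRUE))
  expect_equal(tab$undefined, c(FALSE, FALSE, TRUE))
  # borderline r ~ 0.4 stays in
  noisy <- speed + rnorm(3000, 0, sd(speed) * sqrt(1 / 0.16 - 1))
  r <- cor(noisy, speed)
  expect_lt(r, 0.5)
  expect_true(exclude_putative_interneurons(cbind(noisy), speed)$keep)
})
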