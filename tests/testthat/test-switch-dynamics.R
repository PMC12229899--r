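two_map_tensor <- function(n1 = 15, n2 = 15, nb = 20, n_neu = 6,
                           noise = 0, seed = 1) {
  set.seed(seed)
  map1 <- matrix(runif(nb * n_neu), nb, n_neu)
  map2 <- matrix(runif(nb * n_neu), nb, n_neu)
  A <- array(0, c(n1 + n2, nb, n_neu))
  for (t in seq_len(n1)) A[t, , ] <- map1 + noise * rnorm(nb * n_neu)
  for (t in n1 + seq_len(n2)) A[t, , ] <- map2 + noise * rnorm(nb * n_neu)
  A
}

test_that("normalize_01 rescales per neuron and flags constants", {
  A <- array(0, c(4, 3, 2))
  A[, , 1] <- matrix(seq(2, 13), 4, 3)
  A[, , 2] <- 5
  An <- normalize_01(A)
  expect_equal(range(An[, , 1]), c(0, 1))
  expect_true(all(An[, , 2] == 0))
  expect_equal(attr(An, "constant_neurons"), 2L)
  # an already-[0,1] neuron spanning the full range is unchanged
  B <- array(runif(24), c(4, 3, 2))
  B[1, 1, 1] <- 0; B[4, 3, 1] <- 1
  expect_equal(normalize_01(B)[, , 1], B[, , 1])
})

test_that("k-means separates two exactly repeated maps", {
  A <- two_map_tensor()
  km <- factorized_kmeans(A, k = 2, restarts = 20, seed = 3)
  expect_equal(km$assign, rep(c(1, 2), each = 15))
  expect_true(all(rowSums(km$U) == 1))
  # centroids equal the maps
  expect_equal(as.numeric(km$V[1, ]), as.numeric(two_map_tensor()[1, , ]),
               tolerance = 1e-12)
  expect_lt(km$objective, 1e-20)
  expect_error(factorized_kmeans(A[1:2, , ], k = 5), "exceeds")
})

test_that("k-means objective matches exhaustive labeling on 6 trials", {
  set.seed(4)
  X <- matrix(rnorm(6 * 8), 6, 8)
  km <- factorized_kmeans(X, k = 2, restarts = 100, seed = 5)
  # brute force over all 2^6 assignments with both clusters nonempty
  best <- Inf
  for (mask in 1:(2^6 - 2)) {
    lab <- as.integer(intToBits(mask))[1:6] + 1L
    sse <- 0
    for (c in 1:2) {
      rows <- X[lab == c, , drop = FALSE]
      if (nrow(rows) == 0) next
      ctr <- colMeans(rows)
      sse <- sse + sum(sweep(rows, 2, ctr)^2)
    }
    best <- min(best, sse)
  }
  expect_equal(km$objective, best, tolerance = 1e-9)
})

test_that("more restarts never worsen the objective", {
  set.seed(6)
  X <- matrix(rnorm(30 * 12), 30, 12)
  o1 <- factorized_kmeans(X, restarts = 1, seed = 7)$objective
  o100 <- factorized_kmeans(X, restarts = 100, seed = 7)$objective
  expect_lte(o100, o1 + 1e-9)
})

test_that("distance score is -1/0/+1 at centroid 1, midpoint, centroid 2", {
  set.seed(8)
  v1 <- runif(40); v2 <- runif(40)
  X <- rbind(v1, (v1 + v2) / 2, v2)
  p <- distance_score(X, v1, v2)
  expect_equal(p, c(-1, 0, 1), ignore_attr = TRUE)
  expect_error(distance_score(X, v1, v1), "identical centroids")
})

test_that("distance score is invariant to a consistent feature rotation", {
  set.seed(9)
  v1 <- runif(20); v2 <- runif(20)
  X <- matrix(runif(5 * 20), 5, 20)
  p0 <- distance_score(X, v1, v2)
  Q <- qr.Q(qr(matrix(rnorm(400), 20)))
  expect_equal(distance_score(X %*% Q, as.numeric(v1 %*% Q),
                              as.numeric(v2 %*% Q)), p0, tolerance = 1e-9)
})

test_that("sigmoid fit recovers a step at trial 30 and its own curve", {
  p_step <- c(rep(-1, 30), rep(1, 30)) + 0.05 * sin(1:60)
  fit <- fit_remap_trial(p_step)
  expect_true(fit$converged)
  expect_lt(abs(fit$remap_trial - 30.5), 1)
  # noiseless logistic input returns its own parameters
  t <- 1:60
  p_log <- -0.8 + 1.6 / (1 + exp(-0.9 * (t - 22.3)))
  self <- fit_remap_trial(p_log)
  expect_equal(self$remap_trial, 22.3, tolerance = 0.01)
  expect_equal(unname(self$params["s"]), 0.9, tolerance = 0.01)
  # flat series cannot converge
  expect_false(fit_remap_trial(rep(0.2, 40))$converged)
})

test_that("speckled holdout separates two-map from one-map sessions", {
  A <- two_map_tensor(noise = 0.05, seed = 10)
  res <- kmeans_significance(A, reps = 15, restarts = 5, seed = 11)
  expect_true(res$include)
  expect_lt(res$p, 0.05)
  # single-map session: no advantage over the rotation null
  one <- two_map_tensor(noise = 0.3, seed = 12)
  for (t in 1:30) one[t, , ] <- one[1, , ] + 0.3 * rnorm(20 * 6)
  res1 <- kmeans_significance(one, reps = 15, restarts = 5, seed = 13)
  expect_gt(res1$p, 0.01)
  expect_error(kmeans_significance(A, holdout = 0), "positive")
})

test_that("full tensor pipeline finds the simulated remap trial", {
  s <- small_switch_session()
  gt <- s$ground_truth
  rr <- which(gt$class == "RR")
  A <- population_tensor(s, "events", smooth_sd_cm = 10)
  out <- remap_trial_from_tensor(A[, , rr], restarts = 30, seed = 14)
  expect_true(out$converged)
  expect_gt(out$remap_trial, 28)
  expect_lt(out$remap_trial, 34)
  # lags: licking trails the neural switch by the simulated ~2 trials
  lt <- lag_table(s, rr, restarts = 30)
  expect_true(lt$all_converged)
  expect_gt(lt$lag_lick, 0)
  expect_lt(abs(lt$lag_lick - 2), 2)
})
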