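#' Scale activity to [0, 1] per neuron over the session
#'
#' (x - min) / (max - min) applied per neuron across all trials and bins,
#' making neurons comparable before clustering. Constant neurons are set to
#' 0 and flagged.
#'
#' @param A trials x bins x neurons array (or trials x bins matrix treated
#'   as one neuron).
#' @return array of the same shape with attribute `constant_neurons`.
#' @export
normalize_01 <- function(A) {
  if (is.matrix(A)) A <- array(A, c(dim(A), 1L))
  const <- integer(0)
  for (j in seq_len(dim(A)[3])) {
    v <- A[, , j]
    lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
    if (!is.finite(lo) || hi == lo) {
      A[, , j] <- 0
      const <- c(const, j)
    } else {
      A[, , j] <- (v - lo) / (hi - lo)
    }
  }
  attr(A, "constant_neurons") <- const
  A
}

flatten_trials <- function(A) {
  if (is.matrix(A)) A else matrix(A, nrow = dim(A)[1])
}

#' Factorized k-means on trial population vectors
#'
#' Clusters trials by k-means on their flattened bins x neurons population
#' vectors: X_ijn = sum_k U_i^(k) V_jn^(k) with one-hot trial assignments U
#' and cluster-centroid maps V. Best of `restarts` initializations by
#' within-cluster SSE. Cluster 1 is standardized to the cluster of the
#' first trial in the session.
#'
#' @param A trials x bins x neurons array (normalized; see
#'   [normalize_01()]) or trials x features matrix. NaN entries are imputed
#'   with column means before clustering.
#' @param k number of clusters (2).
#' @param restarts random restarts (100).
#' @param seed RNG seed.
#' @return list of class `rr_kmeans`: `U` (trials x k one-hot), `assign`,
#'   `V` (k x features centroid matrix), `objective` (total within-cluster
#'   SSE), `dims`.
#' @export
factorized_kmeans <- function(A, k = 2, restarts = 100, seed = 1L) {
  X <- flatten_trials(A)
  if (k > nrow(X)) stop("k exceeds the number of trials")
  X <- impute_colmeans(X)
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = restarts, iter.max = 100)
  # standardize labels: cluster 1 = first cluster appearing in the session
  first_seen <- vapply(seq_len(k), function(c) which(km$cluster == c)[1],
                       numeric(1))
  relab <- order(first_seen)
  assign <- match(km$cluster, relab)
  V <- km$centers[relab, , drop = FALSE]
  U <- matrix(0L, nrow(X), k)
  U[cbind(seq_len(nrow(X)), assign)] <- 1L
  out <- list(U = U, assign = assign, V = V, objective = km$tot.withinss,
              dims = if (is.matrix(A)) dim(A) else dim(A))
  class(out) <- "rr_kmeans"
  out
}

impute_colmeans <- function(X) {
  bad <- !is.finite(X)
  if (any(bad)) {
    cm <- colMeans(X, na.rm = TRUE)
    cm[!is.finite(cm)] <- 0
    X[bad] <- cm[col(X)[bad]]
  }
  X
}

#' Speckled-holdout significance of the two-map clustering
#'
#' Tests whether a k = 2 clustering reconstructs the population activity
#' better than expected from a single-map session. On each of `reps`
#' repetitions, a random 10% of matrix entries is held out (speckled
#' holdout), the model is fit on the remaining entries (held-out entries
#' imputed with column means), and the uncentered test R^2 of the k-means
#' reconstruction U V is evaluated on the held-out entries. The null
#' statistic repeats this on data randomized by a random orthogonal
#' rotation across the trial dimension, which preserves per-feature second
#' moments while destroying discrete trial clusters. Sessions are included
#' when the real statistic exceeds the null (paired one-sided Wilcoxon
#' signed-rank, P < 0.05).
#'
#' @param A trials x bins x neurons array (normalized) or trials x features
#'   matrix.
#' @param holdout held-out fraction of entries (0.10); must be positive.
#' @param reps repetitions (50).
#' @param k clusters (2).
#' @param restarts k-means restarts per repetition (10).
#' @param seed RNG seed.
#' @return list of class `rr_kmeans_test`: `include`, `p`, `r2_real`,
#'   `r2_null`.
#' @export
kmeans_significance <- function(A, holdout = 0.10, reps = 50, k = 2,
                                restarts = 10, seed = 1L) {
  if (holdout <= 0) stop("holdout fraction must be positive")
  X <- flatten_trials(A)
  X <- impute_colmeans(X)
  # center across trials: the common mean map is captured by any k and
  # would otherwise dominate the uncentered R^2 for real data while the
  # rotation null destroys it, passing even one-map sessions
  X <- sweep(X, 2L, colMeans(X))
  set.seed(seed)
  n <- length(X)
  r2_one <- function(M) {
    hold <- sample.int(n, max(1L, round(holdout * n)))
    Mtr <- M
    Mtr[hold] <- NA
    Mtr <- impute_colmeans(Mtr)
    km <- stats::kmeans(Mtr, centers = k, nstart = restarts, iter.max = 100)
    recon <- km$centers[km$cluster, , drop = FALSE]
    1 - sum((M[hold] - recon[hold])^2) / sum(M[hold]^2)
  }
  r2_real <- numeric(reps); r2_null <- numeric(reps)
  for (r in seq_len(reps)) {
    r2_real[r] <- r2_one(X)
    Q <- qr.Q(qr(matrix(stats::rnorm(nrow(X)^2), nrow(X))))
    r2_null[r] <- r2_one(Q %*% X)
  }
  wt <- stats::wilcox.test(r2_real, r2_null, paired = TRUE,
                           alternative = "greater", exact = FALSE)
  out <- list(include = wt$p.value < 0.05, p = wt$p.value,
              r2_real = r2_real, r2_null = r2_null)
  class(out) <- "rr_kmeans_test"
  out
}

#' Distance score of each trial between the two cluster centroids
#'
#' Signed normalized projection of each trial's population vector onto the
#' inter-centroid axis, scaled so that a trial equal to the first (pre-
#' switch) centroid scores -1 and a trial equal to the second centroid
#' scores +1; the midpoint scores 0. There is no restriction on how often
#' the score crosses the midpoint.
#'
#' @param A trials x bins x neurons array or trials x features matrix.
#' @param V1,V2 centroid vectors (first and second cluster).
#' @return numeric distance score per trial.
#' @export
distance_score <- function(A, V1, V2) {
  X <- impute_colmeans(flatten_trials(A))
  v1 <- as.numeric(V1); v2 <- as.numeric(V2)
  d <- v2 - v1
  den <- sum(d^2)
  if (den == 0) stop("identical centroids")
  mid <- (v1 + v2) / 2
  as.numeric((X - matrix(mid, nrow(X), length(mid), byrow = TRUE)) %*% d) /
    (den / 2)
}

#' Sigmoid remap trial from a distance-score series
#'
#' Fits a 4-parameter logistic P(t) = a + (b - a) / (1 + exp(-s (t - t0)))
#' by Levenberg-Marquardt least squares (t0 bounded to the trial range,
#' slope s > 0, initialized at the trial of maximum score change). The
#' remap trial is the inflection t0. Flat or non-sigmoidal series fail to
#' converge and are flagged.
#'
#' @param p distance-score (or normalized behavioral score) series per trial.
#' @return list of class `rr_remaptrial`: `remap_trial`, `converged`,
#'   `params` (a, b, s, t0).
#' @export
fit_remap_trial <- function(p) {
  t <- seq_along(p)
  ok <- is.finite(p)
  if (sum(ok) < 5L || stats::sd(p[ok]) < 1e-10) {
    return(structure(list(remap_trial = NA_real_, converged = FALSE,
                          params = NULL), class = "rr_remaptrial"))
  }
  t0_init <- t[ok][which.max(abs(diff(p[ok])))] + 0.5
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a + (b - a) / (1 + exp(-s * (x - t0))),
      data = data.frame(x = t[ok], y = p[ok]),
      start = list(a = min(p[ok]), b = max(p[ok]), s = 1, t0 = t0_init),
      lower = c(a = -2, b = -2, s = 1e-3, t0 = 1),
      upper = c(a = 2, b = 2, s = 20, t0 = length(p)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(remap_trial = NA_real_, converged = FALSE,
                          params = NULL), class = "rr_remaptrial"))
  }
  cf <- stats::coef(fit)
  # a fit that never leaves its floor (slope degenerate or amplitude ~0)
  # is not a detectable transition
  conv <- abs(cf["b"] - cf["a"]) > 0.05 && cf["s"] > 1e-3
  structure(list(remap_trial = unname(cf["t0"]), converged = conv,
                 params = cf), class = "rr_remaptrial")
}

#' @exportS3Method base::print
print.rr_remaptrial <- function(x, ...) {
  if (!x$converged) cat("Remap trial: no converged sigmoid fit\n")
  else cat(sprintf("Remap trial (sigmoid inflection): %.2f\n", x$remap_trial))
  invisible(x)
}

#' Remap-trial detection for one activity or behavior tensor
#'
#' Runs the full trial-resolved pipeline on a trials x bins x neurons
#' tensor (neural population vector) or trials x bins matrix (licking or
#' speed map, maximum-normalized): scale to [0, 1], factorized k-means with
#' k = 2, distance score against the two centroids, sigmoid fit.
#'
#' @param A input tensor/matrix (raw; normalized internally).
#' @param restarts k-means restarts (100).
#' @param seed RNG seed.
#' @return list: `remap_trial`, `converged`, `score` (per-trial distance
#'   score), `model` (`rr_kmeans`).
#' @export
remap_trial_from_tensor <- function(A, restarts = 100, seed = 1L) {
  An <- normalize_01(A)
  km <- factorized_kmeans(An, k = 2, restarts = restarts, seed = seed)
  sc <- distance_score(An, km$V[1, ], km$V[2, ])
  fit <- fit_remap_trial(sc)
  list(remap_trial = fit$remap_trial, converged = fit$converged,
       score = sc, model = km, fit = fit)
}

#' Neural-versus-behavioral remap lags for a session
#'
#' Computes remap trials for the neural population vector (a chosen
#' subpopulation), the spatially binned lick map and the speed map, and
#' their lags (behavioral minus neural; positive = neural leads). Sessions
#' lacking a converged sigmoid in any domain are excluded from the lag
#' columns.
#'
#' @param session an `rr_session`.
#' @param neurons neuron indices for the neural population vector.
#' @param restarts k-means restarts (100).
#' @param seed RNG seed.
#' @return one-row data.frame: `remap_neural`, `remap_lick`, `remap_speed`,
#'   `lag_lick`, `lag_speed`, `all_converged`.
#' @export
lag_table <- function(session, neurons, restarts = 100, seed = NULL) {
  cfg <- session$config
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "switch-timing")
  A <- population_tensor(session, "events", smooth_sd_cm = 10)
  neural <- remap_trial_from_tensor(A[, , neurons, drop = FALSE],
                                    restarts, derive_seed(seed, "pv"))
  fr <- session$frames
  lick_m <- lick_rate_map(fr$lick, fr$position_cm, fr$trial, fr$teleport,
                          cfg$frame_rate_hz, cfg$n_bins, cfg$track_length_cm)
  lick_m[!is.finite(lick_m)] <- 0
  lick_m <- lick_m / max(lick_m)
  speed_m <- speed_map(fr$speed_cms, fr$position_cm, fr$trial, fr$teleport,
                       bin_width_cm = cfg$track_length_cm / cfg$n_bins,
                       track_length_cm = cfg$track_length_cm)
  speed_m[!is.finite(speed_m)] <- 0
  speed_m <- speed_m / max(speed_m)
  lick <- remap_trial_from_tensor(lick_m, restarts, derive_seed(seed, "lick"))
  speed <- remap_trial_from_tensor(speed_m, restarts, derive_seed(seed, "speed"))
  all_conv <- neural$converged && lick$converged && speed$converged
  data.frame(remap_neural = neural$remap_trial,
             remap_lick = lick$remap_trial,
             remap_speed = speed$remap_trial,
             lag_lick = if (all_conv) lick$remap_trial - neural$remap_trial
                        else NA_real_,
             lag_speed = if (all_conv) speed$remap_trial - neural$remap_trial
                         else NA_real_,
             all_converged = all_conv)
}
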