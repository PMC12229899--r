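#' Build the encoding-model design matrix
#'
#' Task variables: linear track position and reward-relative phase, each
#' expanded into 45 raised-cosine basis functions (one per 10-cm / ~0.14-rad
#' bin, half-width 1.5 bin widths, unit-sum normalized across bases), and a
#' rewarded-by-position interaction, where `rewarded` switches from 0 to 1
#' at reward delivery and stays 1 until the trial end (0 throughout omission
#' trials). Movement variables: running speed and acceleration (smoothed
#' with a 5-sample s.d. Gaussian) and lick counts (2-sample s.d. Gaussian),
#' each quantile-transformed and expanded with cubic B-splines on 5 uniform
#' knots (7 bases each). All 45+45+45+7+7+7 = 156 columns are z-scored
#' across samples. Teleport frames are excluded.
#'
#' @param session an `rr_session`.
#' @return list of class `rr_design`: `X` (samples x 156), `groups`
#'   (column group names), `frame_idx` (rows of `session$frames` used),
#'   `trial` (per sample), `strata` (per trial: rewarded-before /
#'   rewarded-after / omission), `pos_bin` (per sample),
#'   `degenerate_columns`.
#' @export
build_design_matrix <- function(session) {
  cfg <- session$config
  fr <- session$frames
  nb <- cfg$n_bins
  L <- cfg$track_length_cm
  use <- !fr$teleport & !is.na(fr$position_cm)
  idx <- which(use)
  pos <- fr$position_cm[idx]
  trial <- fr$trial[idx]
  zone_phase <- to_periodic(session$trials$zone_start_cm, L)
  rr_phase <- align_to_reward(to_periodic(pos, L), zone_phase[trial])

  # rewarded indicator: 1 from delivery to trial end, 0 on omissions
  rewarded <- numeric(length(idx))
  for (t in which(session$trials$rewarded)) {
    rp <- session$trials$reward_pos_cm[t]
    rewarded[trial == t & pos >= rp] <- 1
  }

  cosine_bases <- function(phase, n) {
    centers <- -pi + (seq_len(n) - 0.5) * 2 * pi / n
    w <- 1.5 * 2 * pi / n
    D <- abs(wrap_pi(outer(phase, centers, "-")))
    B <- 0.5 * (1 + cos(pi * D / w)) * (D < w)
    B / rowSums(B)
  }
  pos_B <- cosine_bases(to_periodic(pos, L), nb)
  rr_B <- cosine_bases(rr_phase, nb)
  rew_B <- pos_B * rewarded

  qt <- function(x) (rank(x, ties.method = "average") - 1) / (length(x) - 1)
  spline7 <- function(x) {
    knots <- seq(-0.75, 1.75, by = 0.25)    # 5 uniform knots extended by degree
    splines::splineDesign(knots, pmin(pmax(x, 0), 1), ord = 4L)
  }
  speed_s <- smooth_gaussian(fr$speed_cms, 5)[idx]
  accel <- c(0, diff(fr$speed_cms)) * cfg$frame_rate_hz
  accel_s <- smooth_gaussian(accel, 5)[idx]
  lick_s <- smooth_gaussian(as.numeric(fr$lick), 2)[idx]
  mv <- cbind(spline7(qt(speed_s)), spline7(qt(accel_s)), spline7(qt(lick_s)))

  X <- cbind(pos_B, rr_B, rew_B, mv)
  groups <- c(rep("position", nb), rep("rr_position", nb),
              rep("rewarded_position", nb), rep("speed", 7L),
              rep("acceleration", 7L), rep("licking", 7L))
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  degen <- which(sdv == 0)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  colnames(X) <- paste0(groups, "_", stats::ave(seq_along(groups), groups,
                                                FUN = seq_along))
  strata <- ifelse(!session$trials$rewarded, "omission",
                   ifelse(seq_len(nrow(session$trials)) <= cfg$switch_trial,
                          "rewarded_before", "rewarded_after"))
  pos_bin <- floor((pos %% L) / (L / nb)) + 1L
  out <- list(X = X, groups = groups, frame_idx = idx, trial = trial,
              strata = strata, pos_bin = pos_bin,
              degenerate_columns = degen)
  class(out) <- "rr_design"
  out
}

poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(t1 - (y - mu))
}

#' Fit the Poisson encoding model for one neuron
#'
#' Elastic-net (mixing 0.5) Poisson regression via glmnet on the design
#' matrix, with a trial-grouped 85/15 train/test split stratified over
#' rewarded-before / rewarded-after / omission trials, and fivefold
#' cross-validation inside the training trials to select the penalty.
#' Performance on the held-out test trials is reported as the fraction
#' deviance explained, FDE = 1 - dev_model / dev_null, with the null model
#' predicting the training-mean rate. Downstream analyses include cells
#' with FDE > 0.15.
#'
#' @param design an `rr_design` from [build_design_matrix()].
#' @param y per-sample deconvolved activity (aligned with `design$X`), or a
#'   full per-frame vector (subset by `design$frame_idx`).
#' @param test_frac held-out trial fraction (0.15).
#' @param n_folds CV folds within training (5).
#' @param alpha elastic-net mixing (0.5).
#' @param nlambda penalty path length (10).
#' @param seed RNG seed for the split.
#' @return object of class `rr_glmfit`: `intercept`, `beta`, `lambda`,
#'   `fde_test`, `converged`, train-set deviances (`dev_full`, `dev_null`),
#'   `train_samples`, `test_samples`.
#' @export
fit_poisson_glm <- function(design, y, test_frac = 0.15, n_folds = 5,
                            alpha = 0.5, nlambda = 10, seed = 1L) {
  stopifnot(inherits(design, "rr_design"))
  if (length(y) > nrow(design$X)) y <- y[design$frame_idx]
  stopifnot(length(y) == nrow(design$X))
  set.seed(seed)
  trials <- sort(unique(design$trial))
  strata <- design$strata[trials]
  test_trials <- unlist(lapply(unique(strata), function(s) {
    tr <- trials[strata == s]
    n_test <- max(1L, round(test_frac * length(tr)))
    sample(tr, n_test)
  }), use.names = FALSE)
  is_test <- design$trial %in% test_trials
  train_trials <- setdiff(trials, test_trials)
  # trial-grouped fold ids, stratified
  foldid_tr <- integer(length(train_trials))
  names(foldid_tr) <- train_trials
  for (s in unique(strata)) {
    tr <- train_trials[train_trials %in% trials[strata == s]]
    foldid_tr[as.character(tr)] <- sample(rep_len(seq_len(n_folds), length(tr)))
  }
  foldid <- foldid_tr[as.character(design$trial[!is_test])]

  Xtr <- design$X[!is_test, , drop = FALSE]
  ytr <- y[!is_test]
  if (stats::sd(ytr) == 0 || stats::sd(y[is_test]) == 0) {
    # constant response: null deviance is 0, FDE defined as 0 and flagged
    out <- list(intercept = log(max(mean(ytr), 1e-12)),
                beta = numeric(ncol(design$X)), lambda = NA_real_,
                fde_test = 0, converged = TRUE,
                dev_full = poisson_deviance(ytr, rep(mean(ytr), length(ytr))),
                dev_null = poisson_deviance(ytr, rep(mean(ytr), length(ytr))),
                train_samples = which(!is_test),
                test_samples = which(is_test), degenerate_null = TRUE)
    class(out) <- "rr_glmfit"
    return(out)
  }
  fit <- tryCatch(
    glmnet::cv.glmnet(Xtr, ytr, family = "poisson", alpha = alpha,
                      nlambda = nlambda, lambda.min.ratio = 0.01,
                      foldid = as.integer(foldid), standardize = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(converged = FALSE, fde_test = NA_real_)
    class(out) <- "rr_glmfit"
    return(out)
  }
  cf <- as.numeric(stats::coef(fit, s = "lambda.min"))
  intercept <- cf[1]
  beta <- cf[-1]
  mu_test <- exp(intercept +
                   as.numeric(design$X[is_test, , drop = FALSE] %*% beta))
  dev_model <- poisson_deviance(y[is_test], mu_test)
  dev_null_test <- poisson_deviance(y[is_test], rep(mean(ytr), sum(is_test)))
  fde <- if (dev_null_test <= 0) 0 else 1 - dev_model / dev_null_test
  mu_tr <- exp(intercept + as.numeric(Xtr %*% beta))
  out <- list(intercept = intercept, beta = beta,
              lambda = fit$lambda.min, fde_test = fde,
              converged = TRUE,
              dev_full = poisson_deviance(ytr, mu_tr),
              dev_null = poisson_deviance(ytr, rep(mean(ytr), length(ytr))),
              train_samples = which(!is_test), test_samples = which(is_test),
              degenerate_null = dev_null_test <= 0)
  class(out) <- "rr_glmfit"
  out
}

#' @exportS3Method base::print
print.rr_glmfit <- function(x, ...) {
  if (!x$converged) { cat("Poisson GLM: did not converge\n"); return(invisible(x)) }
  cat(sprintf("Poisson GLM: FDE (test) = %.3f, lambda = %.4g, %d nonzero coefs\n",
              x$fde_test, x$lambda, sum(x$beta != 0)))
  invisible(x)
}

#' Relative contribution of a variable group by ablation
#'
#' Zeroes the fitted coefficients of one variable group and measures the
#' deviance increase on the cross-validation (training) data, normalized by
#' the full model's improvement over the null:
#' (dev_ablated - dev_full) / (dev_null - dev_full). Also returns the
#' per-position-bin variant (deviance sums restricted to samples in each
#' 10-cm track bin).
#'
#' @param fit an `rr_glmfit`.
#' @param design the `rr_design` used for the fit.
#' @param y per-sample activity (or per-frame, subset internally).
#' @param group group name (e.g. "rr_position").
#' @return list: `overall`, `per_bin` (length 45).
#' @export
relative_contribution <- function(fit, design, y, group) {
  stopifnot(inherits(fit, "rr_glmfit"), fit$converged)
  if (!group %in% design$groups) stop("unknown group: ", group)
  if (length(y) > nrow(design$X)) y <- y[design$frame_idx]
  tr <- fit$train_samples
  Xtr <- design$X[tr, , drop = FALSE]
  ytr <- y[tr]
  beta_abl <- fit$beta
  beta_abl[design$groups == group] <- 0
  mu_full <- exp(fit$intercept + as.numeric(Xtr %*% fit$beta))
  mu_abl <- exp(fit$intercept + as.numeric(Xtr %*% beta_abl))
  mu_null <- rep(mean(ytr), length(ytr))
  denom <- fit$dev_null - fit$dev_full
  overall <- if (denom <= 0) NA_real_
             else (poisson_deviance(ytr, mu_abl) - fit$dev_full) / denom
  dev_terms <- function(yy, mm) {
    mm <- pmax(mm, 1e-12)
    2 * (ifelse(yy > 0, yy * log(yy / mm), 0) - (yy - mm))
  }
  pb <- design$pos_bin[tr]
  nb <- max(design$pos_bin)
  per_bin <- rep(NA_real_, nb)
  d_abl <- dev_terms(ytr, mu_abl); d_full <- dev_terms(ytr, mu_full)
  d_null <- dev_terms(ytr, mu_null)
  for (b in seq_len(nb)) {
    sel <- pb == b
    if (!any(sel)) next
    den_b <- sum(d_null[sel]) - sum(d_full[sel])
    per_bin[b] <- if (den_b <= 0) NA_real_
                  else (sum(d_abl[sel]) - sum(d_full[sel])) / den_b
  }
  list(overall = overall, per_bin = per_bin)
}

#' Encoding-model analysis over a set of neurons
#'
#' Fits the Poisson encoding model per neuron, computes the relative
#' contribution of every variable group, and identifies each well-fit
#' cell's top predictor (maximum relative contribution).
#'
#' @param session an `rr_session`.
#' @param neurons neuron indices.
#' @param fde_min inclusion threshold on test FDE for contribution
#'   analysis (0.15).
#' @param seed RNG seed for the splits.
#' @param design optionally a precomputed `rr_design`.
#' @return data.frame with per-neuron `fde`, one contribution column per
#'   group, `top_predictor` (NA when FDE <= fde_min or non-converged).
#' @export
encoding_glm_analysis <- function(session, neurons, fde_min = 0.15,
                                  seed = NULL, design = NULL) {
  cfg <- session$config
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "glm-split")
  if (is.null(design)) design <- build_design_matrix(session)
  grp <- unique(design$groups)
  res <- data.frame(neuron = neurons, fde = NA_real_,
                    top_predictor = NA_character_,
                    stringsAsFactors = FALSE)
  for (g in grp) res[[paste0("rc_", g)]] <- NA_real_
  for (k in seq_along(neurons)) {
    yv <- session$events[design$frame_idx, neurons[k]]
    fit <- fit_poisson_glm(design, yv, seed = seed)
    if (!fit$converged) next
    res$fde[k] <- fit$fde_test
    if (is.na(fit$fde_test) || fit$fde_test <= fde_min) next
    rcs <- vapply(grp, function(g)
      relative_contribution(fit, design, yv, g)$overall, numeric(1))
    for (g in grp) res[[paste0("rc_", g)]][k] <- rcs[[g]]
    if (!all(is.na(rcs)))
      res$top_predictor[k] <- grp[which.max(rcs)]
  }
  res
}

#' Distribution of top predictors per subpopulation
#'
#' @param analysis data.frame from [encoding_glm_analysis()].
#' @param labels character vector of subpopulation labels, aligned with
#'   `analysis$neuron`.
#' @return table of counts (subpopulation x top predictor); empty
#'   subpopulations give empty rows.
#' @export
top_predictor_table <- function(analysis, labels) {
  keep <- !is.na(analysis$top_predictor)
  table(subpop = labels[keep], top = analysis$top_predictor[keep])
}
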