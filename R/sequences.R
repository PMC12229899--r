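#' Cross-validated sequence sorting across a reward switch
#'
#' Neurons are sorted by their peak firing positions on the odd pre-switch
#' trials (unsmoothed binned dF/F in circular track coordinates). The sort
#' is evaluated on the held-out even pre-switch trials and on the
#' post-switch trials: the sequence positions before vs after are the peak
#' positions of the corresponding trial averages.
#'
#' @param session an `rr_session`.
#' @param neurons neuron indices forming the sequence (e.g. an RR or TR
#'   subpopulation); at least 2.
#' @param trial_sets optional pre/post trial sets.
#' @param min_cells minimum cells required (5); fewer flags `low_n` and
#'   returns NA statistics.
#' @param n_perm permutations for the significance test (1000).
#' @param seed RNG seed for the permutation test.
#' @return list of class `rr_sequence`: `order` (sorted neuron ids),
#'   `positions_before`, `positions_after` (phases in radians, sorted
#'   order), `rho`, `p_perm`, `n_cells`, `low_n`.
#' @export
cross_validated_sequence <- function(session, neurons, trial_sets = NULL,
                                     min_cells = 5, n_perm = 1000,
                                     seed = NULL) {
  cfg <- session$config
  if (is.null(seed)) seed <- derive_seed(cfg$seed, "sequence-perm")
  if (is.null(trial_sets)) trial_sets <- default_trial_sets(session)
  if (length(neurons) < 2L) stop("need at least 2 neurons")
  A <- population_tensor(session, "dff", smooth_sd_cm = 0)
  trials <- sort(unique(session$frames$trial))
  pre <- match(trial_sets[[1]], trials)
  post <- match(trial_sets[[2]], trials)
  odd_pre <- pre[seq_along(pre) %% 2L == 1L]
  even_pre <- pre[seq_along(pre) %% 2L == 0L]

  peak_of <- function(rows, i) spatial_peak(A[rows, , i, drop = TRUE])
  sort_peaks <- vapply(neurons, function(i) peak_of(odd_pre, i), numeric(1))
  ord <- neurons[order(sort_peaks)]
  pk_before <- vapply(ord, function(i) peak_of(even_pre, i), numeric(1))
  pk_after <- vapply(ord, function(i) peak_of(post, i), numeric(1))
  pos_before <- bin_phase(pk_before, cfg$n_bins, cfg$track_length_cm)
  pos_after <- bin_phase(pk_after, cfg$n_bins, cfg$track_length_cm)

  low_n <- length(neurons) < min_cells
  if (low_n) {
    rho <- NA_real_; p <- NA_real_
  } else {
    rho <- circ_circ_corr(pos_before, pos_after)
    set.seed(seed)
    p <- sequence_permutation_test(pos_before, pos_after, n_perm = n_perm)
  }
  out <- list(order = ord, positions_before = pos_before,
              positions_after = pos_after, rho = rho, p_perm = p,
              n_cells = length(neurons), low_n = low_n)
  class(out) <- "rr_sequence"
  out
}

#' @exportS3Method base::print
print.rr_sequence <- function(x, ...) {
  cat("Sequence of", x$n_cells, "cells: rho =",
      format(x$rho, digits = 3), ", permutation P =",
      format(x$p_perm, digits = 3),
      if (x$low_n) "[low n]\n" else "\n")
  invisible(x)
}

#' Permutation test for sequence preservation
#'
#' Randomly permutes the cell identities of the after-switch positions and
#' recomputes the circular-circular correlation. Two-tailed:
#' P = (n_{|rho_shuf| >= |rho_obs|} + 1) / (N_perm + 1), so with 1000
#' permutations the smallest attainable P is 1/1001 (< 0.001).
#'
#' @param positions_before,positions_after phase vectors (radians).
#' @param n_perm number of permutations (1000).
#' @param exhaustive enumerate all n! relabelings instead of sampling
#'   (only for n <= 7 cells).
#' @return permutation P value in [1/(N+1), 1].
#' @export
sequence_permutation_test <- function(positions_before, positions_after,
                                      n_perm = 1000, exhaustive = FALSE) {
  obs <- circ_circ_corr(positions_before, positions_after)
  if (is.na(obs)) return(NA_real_)
  if (exhaustive) {
    n <- length(positions_after)
    stopifnot(n <= 7L)
    perms <- all_permutations(n)
    shuf <- vapply(perms, function(p)
      circ_circ_corr(positions_before, positions_after[p]), numeric(1))
    return((sum(abs(shuf) >= abs(obs), na.rm = TRUE) + 1) /
             (length(perms) + 1))
  }
  shuf <- vapply(seq_len(n_perm), function(s)
    circ_circ_corr(positions_before, sample(positions_after)), numeric(1))
  (sum(abs(shuf) >= abs(obs), na.rm = TRUE) + 1) / (n_perm + 1)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Sequence density over position bins
#'
#' Number of cells with peaks in each 2 pi / n_bins phase bin, divided by
#' the total number of place cells (so the densities of subpopulations are
#' comparable). Smoothing, if any, is for plots only and never applied
#' before statistics.
#'
#' @param peaks phases in radians.
#' @param n_place_cells denominator.
#' @param n_bins number of phase bins (45).
#' @return numeric vector of per-bin fractions.
#' @export
sequence_density <- function(peaks, n_place_cells, n_bins = 45) {
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  graphics::hist(wrap_pi(peaks), breaks = breaks, plot = FALSE)$counts /
    n_place_cells
}

#' Match ROIs across days by pixel intersection-over-union
#'
#' Greedy best-match assignment on the IoU matrix of ROI pixel masks. The
#' acceptance rule is the best-vs-second-best property: a candidate match is
#' accepted only if its IoU exceeds the second-best IoU in both its row and
#' its column (and is positive); the reported threshold is the smallest
#' accepted IoU.
#'
#' @param masks_day1,masks_day2 lists of integer vectors of pixel indices
#'   (or logical matrices, flattened internally). Empty masks are excluded.
#' @return data.frame with `roi_day1`, `roi_day2`, `iou`; attribute
#'   `threshold`.
#' @export
match_rois_across_days <- function(masks_day1, masks_day2) {
  as_px <- function(m) if (is.logical(m)) which(m) else as.integer(m)
  m1 <- lapply(masks_day1, as_px)
  m2 <- lapply(masks_day2, as_px)
  ok1 <- which(lengths(m1) > 0L)
  ok2 <- which(lengths(m2) > 0L)
  iou <- matrix(0, length(ok1), length(ok2))
  for (a in seq_along(ok1)) for (b in seq_along(ok2)) {
    i <- length(intersect(m1[[ok1[a]]], m2[[ok2[b]]]))
    if (i > 0L)
      iou[a, b] <- i / length(union(m1[[ok1[a]]], m2[[ok2[b]]]))
  }
  second_best <- function(v) if (length(v) < 2L) 0 else sort(v, decreasing = TRUE)[2]
  pairs <- list()
  work <- iou
  repeat {
    if (all(work <= 0)) break
    ij <- arrayInd(which.max(work), dim(work))
    a <- ij[1]; b <- ij[2]
    best <- work[a, b]
    accept <- best > second_best(iou[a, ]) && best > second_best(iou[, b])
    if (accept)
      pairs[[length(pairs) + 1L]] <- data.frame(roi_day1 = ok1[a],
                                                roi_day2 = ok2[b], iou = best)
    work[a, ] <- 0
    work[, b] <- 0
  }
  out <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(roi_day1 = integer(0), roi_day2 = integer(0), iou = numeric(0))
  attr(out, "threshold") <- if (nrow(out) > 0L) min(out$iou) else NA_real_
  out
}

#' Cross-day recruitment table of remapping categories
#'
#' For cells followed across a day pair, tabulates the fraction of day-A
#' category members taking each day-B category (row-normalized transition
#' fractions), e.g. the fraction of RR cells that remain RR.
#'
#' @param labels_dayA,labels_dayB character vectors of categories, indexed
#'   by each day's neuron ids.
#' @param matching data.frame from [match_rois_across_days()] (columns
#'   `roi_day1`, `roi_day2`).
#' @return matrix of fractions (rows = day-A categories, columns = day-B
#'   categories); empty matrix with attribute `empty = TRUE` when no cells
#'   are matched.
#' @export
recruitment_table <- function(labels_dayA, labels_dayB, matching) {
  if (nrow(matching) == 0L) {
    out <- matrix(numeric(0), 0, 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  a <- labels_dayA[matching$roi_day1]
  b <- labels_dayB[matching$roi_day2]
  tab <- table(dayA = a, dayB = b)
  frac <- sweep(tab, 1L, pmax(rowSums(tab), 1L), "/")
  out <- unclass(as.matrix(frac))
  attr(out, "empty") <- FALSE
  out
}
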