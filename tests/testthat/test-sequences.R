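test_that("noiseless sequences keep their sort order across the switch", {
  s <- small_switch_session()
  gt <- s$ground_truth
  rr <- gt$neuron[gt$class == "RR"]
  seqr <- cross_validated_sequence(s, rr, n_perm = 300)
  # reward-relative population keeps its order: strong positive rho
  expect_gt(seqr$rho, 0.5)
  expect_lt(seqr$p_perm, 0.01)
  expect_equal(seqr$n_cells, length(rr))
  # sort order is the odd-pre peak order
  A <- population_tensor(s, "dff")
  odd <- seq(1, 30, by = 2)
  pks <- vapply(seqr$order, function(i) spatial_peak(A[odd, , i]), numeric(1))
  expect_true(all(diff(pks) >= 0))
  expect_error(cross_validated_sequence(s, rr[1]), "2 neurons")
  low <- cross_validated_sequence(s, rr[1:3])
  expect_true(low$low_n)
  expect_true(is.na(low$rho))
})

test_that("RR sequences shift in track space but align in reward space", {
  s <- small_switch_session()
  gt <- s$ground_truth
  rr <- gt$neuron[gt$class == "RR"]
  seqr <- cross_validated_sequence(s, rr, n_perm = 50)
  shift <- to_periodic(200) - to_periodic(80)   # zone A -> B phase shift
  d <- wrap_pi(seqr$positions_after - seqr$positions_before - shift)
  # after-positions sit near before + zone shift (within ~2 bins for most)
  expect_gt(mean(abs(d) < 2 * 2 * pi / 45), 0.7)
})

test_that("permutation P matches the exhaustive enumeration on 3 cells", {
  a <- c(-2, 0.5, 2.2)
  b <- c(-1.8, 0.8, 2.0)
  obs <- circ_circ_corr(a, b)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  rhos <- vapply(perms, function(p) circ_circ_corr(a, b[p]), numeric(1))
  p_hand <- (sum(abs(rhos) >= abs(obs)) + 1) / (length(perms) + 1)
  expect_equal(sequence_permutation_test(a, b, exhaustive = TRUE), p_hand)
  expect_equal(p_hand, 3 / 7)
  # sampled estimator converges to the enumeration on 4 cells
  set.seed(2)
  a4 <- c(-2, -0.5, 0.5, 2.2)
  b4 <- c(-1.8, 0.8, -0.6, 2.0)
  p_ex <- sequence_permutation_test(a4, b4, exhaustive = TRUE)
  p_mc <- sequence_permutation_test(a4, b4, n_perm = 4000)
  expect_lt(abs(p_mc - p_ex), 0.05)
})

test_that("permutation P floor is 1/(N+1)", {
  set.seed(6)
  a <- sort(runif(30, -pi, pi))
  p <- sequence_permutation_test(a, a, n_perm = 1000)
  expect_equal(p, 1 / 1001)
  expect_lt(p, 0.001)
})

test_that("shuffled labels give approximately uniform P values", {
  set.seed(9)
  a <- runif(15, -pi, pi)
  ps <- replicate(60, sequence_permutation_test(a, sample(a), n_perm = 60))
  expect_gt(mean(ps > 0.2), 0.5)
  # jitter breaks the discreteness ties of the permutation P support
  expect_gt(ks.test(ps + runif(60, 0, 1e-6), "punif")$p.value, 0.001)
})

test_that("sequence density and circular variance behave at the limits", {
  pk <- rep(0.1, 20)
  d <- sequence_density(pk, n_place_cells = 40)
  expect_equal(sum(d > 0), 1)
  expect_equal(max(d), 0.5)
  expect_equal(circ_var(pk), 0)
  set.seed(10)
  u <- runif(5000, -pi, pi)
  du <- sequence_density(u, n_place_cells = 5000)
  expect_lt(max(abs(du - 1 / 45)), 0.01)
  expect_gt(circ_var(u), 0.97)
})

test_that("ROI matching reproduces the hand-computed IoU table", {
  # three overlapping toy masks on a 10x10 grid
  m1 <- list(1:20, 41:60, 81:90)
  m2 <- list(11:30, 45:64, integer(0))
  iou <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_equal(iou(m1[[1]], m2[[1]]), 10 / 30)
  match <- match_rois_across_days(m1, m2)
  expect_equal(nrow(match), 2)
  expect_equal(match$roi_day2[match$roi_day1 == 1], 1)
  expect_equal(match$iou[match$roi_day1 == 2], iou(m1[[2]], m2[[2]]))
  # identical masks match at IoU 1; disjoint masks never match
  ident <- match_rois_across_days(list(1:5, 10:14), list(1:5, 10:14))
  expect_equal(ident$iou, c(1, 1))
  expect_equal(nrow(match_rois_across_days(list(1:5), list(6:9))), 0)
})

test_that("recruitment fractions are diagonal for identical labels", {
  labs <- c("RR", "TR", "RR", "nonplace")
  matching <- data.frame(roi_day1 = 1:4, roi_day2 = 1:4)
  tab <- recruitment_table(labs, labs, matching)
  expect_equal(unname(diag(tab[c("RR", "TR", "nonplace"),
                               c("RR", "TR", "nonplace")])), c(1, 1, 1))
  empty <- recruitment_table(labs, labs,
                             data.frame(roi_day1 = integer(0),
                                        roi_day2 = integer(0)))
  expect_true(attr(empty, "empty"))
})

test_that("simulated RR retention is recovered within binomial error", {
  set.seed(20)
  n <- 300
  labsA <- rep("RR", n)
  retain <- 0.3
  labsB <- ifelse(runif(n) < retain, "RR", "TR")
  tab <- recruitment_table(labsA, labsB, data.frame(roi_day1 = 1:n,
                                                    roi_day2 = 1:n))
  se <- sqrt(retain * (1 - retain) / n)
  expect_lt(abs(tab["RR", "RR"] - retain), 3 * se)
})
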