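#' Periodic track coordinates
#'
#' The 450-cm track is treated as a circle: 0 cm maps to -pi and the track
#' end (450 cm) wraps back to -pi, so phases live in [-pi, pi). Reward-zone
#' alignment is a wrapped subtraction that puts the zone start at phase 0.
#'
#' @param position_cm numeric vector of track positions in cm.
#' @param track_length_cm track length (default 450).
#' @return phases in radians, in [-pi, pi).
#' @export
#' @examples
#' to_periodic(c(0, 225, 450))   # -pi, 0, -pi (450 wraps)
to_periodic <- function(position_cm, track_length_cm = 450) {
  wrap_pi(position_cm / track_length_cm * 2 * pi - pi)
}

#' @rdname to_periodic
#' @param phase phases in radians.
#' @export
from_periodic <- function(phase, track_length_cm = 450) {
  (wrap_pi(phase) + pi) / (2 * pi) * track_length_cm
}

#' @rdname to_periodic
#' @param zone_start_phase phase of the active reward-zone start.
#' @export
align_to_reward <- function(phase, zone_start_phase) {
  wrap_pi(phase - zone_start_phase)
}

#' Wrap angles into [-pi, pi)
#' @param x angles in radians.
#' @export
wrap_pi <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Circular distance in cm between two track positions
#' @param a,b positions in cm.
#' @param track_length_cm track length.
#' @return absolute wrapped distance in cm, in [0, track_length/2].
#' @export
circ_dist_cm <- function(a, b, track_length_cm = 450) {
  d <- abs(a - b) %% track_length_cm
  pmin(d, track_length_cm - d)
}

#' Circular mean of phases
#' @param x phases in radians; NA dropped.
#' @export
circ_mean <- function(x) {
  x <- x[!is.na(x)]
  atan2(mean(sin(x)), mean(cos(x)))
}

#' Circular variance (1 - mean resultant length)
#'
#' Ranges from 0 (all phases identical) to 1 (phases balanced around the
#' circle). For a von Mises sample with concentration kappa the expected
#' value is 1 - I1(kappa)/I0(kappa).
#'
#' @param x phases in radians; NA dropped.
#' @export
circ_var <- function(x) {
  x <- x[!is.na(x)]
  1 - sqrt(mean(sin(x))^2 + mean(cos(x))^2)
}

#' Circular-circular correlation coefficient
#'
#' Jammalamadaka-SenGupta correlation between two samples of angles:
#' rho = sum sin(a - abar) sin(b - bbar) /
#'       sqrt(sum sin^2(a - abar) * sum sin^2(b - bbar)),
#' with abar, bbar the circular means. Used to quantify preservation of
#' sequence order on the circularized track.
#'
#' @param a,b phase vectors in radians, equal length; pairs with NA dropped.
#' @return rho in [-1, 1]; NA if either sample is angularly degenerate.
#' @export
circ_circ_corr <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) return(NA_real_)
  sa <- sin(a - circ_mean(a))
  sb <- sin(b - circ_mean(b))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(NA_real_)
  sum(sa * sb) / den
}
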