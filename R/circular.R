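## Circular statistics for torsion angles. Needed because the compared
## angles sit near the 0/360 wrap; resultant-vector definitions throughout.

#' Circular mean of angles
#'
#' @param theta Angles in degrees.
#' @param na.rm Drop NA values.
#' @return Mean direction in degrees in [0, 360); NA for an empty or
#'   zero-resultant sample.
#' @export
circularMean <- function(theta, na.rm = TRUE) {
  if (na.rm) theta <- theta[!is.na(theta)]
  if (!length(theta)) return(NA_real_)
  s <- mean(sin(theta / DEG)); c <- mean(cos(theta / DEG))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap360(atan2(s, c) * DEG)
}

#' Circular standard deviation of angles
#'
#' sd = sqrt(-2 log Rbar) (in radians, reported in degrees), where Rbar is
#' the mean resultant length.
#'
#' @param theta Angles in degrees.
#' @param na.rm Drop NA values.
#' @return Circular sd in degrees; 0 for a single observation.
#' @export
circularSd <- function(theta, na.rm = TRUE) {
  if (na.rm) theta <- theta[!is.na(theta)]
  if (!length(theta)) return(NA_real_)
  s <- mean(sin(theta / DEG)); c <- mean(cos(theta / DEG))
  R <- min(1, sqrt(s^2 + c^2))
  if (R < 1e-12) return(Inf)
  sqrt(-2 * log(R)) * DEG
}

#' Absolute circular difference between two angles
#'
#' min(|a - b| mod 360, 360 - |a - b| mod 360): symmetric, bounded in
#' [0, 180], zero iff the angles agree modulo 360.
#'
#' @param a,b Angles in degrees (vectorized).
#' @return Absolute circular difference in degrees.
#' @export
circularDiff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}
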