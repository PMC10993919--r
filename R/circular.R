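#' Circular standard deviation of axial angles
#'
#' Azimuths carry a 180-degree (pi) ambiguity, so the angles are doubled
#' before any circular statistic: each azimuth alpha maps to the unit
#' vector exp(2i * alpha). The mean resultant vector is
#' rbar = (1/N) * sum(exp(2i * alpha_n)), its length R = |rbar|, and the
#' circular standard deviation of the doubled angles is sqrt(-2 ln R).
#' Dividing by 2 maps the result back to the azimuth scale.
#'
#' For a wrapped normal population with spread sigma the estimator is
#' consistent: R converges to exp(-2 sigma^2) and s0 to sigma.
#'
#' @param azimuthDeg numeric vector of axial angles in degrees; NA values
#'   are dropped.
#' @return the circular standard deviation s0 in degrees; \code{Inf} when
#'   the doubled angles cancel exactly (R = 0, perfectly dispersed, with a
#'   warning); \code{NA} when fewer than 2 defined angles remain.
#' @examples
#' axialCircularSD(rep(30, 10))              # 0
#' axialCircularSD(c(0, 90))                 # Inf: axial antipodes
#' @export
axialCircularSD <- function(azimuthDeg) {
  a <- azimuthDeg[!is.na(azimuthDeg)]
  if (length(a) < 2L) return(NA_real_)
  doubled <- 2 * a * pi / 180
  rbar <- mean(complex(modulus = 1, argument = doubled))
  R <- Mod(rbar)
  if (R <= .Machine$double.eps) {
    warning("mean resultant vector has length 0; circular SD is infinite")
    return(Inf)
  }
  # floating point can leave R marginally above 1 for identical angles
  R <- min(R, 1)
  sqrt(-2 * log(R)) / 2 * 180 / pi
}

#' Axial circular mean
#'
#' Mean direction of axial angles via the doubled-angle transform; the
#' result is reported on (-90, +90] degrees.
#'
#' @param azimuthDeg numeric vector of axial angles in degrees; NA dropped.
#' @return mean axial angle in degrees, or NA if no defined angles (or the
#'   resultant vanishes).
#' @export
axialCircularMean <- function(azimuthDeg) {
  a <- azimuthDeg[!is.na(azimuthDeg)]
  if (!length(a)) return(NA_real_)
  rbar <- mean(complex(modulus = 1, argument = 2 * a * pi / 180))
  if (Mod(rbar) <= .Machine$double.eps) return(NA_real_)
  m <- Arg(rbar) / 2 * 180 / pi
  if (m <= -90) m + 180 else m
}
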