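#' Calibration transform between chronological age and the clock scale
#'
#' The epigenetic clock is linear not in years but in a calibrated age scale
#' that ticks fast during development and settles to a constant rate in
#' adulthood.  For ages at or below the adult knot the transform is
#' logarithmic, \eqn{F(a) = \log(a + 1) - \log(adult\_age + 1)}; above the
#' knot it is linear, \eqn{F(a) = (a - adult\_age)/(adult\_age + 1)}.  With
#' the natural logarithm the two branches meet at the knot with equal value
#' (zero) and equal derivative \eqn{1/(adult\_age + 1)}, so \eqn{F} is
#' continuous, strictly increasing and C1.
#'
#' @param age Numeric vector of chronological ages in years; all values must
#'   be finite and non-negative (0 is allowed, e.g. cord blood from
#'   newborns).
#' @param adult_age The knot, in years, at which the tick rate becomes
#'   constant.  Default 20.
#' @return Numeric vector of transformed ages (dimensionless clock-scale
#'   units).  \code{transform_age(adult_age) == 0}.
#' @seealso [inverse_transform_age()]
#' @examples
#' transform_age(c(0, 20, 41))        # -log(21), 0, 1
#' inverse_transform_age(transform_age(65))
#' @export
transform_age <- function(age, adult_age = 20) {
  check_adult_age(adult_age)
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0)) {
    domain_error("'age' must be finite and >= 0 years")
  }
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' Inverse calibration transform (clock scale to years)
#'
#' Exact inverse of [transform_age()]: ages are recovered as
#' \eqn{\exp(x + \log(adult\_age + 1)) - 1} for \eqn{x \le 0} and
#' \eqn{x (adult\_age + 1) + adult\_age} for \eqn{x > 0}.  No clipping is
#' applied, so a sufficiently large linear score maps beyond any human
#' lifespan; this is intentional (cancer samples can show extreme
#' DNAm-age acceleration).
#'
#' @param x Numeric vector on the transformed (clock) scale; must be finite.
#' @inheritParams transform_age
#' @return Ages in years (possibly negative for scores below the
#'   transform of age zero, never below -1).
#' @export
inverse_transform_age <- function(x, adult_age = 20) {
  check_adult_age(adult_age)
  if (!is.numeric(x) || any(!is.finite(x))) {
    domain_error("'x' must be a finite numeric vector")
  }
  ifelse(x <= 0,
         exp(x + log(adult_age + 1)) - 1,
         x * (adult_age + 1) + adult_age)
}

check_adult_age <- function(adult_age) {
  if (!is_scalar_number(adult_age) || adult_age <= 0) {
    domain_error("'adult_age' must be a single finite value > 0")
  }
  invisible(adult_age)
}
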