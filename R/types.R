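#' Body model parameters
#'
#' Describes the person as a homogeneous two-segment rigid rod ("cranked
#' rod"): total standing body length, mass, and the fractional positions of
#' each segment's centre of gravity along its length, measured from the
#' segment's proximal end (the feet for the lower segment, the rail pivot
#' for the upper one).  With a homogeneous mass distribution both fractions
#' are 0.5.
#'
#' @param total_length Total body length L in metres.
#' @param mass Body mass in kilograms.
#' @param cog_lower Centre-of-gravity scaling factor `a` of the lower
#'   segment, in (0, 1).
#' @param cog_upper Centre-of-gravity scaling factor `b` of the upper
#'   segment, in (0, 1).
#' @param gravity Gravitational acceleration in m/s^2.  Enters only the
#'   reported force magnitudes; the slip and tilt thresholds depend on
#'   weight ratios and cancel it.
#' @return An object of class `railfall_anthropometry`.
#' @examples
#' anthropometry(1.58, 65)
#' @export
anthropometry <- function(total_length, mass, cog_lower = 0.5,
                          cog_upper = 0.5, gravity = 9.81) {
  stopifnot(
    is.numeric(total_length), length(total_length) == 1L, total_length > 0,
    is.numeric(mass), length(mass) == 1L, mass > 0,
    is.numeric(cog_lower), length(cog_lower) == 1L,
    cog_lower > 0, cog_lower < 1,
    is.numeric(cog_upper), length(cog_upper) == 1L,
    cog_upper > 0, cog_upper < 1,
    is.numeric(gravity), length(gravity) == 1L, gravity > 0
  )
  structure(
    list(total_length = total_length, mass = mass,
         cog_lower = cog_lower, cog_upper = cog_upper, gravity = gravity),
    class = "railfall_anthropometry"
  )
}

#' Railing environment
#'
#' @param height Railing (handrail) height Y above the ground, metres.
#'   Must be smaller than the body length of any anthropometry it is
#'   paired with; that pairing is checked where segments are derived.
#' @param mu Static Coulomb friction coefficient between the feet and the
#'   ground (dimensionless, >= 0).
#' @return An object of class `railfall_scenario`.
#' @examples
#' railing_scenario(0.92, mu = 0.7)
#' @export
railing_scenario <- function(height, mu) {
  stopifnot(
    is.numeric(height), length(height) == 1L, height > 0,
    is.numeric(mu), length(mu) == 1L, mu >= 0
  )
  structure(list(height = height, mu = mu), class = "railfall_scenario")
}

#' Body posture at the railing
#'
#' `alpha` is the angle between the (vertical) railing plane and the lower
#' body segment; `beta` is the flexion angle between the lower and upper
#' segments at the rail pivot.  Angles are given in degrees; they are held
#' in radians internally.
#'
#' @param alpha Lean angle in degrees, 0 <= alpha < 90.
#' @param beta Flexion angle in degrees, 0 <= beta <= 180 - alpha (the
#'   upper segment is not folded back through the lower one).
#' @return An object of class `railfall_posture` with radian fields
#'   `alpha`, `beta` and degree fields `alpha_deg`, `beta_deg`.
#' @examples
#' posture(alpha = 10, beta = 80)
#' @export
posture <- function(alpha, beta) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha < 90,
    is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 180 - alpha
  )
  structure(
    list(alpha = deg2rad(alpha), beta = deg2rad(beta),
         alpha_deg = alpha, beta_deg = beta),
    class = "railfall_posture"
  )
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @export
print.railfall_anthropometry <- function(x, ...) {
  cat(sprintf(
    "Cranked-rod anthropometry: L = %.3f m, m = %.1f kg, a = %.2f, b = %.2f, g = %.2f m/s^2\n",
    x$total_length, x$mass, x$cog_lower, x$cog_upper, x$gravity))
  invisible(x)
}

#' @export
print.railfall_scenario <- function(x, ...) {
  cat(sprintf("Railing scenario: height Y = %.3f m, friction mu = %.2f\n",
              x$height, x$mu))
  invisible(x)
}

#' @export
print.railfall_posture <- function(x, ...) {
  cat(sprintf("Posture: alpha = %.2f deg, beta = %.2f deg\n",
              x$alpha_deg, x$beta_deg))
  invisible(x)
}
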