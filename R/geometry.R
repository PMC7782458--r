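#' Segment lengths from body length, railing height and lean angle
#'
#' The rail contact point divides the body at height Y along the lower
#' segment, so the lower segment has length L1 = Y / cos(alpha) and the
#' upper one L2 = L - L1.  The geometry degenerates (no body left above
#' the rail) once alpha reaches arccos(Y / L); this is signalled through
#' the `valid` flag, never an error, so that region scans stay total.
#'
#' @param anthro A [anthropometry()] object.
#' @param scenario A [railing_scenario()] object.
#' @param alpha Lean angle in degrees, 0 <= alpha < 90.
#' @return An object of class `railfall_segments` with fields
#'   `lower_length`, `upper_length`, `valid`, `pivot_fraction` (L1 / L)
#'   and `alpha` (radians).
#' @examples
#' a <- anthropometry(1.58, 65)
#' s <- railing_scenario(0.92, 0.2)
#' derive_segments(a, s, alpha = 10)
#' @export
derive_segments <- function(anthro, scenario, alpha) {
  stopifnot(inherits(anthro, "railfall_anthropometry"),
            inherits(scenario, "railfall_scenario"),
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha < 90)
  if (scenario$height >= anthro$total_length)
    stop("railing height must be below total body length")
  al <- deg2rad(alpha)
  L1 <- scenario$height / cos(al)
  L2 <- anthro$total_length - L1
  structure(
    list(lower_length = L1, upper_length = L2, valid = L2 > 0,
         pivot_fraction = L1 / anthro$total_length, alpha = al),
    class = "railfall_segments"
  )
}

#' Segment weight forces under the homogeneous split
#'
#' A homogeneous rod carries weight in proportion to length, so the
#' segment weights are G_i = m g L_i / L, recomputed for every lean angle
#' because the segment lengths themselves depend on alpha.
#'
#' @param anthro A [anthropometry()] object.
#' @param geom A valid [derive_segments()] result.
#' @return An object of class `railfall_weights` with `lower_weight` (G1)
#'   and `upper_weight` (G2), newtons.
#' @export
split_weights <- function(anthro, geom) {
  stopifnot(inherits(anthro, "railfall_anthropometry"),
            inherits(geom, "railfall_segments"))
  if (!geom$valid)
    stop("invalid geometry: lower segment reaches past the whole body")
  mg <- anthro$mass * anthro$gravity
  structure(
    list(lower_weight = mg * geom$lower_length / anthro$total_length,
         upper_weight = mg * geom$upper_length / anthro$total_length),
    class = "railfall_weights"
  )
}

#' Anatomical applicability warnings
#'
#' The rod model presumes the rail pivot sits near the lower abdominal /
#' pelvic region, where the trunk can actually flex, and that the feet
#' keep ground contact.  Two screening warnings flag configurations where
#' that breaks down: a pivot fraction L1/L above `pivot_fraction_warn`
#' puts the pivot in the thoracic region (no joint to flex around), and a
#' lean angle above `alpha_warn` is typically only realisable with the
#' feet off the ground.  Values exactly at a threshold count as
#' plausible.  Warnings never block computation.
#'
#' @param geom A [derive_segments()] result.
#' @param posture A [posture()] object (only alpha is inspected).
#' @param pivot_fraction_warn Threshold on L1 / L (default 0.65).
#' @param alpha_warn Threshold on alpha in degrees (default 30).
#' @return Character vector of zero or more codes among
#'   `"PIVOT_ABOVE_ABDOMEN"` and `"LARGE_ALPHA"`.
#' @export
anatomical_plausibility <- function(geom, posture,
                                    pivot_fraction_warn = 0.65,
                                    alpha_warn = 30) {
  stopifnot(inherits(geom, "railfall_segments"),
            inherits(posture, "railfall_posture"))
  out <- character(0)
  if (geom$pivot_fraction > pivot_fraction_warn)
    out <- c(out, "PIVOT_ABOVE_ABDOMEN")
  if (posture$alpha_deg > alpha_warn)
    out <- c(out, "LARGE_ALPHA")
  out
}

#' @export
print.railfall_segments <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(
      "Segments: L1 = %.4f m, L2 = %.4f m (pivot fraction %.3f, alpha = %.2f deg)\n",
      x$lower_length, x$upper_length, x$pivot_fraction, rad2deg(x$alpha)))
  } else {
    cat(sprintf(
      "Segments: invalid geometry at alpha = %.2f deg (Y/cos(alpha) >= L)\n",
      rad2deg(x$alpha)))
  }
  invisible(x)
}

#' @export
print.railfall_weights <- function(x, ...) {
  cat(sprintf("Segment weights: G1 = %.1f N, G2 = %.1f N\n",
              x$lower_weight, x$upper_weight))
  invisible(x)
}
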