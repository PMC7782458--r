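#' Planar cross product
#'
#' Scalar cross product of two 2-vectors, `(x, y) x (u, v) = x v - y u`,
#' used throughout as moment = lever x force.
#'
#' @param u,v Numeric 2-vectors.
#' @return A scalar.
#' @examples
#' cross2d(c(1, 0), c(0, 1))  # 1
#' @export
cross2d <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Planar configuration of the cranked rod
#'
#' Places the model in the plane: the feet contact point A at the origin,
#' x horizontal toward the railing, y up.  The lower segment runs from A
#' at angle alpha to the vertical, so the rail pivot B lands exactly at
#' railing height; the upper segment continues at angle alpha + beta.
#' Segment centres of gravity sit at fractions a and b along their
#' segments.
#'
#' @param anthro A [anthropometry()] object.
#' @param scenario A [railing_scenario()] object.
#' @param posture A [posture()] object.
#' @return An object of class `railfall_configuration` with 2-vector
#'   fields `point_A`, `point_B`, `point_C`, `lower_vector`,
#'   `upper_vector`, `cog_1`, `cog_2`.
#' @export
build_configuration <- function(anthro, scenario, posture) {
  geom <- derive_segments(anthro, scenario, posture$alpha_deg)
  if (!geom$valid) stop("invalid geometry")
  al <- posture$alpha; ab <- posture$alpha + posture$beta
  l1 <- geom$lower_length * c(sin(al), cos(al))
  l2 <- geom$upper_length * c(sin(ab), cos(ab))
  A <- c(0, 0)
  structure(
    list(point_A = A, point_B = A + l1, point_C = A + l1 + l2,
         lower_vector = l1, upper_vector = l2,
         cog_1 = A + anthro$cog_lower * l1,
         cog_2 = A + l1 + anthro$cog_upper * l2),
    class = "railfall_configuration"
  )
}

#' Numerical solution of the planar equilibrium
#'
#' Solves the force and moment balance of the leaning body as a 3x3
#' linear system, independently of the closed-form expressions, and is
#' used to certify them.  Unknowns are the vertical ground reaction and
#' horizontal friction force at the feet and the magnitude of the bearing
#' force at the rail pivot, which is taken perpendicular to the lower
#' segment (frictionless rail contact).  The solution reports signed
#' force vectors, each weight decomposed into segment-orthogonal and
#' segment-collinear components, and the residuals of the force balance
#' and of the moment balances about the feet (A) and the pivot (B) --
#' the moment equation about B is redundant given the other equations,
#' so its residual is a genuine consistency check.
#'
#' @param config A [build_configuration()] result.
#' @param weights A [split_weights()] result.
#' @return An object of class `railfall_equilibrium` with fields
#'   `grf_vector`, `friction_vector`, `bearing_vector`, `weight_components`
#'   (list with `orthogonal_1`, `collinear_1`, `orthogonal_2`,
#'   `collinear_2`) and `residuals` (`force`, `moment_A`, `moment_B`).
#' @export
solve_equilibrium <- function(config, weights) {
  stopifnot(inherits(config, "railfall_configuration"),
            inherits(weights, "railfall_weights"))
  G1 <- c(0, -weights$lower_weight)
  G2 <- c(0, -weights$upper_weight)
  l1 <- config$lower_vector
  L1 <- sqrt(sum(l1^2))
  n <- c(l1[2], -l1[1]) / L1  # unit normal of the lower segment
  # unknowns x = (R, Fx, h): GRF = (0, R), F = (Fx, 0), H = h * n
  # rows: force-x, force-y, moment about A
  M <- rbind(c(0, 1, n[1]),
             c(1, 0, n[2]),
             c(0, 0, cross2d(l1, n)))
  rhs <- c(-G1[1] - G2[1],
           -G1[2] - G2[2],
           -cross2d(config$cog_1 - config$point_A, G1) -
             cross2d(config$cog_2 - config$point_A, G2))
  x <- solve(M, rhs)
  grf <- c(0, x[1]); fr <- c(x[2], 0); H <- x[3] * n
  t1 <- l1 / L1
  l2 <- config$upper_vector
  t2 <- l2 / sqrt(sum(l2^2))
  pts <- rbind(config$cog_1, config$cog_2, config$point_A,
               config$point_A, config$point_B)
  fs <- rbind(G1, G2, grf, fr, H)
  structure(
    list(grf_vector = grf, friction_vector = fr, bearing_vector = H,
         weight_components = list(
           collinear_1 = sum(G1 * t1) * t1,
           orthogonal_1 = G1 - sum(G1 * t1) * t1,
           collinear_2 = sum(G2 * t2) * t2,
           orthogonal_2 = G2 - sum(G2 * t2) * t2),
         residuals = list(
           force = sqrt(sum((colSums(fs))^2)),
           moment_A = moment_about(config$point_A, pts, fs),
           moment_B = moment_about(config$point_B, pts, fs)),
         points = pts, forces = fs),
    class = "railfall_equilibrium"
  )
}

#' Net moment of a force set about a point
#'
#' @param point Numeric 2-vector, the reference point.
#' @param points Matrix with one application point per row.
#' @param forces Matrix with the matching force vector per row.
#' @return Scalar net moment (N m), counterclockwise positive.
#' @export
moment_about <- function(point, points, forces) {
  stopifnot(nrow(points) == nrow(forces))
  s <- 0
  for (i in seq_len(nrow(points)))
    s <- s + cross2d(points[i, ] - point, forces[i, ])
  s
}

#' @export
print.railfall_equilibrium <- function(x, ...) {
  cat(sprintf(
    "Equilibrium solution: GRF = %.2f N, F = %.2f N, |H| = %.2f N\n",
    x$grf_vector[2], x$friction_vector[1],
    sqrt(sum(x$bearing_vector^2))))
  cat(sprintf("  residuals: force %.2e N, moment about A %.2e, about B %.2e N m\n",
              x$residuals$force, abs(x$residuals$moment_A),
              abs(x$residuals$moment_B)))
  invisible(x)
}
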