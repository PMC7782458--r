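#' Ground reaction force at the feet
#'
#' Closed-form vertical ground reaction at the feet for a cranked rod
#' leaning on a railing:
#' \deqn{GRF = G_1 (1 - a \sin^2\alpha) + G_2 (\cos^2\alpha -
#'   b \frac{L_2}{L_1} \sin\alpha \sin(\alpha + \beta))}
#' The value can become negative for extreme postures (the model then
#' needs the feet to pull on the ground); downstream classification flags
#' that case rather than rejecting it.
#'
#' @param anthro A [anthropometry()] object.
#' @param geom A valid [derive_segments()] result.
#' @param posture A [posture()] object.
#' @return Ground reaction force in newtons.
#' @export
ground_reaction <- function(anthro, geom, posture) {
  stopifnot(inherits(posture, "railfall_posture"))
  if (!geom$valid) stop("invalid geometry")
  w <- split_weights(anthro, geom)
  grf_closed_form(w$lower_weight, w$upper_weight,
                  geom$lower_length, geom$upper_length,
                  anthro$cog_lower, anthro$cog_upper,
                  geom$alpha, posture$beta)
}

#' Friction demand at the feet
#'
#' Closed-form horizontal force the feet must transmit for equilibrium:
#' \deqn{F = (a G_1 \sin\alpha + G_2 \sin\alpha +
#'   b G_2 \frac{L_2}{L_1} \sin(\alpha + \beta)) \cos\alpha}
#' It is non-negative throughout the admissible posture domain.
#'
#' @inheritParams ground_reaction
#' @return Friction demand in newtons.
#' @export
friction_demand <- function(anthro, geom, posture) {
  stopifnot(inherits(posture, "railfall_posture"))
  if (!geom$valid) stop("invalid geometry")
  w <- split_weights(anthro, geom)
  friction_closed_form(w$lower_weight, w$upper_weight,
                       geom$lower_length, geom$upper_length,
                       anthro$cog_lower, anthro$cog_upper,
                       geom$alpha, posture$beta)
}

# vectorised over beta (radians)
grf_closed_form <- function(G1, G2, L1, L2, a, b, alpha, beta) {
  G1 * (1 - a * sin(alpha)^2) +
    G2 * (cos(alpha)^2 - b * (L2 / L1) * sin(alpha) * sin(alpha + beta))
}

friction_closed_form <- function(G1, G2, L1, L2, a, b, alpha, beta) {
  (a * G1 * sin(alpha) + G2 * sin(alpha) +
     b * G2 * (L2 / L1) * sin(alpha + beta)) * cos(alpha)
}

#' Ground reaction and friction demand for a full parameter set
#'
#' Convenience wrapper deriving segments and weights internally.
#'
#' @param anthro A [anthropometry()] object.
#' @param scenario A [railing_scenario()] object.
#' @param posture A [posture()] object.
#' @return An object of class `railfall_force_demand` with fields
#'   `ground_reaction` and `friction_demand` (newtons).
#' @examples
#' force_demand(anthropometry(1.58, 65), railing_scenario(0.92, 0.2),
#'              posture(10, 80))
#' @export
force_demand <- function(anthro, scenario, posture) {
  geom <- derive_segments(anthro, scenario, posture$alpha_deg)
  structure(
    list(ground_reaction = ground_reaction(anthro, geom, posture),
         friction_demand = friction_demand(anthro, geom, posture)),
    class = "railfall_force_demand"
  )
}

#' @export
print.railfall_force_demand <- function(x, ...) {
  cat(sprintf("Force demand: GRF = %.1f N, F = %.1f N\n",
              x$ground_reaction, x$friction_demand))
  invisible(x)
}

#' Anti-slip condition
#'
#' The feet hold as long as the friction demand does not exceed the
#' Coulomb capacity: F <= mu * GRF.  Equality counts as holding.
#'
#' @param demand A [force_demand()] object (or any list with
#'   `ground_reaction` and `friction_demand`).
#' @param mu Static friction coefficient.
#' @return `TRUE` if the anti-slip condition holds.
#' @export
anti_slip_holds <- function(demand, mu) {
  demand$friction_demand <= mu * demand$ground_reaction
}

#' Anti-tilt condition
#'
#' The posture does not tip over the rail as long as
#' \deqn{G_2\, b\, L_2 \sin(\alpha + \beta) \le
#'   L_1 (a G_1 + G_2) \sin\alpha,}
#' the primitive inequality behind the arcsin-form tilt threshold.
#' Equality counts as holding; the condition does not involve the
#' friction coefficient.
#'
#' @inheritParams ground_reaction
#' @return `TRUE` if the anti-tilt condition holds.
#' @export
anti_tilt_holds <- function(anthro, geom, posture) {
  stopifnot(inherits(posture, "railfall_posture"))
  if (!geom$valid) stop("invalid geometry")
  w <- split_weights(anthro, geom)
  tilt_margin(w$lower_weight, w$upper_weight,
              geom$lower_length, geom$upper_length,
              anthro$cog_lower, anthro$cog_upper,
              geom$alpha, posture$beta) >= 0
}

# Tilt margin in N*m: >= 0 iff anti-tilt holds.  Vectorised over beta.
tilt_margin <- function(G1, G2, L1, L2, a, b, alpha, beta) {
  L1 * (a * G1 + G2) * sin(alpha) - G2 * b * L2 * sin(alpha + beta)
}

# Slip margin in N: mu*GRF - F, >= 0 iff anti-slip holds.  Vectorised.
slip_margin <- function(G1, G2, L1, L2, a, b, alpha, beta, mu) {
  mu * grf_closed_form(G1, G2, L1, L2, a, b, alpha, beta) -
    friction_closed_form(G1, G2, L1, L2, a, b, alpha, beta)
}

#' Both arcsin branches of a threshold angle
#'
#' The slip and tilt thresholds solve equations of the form
#' sin(beta + alpha) = s; for every first-branch solution beta1 there is a
#' supplementary second branch beta2 = 180 - beta1 - 2 alpha with the same
#' sine of (beta + alpha).  Instability intervals run between the two.
#'
#' @param beta1 First-branch angle in degrees.
#' @param alpha Lean angle in degrees.
#' @return List with `beta_1` and `beta_2` (degrees).
#' @examples
#' arcsin_branch_pair(50, 10)  # beta_2 = 110
#' @export
arcsin_branch_pair <- function(beta1, alpha) {
  list(beta_1 = beta1, beta_2 = 180 - beta1 - 2 * alpha)
}

# ---- condition-interval machinery ------------------------------------

# Locate {beta : margin(beta) < 0} within dom (radians) by a coarse scan
# plus bisection refinement of each sign change.  margin must be
# vectorised.  Returns a 2-column matrix of (lo, hi) in radians; zero
# rows means the condition holds everywhere.
find_violation_intervals <- function(margin, dom, n_scan = 200,
                                     tol = 1e-8) {
  grid <- seq(dom[1], dom[2], length.out = n_scan + 1)
  viol <- margin(grid) < 0
  if (!any(viol)) return(matrix(numeric(0), ncol = 2))
  r <- rle(viol)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- NULL
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    lo <- if (i0 == 1L) dom[1] else
      bisect_root(margin, grid[i0 - 1L], grid[i0], tol)
    hi <- if (i1 == length(grid)) dom[2] else
      bisect_root(margin, grid[i1], grid[i1 + 1L], tol)
    out <- rbind(out, c(lo, hi))
  }
  out
}

# Bisection for the sign change of f between a (f >= 0) and b (f < 0),
# in either order; converges to tol on the abscissa.
bisect_root <- function(f, a, b, tol = 1e-8) {
  fa <- f(a)
  while (abs(b - a) > tol) {
    m <- (a + b) / 2
    fm <- f(m)
    if ((fa >= 0) == (fm >= 0)) { a <- m; fa <- fm } else b <- m
  }
  (a + b) / 2
}

new_condition_interval <- function(kind, mat_rad, dom_rad) {
  status <- if (nrow(mat_rad) == 0L) "empty"
  else if (nrow(mat_rad) == 1L &&
           mat_rad[1, 1] <= dom_rad[1] + 1e-12 &&
           mat_rad[1, 2] >= dom_rad[2] - 1e-12) "all"
  else "interval"
  structure(
    list(kind = kind, status = status,
         intervals = matrix(rad2deg(mat_rad), ncol = 2),
         beta_domain = rad2deg(dom_rad)),
    class = "railfall_interval"
  )
}

#' @export
print.railfall_interval <- function(x, ...) {
  lab <- switch(x$status,
    empty = "condition never fulfilled in the beta domain",
    all = "condition fulfilled throughout the beta domain",
    paste(apply(x$intervals, 1, function(r)
      sprintf("(%.2f, %.2f) deg", r[1], r[2])), collapse = " U "))
  cat(sprintf("%s condition over beta in [%g, %g] deg: %s\n",
              x$kind, x$beta_domain[1], x$beta_domain[2], lab))
  invisible(x)
}

condition_context <- function(anthro, scenario, alpha) {
  geom <- derive_segments(anthro, scenario, alpha)
  if (!geom$valid)
    stop(sprintf("invalid geometry at alpha = %g deg", alpha))
  w <- split_weights(anthro, geom)
  list(G1 = w$lower_weight, G2 = w$upper_weight,
       L1 = geom$lower_length, L2 = geom$upper_length,
       a = anthro$cog_lower, b = anthro$cog_upper,
       alpha = geom$alpha, mu = scenario$mu)
}

#' Beta interval of the slip condition at fixed alpha
#'
#' Scans the primitive slip inequality F > mu * GRF over the beta domain
#' and refines every interval endpoint by bisection (default tolerance
#' 1e-8 rad).  Returns the maximal open interval(s) of beta in which the
#' feet must slip; empty when the anti-slip condition holds throughout.
#'
#' @param anthro A [anthropometry()] object.
#' @param scenario A [railing_scenario()] object.
#' @param alpha Lean angle in degrees.
#' @param beta_domain Length-2 numeric, the beta range scanned (degrees).
#' @return A `railfall_interval` object (`kind = "slip"`).
#' @examples
#' slip_beta_interval(anthropometry(1.58, 65), railing_scenario(0.92, 0.2), 10)
#' @export
slip_beta_interval <- function(anthro, scenario, alpha,
                               beta_domain = c(0, 130)) {
  ctx <- condition_context(anthro, scenario, alpha)
  dom <- deg2rad(beta_domain)
  margin <- function(beta)
    slip_margin(ctx$G1, ctx$G2, ctx$L1, ctx$L2, ctx$a, ctx$b,
                ctx$alpha, beta, ctx$mu)
  new_condition_interval("slip", find_violation_intervals(margin, dom), dom)
}

#' Beta interval of the tilt condition at fixed alpha
#'
#' Same scan-plus-bisection machinery applied to the primitive tilt
#' inequality; the result is independent of the friction coefficient.
#'
#' @inheritParams slip_beta_interval
#' @return A `railfall_interval` object (`kind = "tilt"`).
#' @examples
#' tilt_beta_interval(anthropometry(1.58, 65), railing_scenario(0.92, 0.2), 10)
#' @export
tilt_beta_interval <- function(anthro, scenario, alpha,
                               beta_domain = c(0, 130)) {
  ctx <- condition_context(anthro, scenario, alpha)
  dom <- deg2rad(beta_domain)
  margin <- function(beta)
    tilt_margin(ctx$G1, ctx$G2, ctx$L1, ctx$L2, ctx$a, ctx$b,
                ctx$alpha, beta)
  new_condition_interval("tilt", find_violation_intervals(margin, dom), dom)
}

# Closed-form slip endpoints: solves the slip inequality analytically for
# sin(alpha + beta).  Returns list(status, beta1, beta2) in radians
# (unclipped); status "empty" when anti-slip holds for every beta,
# "all" when it fails for every beta in [0, pi - alpha].
slip_closed_form <- function(anthro, scenario, alpha) {
  ctx <- condition_context(anthro, scenario, alpha)
  k <- ctx$b * ctx$G2 * (ctx$L2 / ctx$L1)
  s_thr <- (ctx$mu * ctx$G1 * (1 - ctx$a * sin(ctx$alpha)^2) +
              ctx$mu * ctx$G2 * cos(ctx$alpha)^2 -
              (ctx$a * ctx$G1 + ctx$G2) * sin(ctx$alpha) * cos(ctx$alpha)) /
    (k * (cos(ctx$alpha) + ctx$mu * sin(ctx$alpha)))
  if (s_thr >= 1) return(list(status = "empty"))
  if (s_thr <= -1) return(list(status = "all"))
  b1 <- asin(s_thr) - ctx$alpha
  list(status = "interval", beta1 = b1, beta2 = pi - b1 - 2 * ctx$alpha)
}

# Closed-form tilt endpoints: sin(alpha + beta) threshold from the tilt
# inequality; beta1 = asin(arg) - alpha, beta2 its second arcsin branch.
tilt_closed_form <- function(anthro, scenario, alpha) {
  ctx <- condition_context(anthro, scenario, alpha)
  arg <- ctx$L1 * (ctx$a * ctx$G1 + ctx$G2) * sin(ctx$alpha) /
    (ctx$G2 * ctx$b * ctx$L2)
  if (arg >= 1) return(list(status = "empty"))
  b1 <- asin(arg) - ctx$alpha
  list(status = "interval", beta1 = b1, beta2 = pi - b1 - 2 * ctx$alpha)
}

#' Classify a posture
#'
#' Total classification of one (alpha, beta) posture: degenerate geometry
#' yields `INVALID_GEOMETRY`; otherwise the slip and tilt conditions are
#' evaluated directly and combined into `STABLE`, `SLIP_ONLY`,
#' `TILT_ONLY` or `FALL_POSSIBLE` (both instability conditions fulfilled
#' simultaneously -- the model's criterion for a fall over the railing).
#' A negative ground reaction raises the `grf_negative` flag without
#' changing the algebra, and anatomical plausibility warnings are
#' attached.
#'
#' @inheritParams slip_beta_interval
#' @param posture A [posture()] object.
#' @param pivot_fraction_warn,alpha_warn Passed to
#'   [anatomical_plausibility()].
#' @return An object of class `railfall_class` with fields `class`,
#'   `grf_negative`, `warnings`, and (when geometry is valid)
#'   `ground_reaction`, `friction_demand`.
#' @examples
#' classify_posture(anthropometry(1.58, 65), railing_scenario(0.92, 0.2),
#'                  posture(10, 80))
#' @export
classify_posture <- function(anthro, scenario, posture,
                             pivot_fraction_warn = 0.65, alpha_warn = 30) {
  geom <- derive_segments(anthro, scenario, posture$alpha_deg)
  if (!geom$valid) {
    return(structure(
      list(class = "INVALID_GEOMETRY", grf_negative = FALSE,
           warnings = character(0),
           ground_reaction = NA_real_, friction_demand = NA_real_),
      class = "railfall_class"))
  }
  w <- split_weights(anthro, geom)
  grf <- grf_closed_form(w$lower_weight, w$upper_weight,
                         geom$lower_length, geom$upper_length,
                         anthro$cog_lower, anthro$cog_upper,
                         geom$alpha, posture$beta)
  f <- friction_closed_form(w$lower_weight, w$upper_weight,
                            geom$lower_length, geom$upper_length,
                            anthro$cog_lower, anthro$cog_upper,
                            geom$alpha, posture$beta)
  slip <- f > scenario$mu * grf
  tilt <- tilt_margin(w$lower_weight, w$upper_weight,
                      geom$lower_length, geom$upper_length,
                      anthro$cog_lower, anthro$cog_upper,
                      geom$alpha, posture$beta) < 0
  cls <- if (slip && tilt) "FALL_POSSIBLE"
  else if (slip) "SLIP_ONLY"
  else if (tilt) "TILT_ONLY"
  else "STABLE"
  structure(
    list(class = cls, grf_negative = grf < 0,
         warnings = anatomical_plausibility(geom, posture,
                                            pivot_fraction_warn, alpha_warn),
         ground_reaction = grf, friction_demand = f),
    class = "railfall_class"
  )
}

#' @export
print.railfall_class <- function(x, ...) {
  cat("Posture class:", x$class, "\n")
  if (!is.na(x$ground_reaction))
    cat(sprintf("  GRF = %.1f N, F = %.1f N%s\n", x$ground_reaction,
                x$friction_demand,
                if (x$grf_negative) "  [GRF negative]" else ""))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}
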