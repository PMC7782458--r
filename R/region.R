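# Interval set algebra on 2-column (lower, upper) matrices, degrees.
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(numeric(0), ncol = 2))
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (lo < hi) out <- rbind(out, c(lo, hi))
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

union_intervals <- function(a, b) {
  m <- rbind(a, b)
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    k <- nrow(out)
    if (m[i, 1] <= out[k, 2]) out[k, 2] <- max(out[k, 2], m[i, 2])
    else out <- rbind(out, m[i, ])
  }
  out
}

interval_from_matrix <- function(kind, mat_deg, beta_domain) {
  dom <- deg2rad(beta_domain)
  new_condition_interval(kind, deg2rad(
    matrix(mat_deg, ncol = 2)), dom)
}

#' Beta interval in which a fall over the railing is possible
#'
#' Intersection of the slip and tilt beta-intervals at a fixed lean
#' angle: the postures in which both instability conditions are
#' fulfilled simultaneously, the model's criterion for a fall.
#'
#' @inheritParams slip_beta_interval
#' @return A `railfall_interval` object (`kind = "fall"`).
#' @examples
#' fall_interval(anthropometry(1.58, 65), railing_scenario(0.92, 0.2), 10)
#' @export
fall_interval <- function(anthro, scenario, alpha, beta_domain = c(0, 130)) {
  s <- slip_beta_interval(anthro, scenario, alpha, beta_domain)
  t <- tilt_beta_interval(anthro, scenario, alpha, beta_domain)
  interval_from_matrix("fall", intersect_intervals(s$intervals, t$intervals),
                       beta_domain)
}

#' Beta interval in which at least one instability condition holds
#'
#' Union of the slip and tilt beta-intervals at a fixed lean angle;
#' unlike the intersection it is insensitive to which of the two
#' conditions an interval is attributed to.
#'
#' @inheritParams slip_beta_interval
#' @return A `railfall_interval` object (`kind = "instability"`).
#' @export
instability_union <- function(anthro, scenario, alpha,
                              beta_domain = c(0, 130)) {
  s <- slip_beta_interval(anthro, scenario, alpha, beta_domain)
  t <- tilt_beta_interval(anthro, scenario, alpha, beta_domain)
  interval_from_matrix("instability",
                       union_intervals(s$intervals, t$intervals),
                       beta_domain)
}

#' Map the (alpha, beta) stability region
#'
#' Classifies every cell of a regular (alpha, beta) grid and, for each
#' valid alpha column, locates the analytic slip, tilt and fall
#' beta-intervals by scan plus bisection.  Grid cells and analytic
#' intervals come from the same primitive inequalities, so they agree up
#' to grid resolution; printed endpoints should be taken from the
#' interval table, not the grid.
#'
#' @param anthro A [anthropometry()] object.
#' @param scenario A [railing_scenario()] object.
#' @param alpha_range,beta_range Length-2 numeric ranges in degrees.
#'   `alpha_range` defaults to the full validity range
#'   `[0, arccos(Y / L))`.
#' @param step Grid step in degrees.
#' @return An object of class `railfall_region_map`: a list with `grid`
#'   (data frame `alpha_deg`, `beta_deg`, `class`, `grf_N`, `friction_N`,
#'   `grf_negative`), `intervals` (per-alpha data frame of slip/tilt/fall
#'   endpoints, NA when empty), and the generating parameters.
#' @examples
#' \donttest{
#' m <- scan_region(anthropometry(1.58, 65), railing_scenario(0.92, 0.2))
#' table(m$grid$class)
#' }
#' @export
scan_region <- function(anthro, scenario, alpha_range = NULL,
                        beta_range = c(0, 130), step = 1) {
  stopifnot(step > 0, length(beta_range) == 2L,
            beta_range[2] >= beta_range[1])
  alpha_max <- rad2deg(acos(scenario$height / anthro$total_length))
  if (is.null(alpha_range)) alpha_range <- c(0, alpha_max - 1e-9)
  stopifnot(length(alpha_range) == 2L, alpha_range[2] >= alpha_range[1])
  alphas <- seq(alpha_range[1], alpha_range[2], by = step)
  betas <- seq(beta_range[1], beta_range[2], by = step)
  a <- anthro$cog_lower; b <- anthro$cog_upper
  mu <- scenario$mu
  grid_rows <- vector("list", length(alphas))
  int_rows <- vector("list", length(alphas))
  for (i in seq_along(alphas)) {
    al_deg <- alphas[i]
    al <- deg2rad(al_deg)
    L1 <- scenario$height / cos(al)
    L2 <- anthro$total_length - L1
    if (L2 <= 0) {
      grid_rows[[i]] <- data.frame(
        alpha_deg = al_deg, beta_deg = betas, class = "INVALID_GEOMETRY",
        grf_N = NA_real_, friction_N = NA_real_, grf_negative = FALSE)
      int_rows[[i]] <- data.frame(
        alpha_deg = al_deg, valid = FALSE,
        slip_lower = NA_real_, slip_upper = NA_real_,
        tilt_lower = NA_real_, tilt_upper = NA_real_,
        fall_lower = NA_real_, fall_upper = NA_real_)
      next
    }
    mg <- anthro$mass * anthro$gravity
    G1 <- mg * L1 / anthro$total_length
    G2 <- mg * L2 / anthro$total_length
    br <- deg2rad(betas)
    grf <- grf_closed_form(G1, G2, L1, L2, a, b, al, br)
    f <- friction_closed_form(G1, G2, L1, L2, a, b, al, br)
    slip <- f > mu * grf
    tilt <- tilt_margin(G1, G2, L1, L2, a, b, al, br) < 0
    cls <- ifelse(slip & tilt, "FALL_POSSIBLE",
                  ifelse(slip, "SLIP_ONLY",
                         ifelse(tilt, "TILT_ONLY", "STABLE")))
    grid_rows[[i]] <- data.frame(
      alpha_deg = al_deg, beta_deg = betas, class = cls,
      grf_N = grf, friction_N = f, grf_negative = grf < 0)
    si <- slip_beta_interval(anthro, scenario, al_deg, beta_range)
    ti <- tilt_beta_interval(anthro, scenario, al_deg, beta_range)
    fi <- intersect_intervals(si$intervals, ti$intervals)
    first_or_na <- function(m, k)
      if (nrow(m) >= 1L) m[1, k] else NA_real_
    int_rows[[i]] <- data.frame(
      alpha_deg = al_deg, valid = TRUE,
      slip_lower = first_or_na(si$intervals, 1),
      slip_upper = first_or_na(si$intervals, 2),
      tilt_lower = first_or_na(ti$intervals, 1),
      tilt_upper = first_or_na(ti$intervals, 2),
      fall_lower = first_or_na(fi, 1),
      fall_upper = first_or_na(fi, 2))
  }
  structure(
    list(grid = do.call(rbind, grid_rows),
         intervals = do.call(rbind, int_rows),
         anthro = anthro, scenario = scenario,
         alpha_range = alpha_range, beta_range = beta_range, step = step),
    class = "railfall_region_map"
  )
}

#' @export
print.railfall_region_map <- function(x, ...) {
  n_fall <- sum(x$grid$class == "FALL_POSSIBLE")
  cat(sprintf(
    "Stability region map (mu = %.2f): alpha in [%.1f, %.1f] deg, beta in [%g, %g] deg, step %g deg\n",
    x$scenario$mu, x$alpha_range[1], x$alpha_range[2],
    x$beta_range[1], x$beta_range[2], x$step))
  print(table(x$grid$class))
  cat(if (n_fall)
    sprintf("Fall possible in %d of %d cells.\n", n_fall, nrow(x$grid))
    else "No (alpha, beta) combination permits a fall.\n")
  invisible(x)
}

#' Area of the fall-possible region
#'
#' Cell-count times cell-area in squared degrees.
#'
#' @param map A [scan_region()] result.
#' @return Area in deg^2.
#' @export
fall_region_area <- function(map) {
  stopifnot(inherits(map, "railfall_region_map"))
  sum(map$grid$class == "FALL_POSSIBLE") * map$step^2
}

#' Sensitivity of the fall region to COG factors and friction
#'
#' Re-runs [scan_region()] for every combination of the supplied
#' centre-of-gravity scaling factors and friction coefficients and
#' summarises whether the fall region is empty and how large it is.
#'
#' @param anthro Baseline [anthropometry()] (length, mass, gravity kept).
#' @param scenario Baseline [railing_scenario()] (height kept).
#' @param a_values,b_values COG scaling factors to sweep, each in (0, 1).
#' @param mu_values Friction coefficients to sweep.
#' @param beta_range,step Grid controls passed to [scan_region()].
#' @return Data frame with one row per (a, b, mu): `fall_empty`,
#'   `fall_cells`, `fall_area_deg2`, and the number of alpha columns with
#'   a non-empty fall interval (`alphas_with_fall`).
#' @export
sensitivity_scan <- function(anthro, scenario,
                             a_values = c(0.4, 0.5, 0.6),
                             b_values = c(0.4, 0.5, 0.6),
                             mu_values = c(0.7, 0.2),
                             beta_range = c(0, 130), step = 1) {
  stopifnot(all(a_values > 0 & a_values < 1),
            all(b_values > 0 & b_values < 1), all(mu_values >= 0))
  combos <- expand.grid(a = a_values, b = b_values, mu = mu_values,
                        KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    an <- anthropometry(anthro$total_length, anthro$mass,
                        combos$a[i], combos$b[i], anthro$gravity)
    sc <- railing_scenario(scenario$height, combos$mu[i])
    m <- scan_region(an, sc, beta_range = beta_range, step = step)
    n_fall <- sum(m$grid$class == "FALL_POSSIBLE")
    data.frame(
      a = combos$a[i], b = combos$b[i], mu = combos$mu[i],
      fall_empty = n_fall == 0L, fall_cells = n_fall,
      fall_area_deg2 = n_fall * step^2,
      alphas_with_fall = sum(!is.na(m$intervals$fall_lower)))
  })
  do.call(rbind, res)
}

#' Plot a stability region map
#'
#' Shaded (beta, alpha) regions in the style of the model's stability
#' charts: slip-only, tilt-only and their overlap (fall possible).
#'
#' @param x A [scan_region()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.railfall_region_map <- function(x, ...) {
  g <- x$grid[x$grid$class != "INVALID_GEOMETRY", ]
  g$class <- factor(g$class, levels = c("STABLE", "SLIP_ONLY",
                                        "TILT_ONLY", "FALL_POSSIBLE"))
  ggplot2::ggplot(g, ggplot2::aes(x = beta_deg, y = alpha_deg,
                                  fill = class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(STABLE = "grey92", SLIP_ONLY = "#74add1",
                 TILT_ONLY = "#fdae61", FALL_POSSIBLE = "#d73027"),
      drop = FALSE, name = NULL) +
    ggplot2::labs(
      x = "beta (deg)", y = "alpha (deg)",
      title = sprintf("Slip / tilt stability regions (mu = %.2f)",
                      x$scenario$mu)) +
    ggplot2::theme_minimal()
}

#' Write a region map grid to CSV
#'
#' @param map A [scan_region()] result.
#' @param path Output file path.
#' @param warnings Attach per-row plausibility warning codes.
#' @return `path`, invisibly.
#' @export
write_region_csv <- function(map, path, warnings = TRUE) {
  g <- map$grid
  if (warnings) {
    per_alpha <- vapply(g$alpha_deg, function(al) {
      geom <- derive_segments(map$anthro, map$scenario, min(al, 89.999))
      if (!geom$valid) return("")
      paste(anatomical_plausibility(
        geom, posture(min(al, 89.999), 0)), collapse = ";")
    }, character(1))
    g$warnings <- per_alpha
  }
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-alpha condition intervals to JSON
#'
#' @param map A [scan_region()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intervals_json <- function(map, path) {
  iv <- map$intervals
  out <- lapply(seq_len(nrow(iv)), function(i) {
    row <- iv[i, ]
    pair <- function(lo, hi)
      if (is.na(lo)) list() else list(lo, hi)
    list(alpha_deg = row$alpha_deg, valid = row$valid,
         slip = pair(row$slip_lower, row$slip_upper),
         tilt = pair(row$tilt_lower, row$tilt_upper),
         fall = pair(row$fall_lower, row$fall_upper))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Case report for one parameter set
#'
#' Assembles, for a single anthropometry/railing pairing, the region maps
#' at the requested friction coefficients, the condition intervals at a
#' reference lean angle, anatomical plausibility warnings, and the
#' equilibrium-oracle verification status, as a machine-readable list
#' with a printed human-readable summary.
#'
#' @param anthro A [anthropometry()] object.
#' @param scenario A [railing_scenario()] object; its mu is used unless
#'   `mu_values` is given.
#' @param mu_values Friction coefficients to report on.
#' @param alpha_ref Reference lean angle in degrees for the printed
#'   interval endpoints.
#' @param beta_range,step Grid controls.
#' @return An object of class `railfall_case_report`.
#' @export
case_report <- function(anthro, scenario, mu_values = scenario$mu,
                        alpha_ref = 10, beta_range = c(0, 130), step = 1) {
  geom <- derive_segments(anthro, scenario, alpha_ref)
  entries <- lapply(mu_values, function(mu) {
    sc <- railing_scenario(scenario$height, mu)
    map <- scan_region(anthro, sc, beta_range = beta_range, step = step)
    ref <- if (geom$valid) list(
      slip = slip_beta_interval(anthro, sc, alpha_ref, beta_range),
      tilt = tilt_beta_interval(anthro, sc, alpha_ref, beta_range),
      fall = fall_interval(anthro, sc, alpha_ref, beta_range),
      union = instability_union(anthro, sc, alpha_ref, beta_range))
    else NULL
    list(mu = mu, map = map, reference = ref,
         fall_cells = sum(map$grid$class == "FALL_POSSIBLE"))
  })
  ver <- if (geom$valid) {
    p <- posture(alpha_ref, min(80, 180 - alpha_ref))
    w <- split_weights(anthro, geom)
    eq <- solve_equilibrium(build_configuration(anthro, scenario, p), w)
    mg <- anthro$mass * anthro$gravity
    list(
      grf_rel_err = abs(eq$grf_vector[2] -
                          ground_reaction(anthro, geom, p)) / mg,
      friction_rel_err = abs(abs(eq$friction_vector[1]) -
                               friction_demand(anthro, geom, p)) / mg,
      moment_residual_A = abs(eq$residuals$moment_A),
      moment_residual_B = abs(eq$residuals$moment_B))
  } else NULL
  structure(
    list(anthro = anthro, scenario = scenario, alpha_ref = alpha_ref,
         geometry = geom,
         warnings = if (geom$valid)
           anatomical_plausibility(geom, posture(alpha_ref, 0))
         else character(0),
         entries = entries, verification = ver),
    class = "railfall_case_report"
  )
}

#' @export
print.railfall_case_report <- function(x, ...) {
  cat("=== Fall-over-railing case report ===\n")
  print(x$anthro)
  cat(sprintf("Railing height Y = %.3f m\n", x$scenario$height))
  print(x$geometry)
  if (length(x$warnings))
    cat("Plausibility warnings:", paste(x$warnings, collapse = ", "), "\n")
  fmt_iv <- function(iv) {
    if (nrow(iv$intervals) == 0L) return("empty")
    paste(apply(iv$intervals, 1, function(r)
      sprintf("(%.1f, %.1f) deg", r[1], r[2])), collapse = " U ")
  }
  for (e in x$entries) {
    cat(sprintf("\n-- mu = %.2f --\n", e$mu))
    if (!is.null(e$reference)) {
      cat(sprintf("  at alpha = %.1f deg: slip %s | tilt %s | fall %s\n",
                  x$alpha_ref, fmt_iv(e$reference$slip),
                  fmt_iv(e$reference$tilt), fmt_iv(e$reference$fall)))
    }
    cat(if (e$fall_cells)
      sprintf("  fall region: %d grid cells\n", e$fall_cells)
      else "  no (alpha, beta) combination permits a fall\n")
  }
  if (!is.null(x$verification))
    cat(sprintf(
      "\nOracle verification: GRF rel. err %.1e, F rel. err %.1e, moment residuals %.1e / %.1e N m\n",
      x$verification$grf_rel_err, x$verification$friction_rel_err,
      x$verification$moment_residual_A, x$verification$moment_residual_B))
  invisible(x)
}
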