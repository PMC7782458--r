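#' Reproducible random scenario fixtures
#'
#' Draws parameter sets spanning the model's physically sensible ranges:
#' body length 1.4--2.0 m, mass 45--110 kg, railing height 0.8--1.2 m
#' (always below 0.8 L), friction 0.05--1.0, COG factors 0.3--0.7, alpha
#' uniform inside the validity range of each draw, beta uniform in
#' [0, min(130, 180 - alpha)].  Used by the property suites that certify
#' the closed forms against the equilibrium solver.
#'
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param n Number of parameter sets.
#' @return Data frame with columns `total_length`, `mass`, `height`,
#'   `mu`, `a`, `b`, `alpha`, `beta` (angles in degrees).
#' @examples
#' generate_fixtures(42, 5)
#' @export
generate_fixtures <- function(seed, n) {
  stopifnot(n > 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  L <- stats::runif(n, 1.4, 2.0)
  m <- stats::runif(n, 45, 110)
  Y <- stats::runif(n, 0.8, pmin(1.2, 0.8 * L))
  mu <- stats::runif(n, 0.05, 1.0)
  a <- stats::runif(n, 0.3, 0.7)
  b <- stats::runif(n, 0.3, 0.7)
  alpha_max <- rad2deg(acos(Y / L))
  alpha <- stats::runif(n, 0, 0.98 * alpha_max)
  beta <- stats::runif(n, 0, pmin(130, 180 - alpha))
  data.frame(total_length = L, mass = m, height = Y, mu = mu,
             a = a, b = b, alpha = alpha, beta = beta)
}
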