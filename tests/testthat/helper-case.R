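# Worked-example parameters: 1.58 m / 65 kg person, 0.92 m railing,
# homogeneous rod (a = b = 0.5).
case_anthro <- function(a = 0.5, b = 0.5)
  anthropometry(1.58, 65, cog_lower = a, cog_upper = b)

case_scenario <- function(mu) railing_scenario(0.92, mu)

# Independent brute-force oracle: violation range of a primitive
# inequality located by dense grid evaluation (no bisection machinery).
brute_violation_range <- function(margin, beta_deg_max = 130,
                                  res_deg = 0.01) {
  b <- seq(0, beta_deg_max, by = res_deg)
  v <- margin(b * pi / 180) < 0
  if (!any(v)) return(NULL)
  c(min(b[v]), max(b[v]))
}

# Raw inequality margins written out independently of the package's
# internal helpers (same formulas, separate code path).
case_margins <- function(alpha_deg, mu, a = 0.5, b = 0.5,
                         L = 1.58, m = 65, Y = 0.92, g = 9.81) {
  al <- alpha_deg * pi / 180
  L1 <- Y / cos(al); L2 <- L - L1
  G1 <- m * g * L1 / L; G2 <- m * g * L2 / L
  list(
    slip = function(beta) {
      grf <- G1 * (1 - a * sin(al)^2) +
        G2 * (cos(al)^2 - b * (L2 / L1) * sin(al) * sin(al + beta))
      f <- (a * G1 * sin(al) + G2 * sin(al) +
              b * G2 * (L2 / L1) * sin(al + beta)) * cos(al)
      mu * grf - f
    },
    tilt = function(beta)
      L1 * (a * G1 + G2) * sin(al) - G2 * b * L2 * sin(al + beta)
  )
}
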