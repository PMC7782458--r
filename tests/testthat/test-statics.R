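test_that("closed-form forces reduce correctly in analytic limits", {
  an <- case_anthro(); sc <- case_scenario(0.2)
  g <- derive_segments(an, sc, 0)
  w <- split_weights(an, g)

  # upright lower segment: full weight on the feet, for any beta
  for (be in c(0, 45, 90, 130))
    expect_equal(ground_reaction(an, g, posture(0, be)),
                 w$lower_weight + w$upper_weight, tolerance = 1e-14)

  expect_equal(friction_demand(an, g, posture(0, 0)), 0)

  # horizontal upper segment at alpha = 0: F = b G2 L2 / L1
  expect_equal(friction_demand(an, g, posture(0, 90)),
               0.5 * w$upper_weight * g$upper_length / g$lower_length,
               tolerance = 1e-12)
})

test_that("anti-slip is the Coulomb inequality with equality counted stable", {
  d <- function(f, grf) list(friction_demand = f, ground_reaction = grf)
  expect_true(anti_slip_holds(d(0, 100), 0.2))
  expect_true(anti_slip_holds(d(70, 100), 0.7))   # boundary
  expect_true(anti_slip_holds(d(60, 100), 0.7))
  expect_false(anti_slip_holds(d(80, 100), 0.7))
})

test_that("anti-tilt threshold is beta = 0 at alpha = 0 and the worked example tips at beta = 80 deg", {
  an <- case_anthro(); sc <- case_scenario(0.2)
  g0 <- derive_segments(an, sc, 0)
  expect_true(anti_tilt_holds(an, g0, posture(0, 0)))
  for (be in c(1e-6, 1, 30, 120))
    expect_false(anti_tilt_holds(an, g0, posture(0, be)))

  g10 <- derive_segments(an, sc, 10)
  expect_false(anti_tilt_holds(an, g10, posture(10, 80)))
  expect_true(anti_tilt_holds(an, g10, posture(10, 40)))
})

test_that("condition intervals match an independent dense-scan oracle", {
  an <- case_anthro()

  # mu = 0.7: anti-slip holds over the whole beta domain
  m7 <- case_margins(10, 0.7)
  expect_null(brute_violation_range(m7$slip))
  s7 <- slip_beta_interval(an, case_scenario(0.7), 10)
  expect_identical(s7$status, "empty")

  # mu = 0.2: slip over ~(21.5, 130] deg
  m2 <- case_margins(10, 0.2)
  br <- brute_violation_range(m2$slip)
  s2 <- slip_beta_interval(an, case_scenario(0.2), 10)
  expect_identical(s2$status, "interval")
  expect_equal(s2$intervals[1, 1], br[1], tolerance = 0.011)
  expect_equal(s2$intervals[1, 2], 130)

  # tilt: (50, 110) deg, independent of mu
  brt <- brute_violation_range(m2$tilt)
  t2 <- tilt_beta_interval(an, case_scenario(0.2), 10)
  expect_equal(t2$intervals[1, ], br <- brt, tolerance = 0.011,
               ignore_attr = TRUE)
  expect_equal(round(t2$intervals[1, 1]), 50)
  expect_equal(round(t2$intervals[1, 2]), 110)
})

test_that("scanned endpoints agree with the closed-form arcsin solutions to 1e-8 rad", {
  an <- case_anthro()
  for (mu in c(0.2, 0.7)) {
    sc <- railing_scenario(0.92, mu)
    for (al in c(2, 5, 10, 20, 30, 45)) {
      cf <- railfall:::tilt_closed_form(an, sc, al)
      iv <- tilt_beta_interval(an, sc, al, beta_domain = c(0, 170 - al))
      if (cf$status == "interval" && cf$beta1 > 0) {
        expect_lt(abs(iv$intervals[1, 1] * pi / 180 - cf$beta1), 1e-8)
        expect_lt(abs(iv$intervals[1, 2] * pi / 180 -
                        min(cf$beta2, (170 - al) * pi / 180)), 1e-8)
      } else if (cf$status == "empty") {
        expect_identical(iv$status, "empty")
      }
      cfs <- railfall:::slip_closed_form(an, sc, al)
      ivs <- slip_beta_interval(an, sc, al, beta_domain = c(0, 170 - al))
      if (cfs$status == "interval" && cfs$beta1 > 0 &&
          cfs$beta2 < (170 - al) * pi / 180) {
        expect_lt(abs(ivs$intervals[1, 1] * pi / 180 - cfs$beta1), 1e-8)
        expect_lt(abs(ivs$intervals[1, 2] * pi / 180 - cfs$beta2), 1e-8)
      } else if (cfs$status == "empty") {
        expect_identical(ivs$status, "empty")
      }
    }
  }
})

test_that("second arcsin branch is the supplementary solution", {
  expect_equal(arcsin_branch_pair(30, 10)$beta_2, 130)
  expect_equal(arcsin_branch_pair(50, 10)$beta_2, 110)
  p <- arcsin_branch_pair(37.3, 0)
  expect_equal(p$beta_2, 180 - 37.3)
  expect_equal(sin((p$beta_1 + 0) * pi / 180),
               sin((p$beta_2 + 0) * pi / 180), tolerance = 1e-12)
})

test_that("tilt intervals are friction-invariant and slip intervals shrink with friction", {
  an <- case_anthro()
  t02 <- tilt_beta_interval(an, case_scenario(0.2), 10)
  t07 <- tilt_beta_interval(an, case_scenario(0.7), 10)
  expect_identical(t02$intervals, t07$intervals)

  mus <- c(0.1, 0.2, 0.35, 0.5)
  ivs <- lapply(mus, function(mu)
    slip_beta_interval(an, case_scenario(mu), 10)$intervals)
  for (k in seq_along(mus)[-1]) {
    if (nrow(ivs[[k]]) == 0L) next
    expect_gte(ivs[[k]][1, 1], ivs[[k - 1]][1, 1])
    expect_lte(ivs[[k]][1, 2], ivs[[k - 1]][1, 2])
  }
})

test_that("tilt margin vanishes at the computed tilt boundary", {
  an <- case_anthro(); sc <- case_scenario(0.2)
  mgL <- 65 * 9.81 * 1.58
  for (al in c(5, 10, 25, 40)) {
    cf <- railfall:::tilt_closed_form(an, sc, al)
    if (cf$status != "interval") next
    m <- case_margins(al, 0.2)
    expect_lt(abs(m$tilt(cf$beta1)), 1e-10 * mgL)
    expect_lt(abs(m$tilt(cf$beta2)), 1e-10 * mgL)
  }
})

test_that("posture classification partitions the plane and matches the worked example", {
  an <- case_anthro()

  expect_identical(
    classify_posture(an, case_scenario(0.2), posture(10, 80))$class,
    "FALL_POSSIBLE")
  expect_false(
    classify_posture(an, case_scenario(0.7), posture(10, 80))$class ==
      "FALL_POSSIBLE")
  expect_identical(
    classify_posture(an, case_scenario(0.2), posture(0, 0))$class, "STABLE")
  expect_identical(
    classify_posture(an, case_scenario(0.2), posture(60, 0))$class,
    "INVALID_GEOMETRY")

  # exactly one class per cell; FALL_POSSIBLE = slip AND tilt
  sc <- case_scenario(0.2)
  for (al in c(5, 10, 20)) {
    s <- slip_beta_interval(an, sc, al)$intervals
    t <- tilt_beta_interval(an, sc, al)$intervals
    inside <- function(m, be)
      nrow(m) > 0L && any(be > m[, 1] & be < m[, 2])
    for (be in seq(0, 130, by = 7)) {
      cls <- classify_posture(an, sc, posture(al, be))$class
      want <- if (inside(s, be) && inside(t, be)) "FALL_POSSIBLE"
      else if (inside(s, be)) "SLIP_ONLY"
      else if (inside(t, be)) "TILT_ONLY"
      else "STABLE"
      # skip cells within bisection distance of an endpoint
      near_edge <- any(abs(c(s, t) - be) < 1e-6)
      if (!near_edge) expect_identical(cls, want)
    }
  }
})
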