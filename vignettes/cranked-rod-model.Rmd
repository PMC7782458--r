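---
title: "The cranked-rod model for quasi-static falls over railings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cranked-rod model for quasi-static falls over railings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(railfall)
```

## The question and the model

A recurring question in forensic casework is whether a person leaning
against a balcony or bridge railing could have gone over it *without* any
dynamic contribution — no push, no jump, no initial velocity.  `railfall`
answers the mechanical part of that question with a deliberately simple
quasi-static model: the body is a rigid two-segment rod (a "cranked rod")
that touches the ground at the feet (point A) and pivots on the handrail
(point B), with the head end at C.  Two angles describe the posture:

* `alpha` — the lean of the lower body segment against the (vertical)
  railing plane, and
* `beta` — the flexion of the upper body over the rail, measured between
  the two segments at the pivot.

Because the rail sits at a known height `Y` on the lower segment, the
segment lengths are functions of the posture, not constants:
`L1 = Y / cos(alpha)` and `L2 = L - L1`, with `L` the total body length.
Assuming a homogeneous mass distribution, each segment carries weight in
proportion to its length, `G_i = m g L_i / L`, recomputed for every
`alpha`.  Homogeneity is the only mass model consistent with the rod
idealisation; segment-wise anthropometric mass tables are deliberately
out of scope.  The centres of gravity sit at fractions `a` and `b` along
each segment (0.5 for a homogeneous rod); both are exposed as parameters
because the sensitivity of the result to them is itself of interest.

Two independent mechanisms can defeat the posture:

* **Slip.** Equilibrium demands a horizontal friction force `F` at the
  feet.  The feet hold while `F <= mu * GRF` (the *anti-slip* condition,
  Coulomb friction with coefficient `mu`); otherwise the feet must
  slide toward the railing.
* **Tilt.** The lower-body weight provides a restoring moment about the
  rail pivot while the flexed upper body provides a tipping one.  The
  *anti-tilt* condition bounds `beta` by an arcsin threshold that grows
  with `alpha` and is independent of friction.

A fall over the railing is considered mechanically possible only where
**both** conditions fail simultaneously.  That conjunction — not the
popular "centre of mass above the handrail" heuristic — is the model's
criterion, and the package's central output is the `(alpha, beta)` region
in which it holds.

## Closed forms, primitive inequalities, and the equilibrium oracle

Force and moment balance of the leaning rod yield closed forms for the
vertical ground reaction and the friction demand:

```
GRF = G1 (1 - a sin^2 alpha)
    + G2 (cos^2 alpha - b (L2/L1) sin alpha sin(alpha + beta))
F   = (a G1 sin alpha + G2 sin alpha
    + b G2 (L2/L1) sin(alpha + beta)) cos alpha
```

and the tilt condition reduces to

```
G2 b L2 sin(alpha + beta) > L1 (a G1 + G2) sin alpha .
```

The package treats these **primitive inequalities as ground truth** and
uses the arcsin forms only as analytic cross-checks.  The reason is
numerical: solving `sin(alpha + beta) = s` for `beta` involves a branch
choice (the supplementary solution `beta2 = 180 - beta1 - 2 alpha`) and an
arcsin domain check (`|s| <= 1`), both of which are edge cases a direct
inequality scan never has to special-case.  `slip_beta_interval()` and
`tilt_beta_interval()` scan the margin of the inequality over the `beta`
domain on a 200-point grid and refine every sign change by bisection to
1e-8 rad; the test suite asserts that, wherever the arcsin argument lies
strictly inside (-1, 1), these scanned endpoints coincide with the
closed-form solutions.

One subtlety deserves a note.  The tilt threshold implemented here is the
arcsin form whose numerator is `L1 (a G1 + G2) sin alpha`.  A naive moment
balance of the two weights alone about the pivot (with centres of gravity
at fractions `a` and `b` from each segment's proximal end) would instead
give a numerator `(1 - a) G1 L1 sin alpha`, which produces a very
different, much smaller threshold.  The implemented form is the one the
model's published stability charts and worked-example interval are built
on, and it is the one this package reproduces and tests; the package
therefore defines the *tilt margin* as the implemented expression (in
N·m) and verifies that it vanishes at the computed interval endpoints,
rather than asserting a weights-only moment balance that the threshold
does not satisfy.

Because closed forms are easy to mistranscribe, the package carries an
independent **equilibrium oracle** (`solve_equilibrium()`): it places the
rod in the plane, treats the vertical ground reaction, the horizontal
friction force and the rail bearing force as unknowns of the 3x3 linear
force/moment system, and solves it numerically.  The system is closed by
taking the bearing force perpendicular to the lower segment — the rail
contact is frictionless, consistent with the model's stated neglect of
pivot friction — and that closure reproduces the closed forms to machine
precision (the test suite requires 1e-9 relative agreement of `m g` on
1,000 random parameter sets, and moment residuals about the feet, the
pivot and an arbitrary third point below 1e-9 `m g L`).  The moment
equation about the pivot is redundant given the other equations, so its
residual is a genuine consistency check, not a fitted quantity.

## Parameters, units, and defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `total_length` | body length L | m | — (1.58 in the worked example) |
| `mass` | body mass | kg | — (65) |
| `height` | railing height Y | m | — (0.92) |
| `mu` | static friction, feet–ground | — | — (0.5–0.7 is typical for shoe–concrete; 0.2 models a slippery floor) |
| `cog_lower` (`a`), `cog_upper` (`b`) | COG fraction per segment | — | 0.5 |
| `gravity` | g | m/s² | 9.81 |
| `beta_domain` | scanned flexion range | deg | [0, 130] |
| scan points / bisection tol | interval location | — / rad | 200 / 1e-8 |

Angles are degrees at every user-facing interface and radians internally.
`g` cancels from both thresholds (they depend only on weight ratios and
`mu`); it matters only for reported force magnitudes.  The `beta` domain
default of [0, 130] degrees covers every flexion a torso can plausibly
produce while keeping `alpha + beta` well below 180 degrees (postures
folded back through the lower segment are excluded as unphysical); it is
configurable everywhere it appears.  Boundary ties count as stable:
equality in either condition is the *anti*- (stable) side, matching the
non-strict inequalities that define the conditions.

A negative ground reaction can arise algebraically for extreme postures.
Classification applies the conditions as written but raises a
`grf_negative` flag, since Coulomb friction against a negative normal
force is physically meaningless and such postures need scrutiny.

## Applicability warnings

The rod idealisation breaks down when the pivot does not correspond to a
body region that can actually flex.  Two screening warnings — never
errors — flag this: `PIVOT_ABOVE_ABDOMEN` when the pivot fraction `L1/L`
exceeds 0.65 (the pivot then sits at the thoracic region, where no joint
permits the assumed flexion), and `LARGE_ALPHA` when `alpha` exceeds 30
degrees (such leans are typically only realisable with the feet off the
ground, where the whole quasi-static premise fails).  Both thresholds are
configurable; they are screening heuristics for qualitative anatomical
statements, not calibrated cutoffs, which is why they warn instead of
block.

## The worked example

The bundled worked example is a 1.58 m, 65 kg person at a 0.92 m railing.
At `alpha` = 10°:

```{r example}
an <- anthropometry(1.58, 65)
tilt_beta_interval(an, railing_scenario(0.92, 0.7), 10)
slip_beta_interval(an, railing_scenario(0.92, 0.7), 10)
fall_interval(an, railing_scenario(0.92, 0.2), 10)
```

With good footing (`mu` = 0.7) the slip condition is never met, so no
posture can fall even though the tilt condition holds for `beta` between
about 50° and 110°.  On a slippery floor (`mu` = 0.2) the slip interval
widens to cover the tilt interval, and a fall becomes mechanically
possible exactly for `beta` in (50°, 110°) — the conjunction region.  The
full maps:

```{r maps}
m7 <- scan_region(an, railing_scenario(0.92, 0.7), step = 1)
m2 <- scan_region(an, railing_scenario(0.92, 0.2), step = 1)
m7
fall_region_area(m2)
```

```{r plot, fig.width = 7, fig.height = 4.5}
plot(m2)
```

The sensitivity sweep varies both COG fractions over 0.4–0.6 at both
friction levels (18 maps, 1° grid — a few seconds of compute) and finds
the topology unchanged: empty fall region at `mu` = 0.7, non-empty at
`mu` = 0.2 for all nine (a, b) combinations:

```{r sensitivity}
sensitivity_scan(an, railing_scenario(0.92, 0.2))
```

## Numerical and design choices

* **Endpoints from analysis, not the grid.** Region maps classify grid
  cells, but printed interval endpoints always come from the
  scan-plus-bisection path, so grid resolution never aliases a reported
  threshold.  Rounding to the nearest degree is applied only at the
  reporting layer.
* **Degenerate geometry is a value, not an error.** `alpha >=
  arccos(Y/L)` leaves no body above the rail; `derive_segments()` flags
  it and `classify_posture()` returns `INVALID_GEOMETRY`, keeping region
  scans total.
* **Weight split per alpha.** Whether the segment weights should be
  recomputed as `alpha` varies is genuinely open; homogeneity implies
  they must (the pivot moves along the body), and that choice reproduces
  the worked-example interval, so it is adopted throughout.
* **Fixtures.** `generate_fixtures()` draws seeded parameter sets with
  body length 1.4–2.0 m, mass 45–110 kg, railing 0.8–1.2 m (below 0.8 L),
  `mu` 0.05–1.0, COG fractions 0.3–0.7, and admissible angles — ranges a
  practitioner would accept as covering adult anthropometry and common
  railings.  They exist to exercise the algebra across the valid domain,
  not to emulate case data.

## What passing tests do and do not show

The synthetic fixtures certify *internal* correctness: closed forms
against an independent equilibrium solver, scanned intervals against
arcsin solutions, classification against interval membership.  They say
nothing about whether a real fall occurred.  The model is quasi-static
(no pushing, jumping, or recovery movements), rigid (no soft-tissue
deformation), frictionless at the rail pivot, and planar; active balance
reactions — which real people attempt — are outside it entirely.  Its
proper forensic use is as one strand of a multifactorial assessment:
a mechanical screen for whether any plausible posture could have led
over the railing at all, alongside injury-pattern, trace and, where
warranted, dynamic simulation evidence.
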