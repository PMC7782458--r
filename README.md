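# railfall

Quasi-static mechanics of falls over railings, for forensic
reconstruction.

A frequent forensic question is whether a person leaning against a
balcony or bridge railing could have gone over it *accidentally* — with
no push, jump, or initial velocity.  `railfall` models the body as a
rigid two-segment rod ("cranked rod") touching the ground at the feet
(A) and pivoting on the handrail (B).  The posture is described by the
lean angle `alpha` of the lower body against the vertical railing plane
and the flexion angle `beta` of the upper body over the rail.  With body
length `L`, railing height `Y`, mass `m` and centre-of-gravity fractions
`a`, `b`, the rail splits the body into segments `L1 = Y / cos(alpha)`
and `L2 = L - L1` carrying weights `G_i = m g L_i / L`.

Two conditions decide stability:

* **anti-slip** — the friction demand at the feet stays within the
  Coulomb capacity, `F <= mu * GRF`, with the closed forms

  ```
  GRF = G1 (1 - a sin^2 a) + G2 (cos^2 a - b (L2/L1) sin a sin(a + b))
  F   = (a G1 sin a + G2 sin a + b G2 (L2/L1) sin(a + b)) cos a
  ```

* **anti-tilt** — the flexed upper body does not out-lever the lower
  body about the rail pivot:
  `G2 b L2 sin(alpha + beta) <= L1 (a G1 + G2) sin(alpha)`.

A fall over the railing is mechanically possible only where **both**
conditions are violated simultaneously.  The package locates the
`beta`-intervals of each instability condition (scan of the primitive
inequality + bisection to 1e-8 rad, cross-checked against the arcsin
closed forms and their supplementary branch
`beta2 = 180 - beta1 - 2 alpha`), maps the `(alpha, beta)` stability
region, sweeps the sensitivity to `a`, `b` and `mu`, and certifies all
closed forms against an independent numerical solution of the planar
force/moment equilibrium.

## Worked example

A 1.58 m, 65 kg person at a 0.92 m railing (homogeneous rod,
`a = b = 0.5`):

```r
library(railfall)
an <- anthropometry(1.58, 65)

fall_interval(an, railing_scenario(0.92, 0.2), alpha = 10)
#> fall condition over beta in [0, 130] deg: (49.97, 110.03) deg

instability_union(an, railing_scenario(0.92, 0.7), alpha = 10)
#> instability condition over beta in [0, 130] deg: (49.97, 110.03) deg

scan_region(an, railing_scenario(0.92, 0.7), step = 0.5)
#> Stability region map (mu = 0.70): ...
#> No (alpha, beta) combination permits a fall.
```

Read: on a slippery floor (`mu = 0.2`), leaning at 10° and flexing the
torso between about **50° and 110°** puts the body where it must both
slide and tip — a fall over the railing is mechanically possible.  With
ordinary shoe–concrete friction (`mu = 0.7`) the same flexion range
violates only one condition at a time, and scanning the entire admissible
posture grid finds **no** combination that permits a fall: the scenario
then requires a dynamic contribution the model deliberately excludes.

`classify_posture()` labels single postures (`STABLE`, `SLIP_ONLY`,
`TILT_ONLY`, `FALL_POSSIBLE`, `INVALID_GEOMETRY`), attaches anatomical
plausibility warnings (pivot above the abdomen, excessive lean), and
`plot()` on a region map draws the shaded slip/tilt/overlap chart.  A
thin command-line front end lives at `inst/cli/railfall`
(`classify`, `thresholds`, `map`, `sensitivity`, `case-report`).

See `vignettes/cranked-rod-model.Rmd` for the model's assumptions,
numerical choices and limitations.

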