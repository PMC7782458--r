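Package: railfall
Title: Quasi-Static Cranked-Rod Model for Falls over Railings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forensic-biomechanics assessment of whether a person leaning
    against a railing can fall over it without any dynamic component.  The
    body is modeled as a two-segment rigid rod ("cranked rod") pivoting on
    the handrail: a Coulomb-friction anti-slip condition at the feet and a
    moment-based anti-tilt condition at the rail pivot are evaluated in
    closed form, beta-intervals of instability are located by scanning and
    bisection on the primitive inequalities, and the (alpha, beta) posture
    region in which a fall is mechanically possible is mapped, with a
    sensitivity sweep over center-of-gravity scaling factors and friction.
    An independent planar force/moment equilibrium solver certifies the
    closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
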