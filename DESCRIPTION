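Package: lumbosim
Title: Muscle-Driven Forward-Dynamic Hybrid FE-Rigid-Body Model of the Lumbosacral Spine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained simulator of the human lumbosacral spine combining
    rigid vertebrae with fiber-reinforced hyperelastic finite-element
    intervertebral discs, tension-only ligaments, unilateral facet contacts,
    Hill-type trunk muscle fascicles placed by landmark-based affine
    registration, an abdominal kinematic chain with intra-abdominal pressure,
    and a tracking-controller muscle-recruitment solver. Includes a synthetic
    parametric spine generator, calibration protocols for maximum specific
    muscle tension and segmental spinal rhythms, and a validation load-case
    suite reporting intradiscal pressures, intra-abdominal pressure, muscle
    group forces, and intervertebral rotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
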