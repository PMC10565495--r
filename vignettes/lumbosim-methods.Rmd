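---
title: "Model and methods of the lumbosim spine simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods of the lumbosim spine simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lumbosim` simulates the human lumbosacral spine as a muscle-driven hybrid
model: rigid vertebrae coupled by deformable finite-element intervertebral
discs, tension-only ligaments and unilateral facet contacts, actuated by
Hill-type trunk muscle fascicles whose excitations are chosen per step by a
tracking controller. This vignette describes the model, its numerical
treatment, the design decisions that were genuinely open, and what the
bundled synthetic spine can and cannot show about real anatomy.

## Coordinate conventions and bodies

The global frame is right-handed with +x anterior, +y to the subject's
left, +z cranial; gravity acts along -z at 9.81 m/s^2. All user-facing
angles are degrees (radians internally); pressures are reported in MPa
(intradiscal) and mmHg (intra-abdominal) following the conventions of the
in vivo literature.

Dynamic rigid bodies are the lumped thorax (everything cranial to L1,
rigidly connected to L1) and the vertebrae L2-L5. The sacrum and pelvis
are rigidly connected and stationary. A second, quasi-massless abdominal
plate is dynamically active but is eliminated from the global unknowns by
an exact inner static solve (see below). Positive sagittal rotation about
+y is flexion.

## The synthetic parametric spine

The generator (`build_synthetic_lss()`) defines the study conditions. Key
defaults, all configuration inputs:

* L1-S1 superior-endplate lordosis 47.5 deg, sacral slope 36.3 deg,
  pelvic incidence 45.36 deg, pelvic tilt 9.06 deg. The lordotic wedge is
  distributed over the five discs with caudally increasing fractions
  (12/17/20/24/27 %), a typical in vivo pattern; the built lordosis
  matches the configured value to well under 0.5 deg.
* body mass 90 kg (a heavier mid-size male); 40 % of body mass is lumped
  cranial to L1 at COM_UB, 2 cm anterior and 20 cm cranial of L1. The
  per-level vertebral masses and inertias are plausible placeholders and
  are configurable.
* vertebral body height 28 mm, disc height 11 mm, disc radii 12 mm
  (nucleus) / 21 mm (annulus).

Muscle attachment coordinates are parametric archetypes of the twelve
trunk muscle groups (counts per group from the shipped inventory table:
129 right-side fascicles, 119 without transversus abdominis), generated on
the right side and mirrored about y = 0, so the model is exactly
mirror-symmetric at build time. They are synthetic stand-ins, not
digitized anatomy: passing tests demonstrate the mechanics and protocols,
not subject-specific geometry. Group PCSA totals are mid-literature
values; fiber length is 50 % of the neutral musculotendon length, with the
tendon slack length chosen so each fiber sits at optimal length in the
neutral build (so passive force and stiffness vanish exactly at neutral).

## FE discs

Each disc is an 8-node hexahedral butterfly (O-grid) mesh between the two
endplates: a 3x3 core block plus six concentric rings of twelve sectors
(81 elements, 176 nodes in the default one-layer configuration). The core
and first ring are nucleus pulposus (isochoric Yeoh with volumetric
penalty), the outer five rings annulus fibrosus (isochoric Mooney-Rivlin),
with five criss-crossed rings of tension-only collagen fiber cables
(+-about 45 deg to the transverse plane as realized by the mesh) spanning
the annulus boundaries. The cranial and caudal node layers are bound to
the adjacent vertebra frames; with one element layer every node is bound,
which makes the disc response an algebraic function of the two vertebra
poses. Meshes with interior layers equilibrate their free nodes by an
inner Newton solve.

Three numerical choices matter:

* **Region-level nucleus incompressibility.** The nucleus behaves as an
  incompressible fluid, so its volumetric penalty acts on the *region*
  volume: one hydrostatic pressure `kappa (Jbar_nuc - 1)` for the whole
  nucleus. This is exactly the hydrostatic-nucleus assumption that also
  underlies the intradiscal pressure (IDP) readout, and it lets bending
  redistribute nucleus volume freely while net compression is strongly
  penalized (nucleus volume change stays below 1 % at a 500 N compressive
  load with the default bulk modulus of 200 MPa). With a per-element
  penalty the endplate-bound mesh shows a spurious bending stiffness
  several times the physiological value.
* **Reduced integration.** The default model discs use single-point
  quadrature; with all nodes bound to rigid endplates there are no
  hourglass modes to stabilize. Full 2x2x2 quadrature is available
  (`gauss_order = 2`) and is the default for standalone discs.
* **Constitutive calibration.** The hyperelastic constants are
  configuration inputs. The defaults were calibrated once so
  that a single synthetic disc shows about 2 Nm/deg sagittal bending
  stiffness and about 4 kN/mm axial stiffness, inside the in vitro range
  for lumbar functional spinal units; ligament force tables were scaled to
  the same end.

The IDP is the negative mean over all nucleus FE nodes of the mean normal
stress tr(sigma)/3, with volume-weighted element-to-node averaging,
reported in MPa. Facet contacts are node-to-plane penalties (frictionless,
compressive-only, 400 kN/m) at the superior articular processes, one pair
per level.

## Musculotendon model

Fascicles are tension-only path actuators with rigid tendons: the fiber
state is algebraic in musculotendon length, using a fixed-width pennation
model. The normalized curve set is the standard closed-form family
(tri-Gaussian active force-length, exponential passive force-length,
logarithmic force-velocity), normalized so the active curve is exactly 1
at optimal length and the velocity curve exactly 1 at zero velocity. The
passive curve is written C1 with zero slope at slack so that force and
stiffness engage together — static solvers otherwise stall on the slope
kink that every fascicle occupies at the neutral build. Maximum isometric
force is the reference PCSA times the specific tension K (default
100 N/cm^2 after the calibration protocol) scaled by body mass and
inverse musculotendon length. A resting tone of 0.1 % acts as a lower
excitation bound (`max(e, tone)`).

Paths run straight between attachment and via points; designated
fascicles wrap the lumbar cylinder (analytic tangent-arc-tangent
construction, shorter side, geodesic axial interpolation) or the thoracic
ellipsoids (taut-string iteration with radial projection, tolerance
1e-6 m). The lumbar cylinder is kinematically slaved to the spine: in
extension its hinge keeps the angular sum of the S1-L1 and
S1-wrapping-body directions to the S1 perpendicular constant and its
slider advances 0.54:1 with the L2-S1 height loss; in flexion the hinge is
fixed and the slider follows anterior L4 displacement 1.3:1.

## Abdominal chain and intra-abdominal pressure

The abdominal plate is posed by an open kinematic chain
(sacrum-UJ-HJ-CJ-plate) whose five coordinates follow the
thorax-relative-to-pelvis angles through quadratic polynomials with
separate flexion/extension branches. The two branches are blended C1 over
+-0.5 deg about zero (both vanish there), purely to keep the static
solver off the derivative kink; outside that band the tabulated branch
polynomials hold exactly. The Z coordinate's polynomial output has no
uniquely implied unit; it is interpreted as centimeters per degree-argument with
a configurable scale, and the implied cavity-volume drift can be reported
as a diagnostic.

The dynamically active plate AP_IAP carries the insertions of the
internal/external obliques and transversus abdominis, tied to the
kinematic plate by a six-dimensional spring (90 kN/m along the plate
normal, 1 MN/m shear, 500 Nm/rad). Because AP_IAP is quasi-massless, its
pose is solved to exact static equilibrium *inside* the residual (a 6-DOF
inner Newton solve) rather than carried as a global unknown; this
eliminates the stiffest subsystem from the outer solve, which otherwise
dominates its conditioning. The spring's normal force is the abdominal
compression F_AP; the cavity relation converts it to the diaphragm force
and pressure with entwinement 0.6, a 4 mmHg resting offset and a 200 mmHg
cap. Cavity dimensions (0.24 m diameter, 0.26 m height) are anthropometric
estimates for the synthetic trunk: the sources never print them, so they
are configuration inputs. The diaphragm force acts cranially at a point
5.1 cm anterior of T12 and rotates with the thorax; its reaction is taken
by the stationary pelvis.

### Fitting the chain coefficients

`fit_abdominal_polynomials()` reproduces the calibration pipeline on
synthetic motion capture: per-direction fits initialize a combined
all-direction fit, minimizing unnormalized dynamic-time-warping distances
between reference and simulated marker curves. Two deliberate deviations,
both forced by identifiability analysis on noiseless synthetic data:

* the DTW is *dependent* (all marker components share one warping path).
  With independent per-component warps only curve endpoints are
  identifiable for monotone profiles, so the linear/quadratic coefficient
  split cannot be recovered in principle;
* the cost includes the rigid 60 mm marker triangle in addition to the
  plate marker. With the plate marker alone the rotational joint split is
  unidentifiable (empirically 30-170 % coefficient error at numerically
  negligible cost);
* each stage runs a factorial grid scan followed by restarted
  Nelder-Mead. A Hooke-Jeeves pattern search — the obvious first choice —
  demonstrably stalls in the DTW cost's narrow curved valleys within a few
  percent of the optimum.

With these choices the generating coefficients are recovered to well
under 1 % from noiseless synthetic recordings.

## Tracking controller and quasi-static solution

Muscle redundancy is resolved per step by a bounded quadratic program over
the 24 excitation groups (12 per side): weighted tracked-coordinate error
(thorax sagittal rotation and center-of-rotation x-translation, weight 15;
L2-L5 sagittal rotations, weight 1), plus 0.667 times the squared group
excitations and 0.3e-4 times the squared excitation rate, subject to
0 <= e <= 1. The QP is solved exactly by a primal active-set method and is
verified against exhaustive grid search in the tests.

The central numerical finding of this implementation is that **poses and
excitations must be advanced jointly**: at fixed excitations the upright
spine is buckling-unstable (the tangent stiffness has negative
eigenvalues), so "solve statics, then update muscles" is ill-posed — the
system is only stable in closed loop, as it is in a forward-dynamic
simulation with an active controller. Each quasi-static iteration therefore linearizes the force
balance, eliminates the pose step through the (finite-difference) tangent
stiffness, solves the tracking QP for the excitation step on the
eliminated sensitivities, and applies both under a trust region with a
merit test (scaled force residual plus weighted tracking error). A state
is accepted as static when the net wrench on every dynamic body is below
0.5 N and 0.05 Nm and the excitations are stationary. Because the model is
mirror-symmetric and all tracked coordinates are mirror-even, paired
left/right sensitivity columns are averaged; this removes
finite-difference noise that would otherwise excite the soft
left-minus-right excitation direction (which is restrained only by the
excitation penalty).

A transient path (`step()`) provides first-order implicit (backward
Euler) integration with a 0.01 s step cap; since all rigid couplings are
composed kinematically there are no bilateral constraint multipliers. The
protocols below use the quasi-static path.

### Protocols

Settling ramps gravity under controller action, performs a 2 deg thorax
excursion and return, and stores the result as the upright reference
(alpha_y = 0); the excursion demonstrably leaves every disc at or below
the pre-excursion pressure. Load cases ramp the thorax target in <= 5 deg
increments (distributed over the vertebral targets by the validation
rhythm, default R5) and then the external load along a smoothstep with
increments scaled to the applied moment. The hand load acts vertically at
a thorax-fixed point whose lever from the origin equals the tabulated
value in the target posture. The maximum-isometric-extension calibration
applies a thorax-fixed horizontal force at T7 (700 N at -10 deg, 870 N at
+10 deg) with gravity off and checks that tracking stays within 1 deg
without any group saturating.

## Known limitations and behaviors to be aware of

* **Recruitment branch multiplicity.** The closed-loop fixed point is not
  unique: independently settled runs can land on different, equally
  converged recruitment patterns (e.g. ligament-like co-contraction vs an
  IAP-assisted abdominal strategy) with intradiscal pressures differing
  by tens of percent. Comparisons between conditions should therefore
  share one settled reference, as the bundled experiment functions do.
  Local rather than global optima are an acknowledged property of
  optimization-driven muscle recruitment in general.
* **Co-contraction level.** Enforcing the vertebral rhythm targets on the
  synthetic geometry recruits noticeable antagonist co-contraction, so
  absolute intradiscal pressures run higher than the in vivo range
  (upright L4/5 about 2 MPa rather than about 0.5). Relative changes
  across postures and loads behave physiologically. At near-zero hand
  loads the controller trades stabilizing co-contraction against the
  external moment, which can transiently lower IDP by a few percent; the
  monotone IDP-versus-load property holds in the load-dominated regime
  (40 N and beyond).
* **Resting-tone sensitivity.** The 0.1 % tone acts on the total maximum
  isometric force of all 258 fascicles (about 59 kN), i.e. a compressive
  preload of roughly 60 N against an upright disc load of about 450 N:
  removing the tone shifts the caudal IDPs by several percent. This is a
  property of the synthetic muscle inventory's aggregate strength, not of
  the tone rule.
* **Abdominal co-activation.** Like other purely optimization-driven
  recruitment schemes, the controller has no explicit abdominal
  co-activation target, so the intra-abdominal pressure stays near its
  offset in most flexed postures and rises mainly when abdominal groups
  are recruited as agonists.
* The thorax is one lumped body; the pelvis is stationary (no lumbopelvic
  rhythm); breathing and abdominal-wall deformation are not modeled.

## Problem sizes used in checks

The shipped tests and the acceptance script run entirely on the synthetic
spine at its default desk scale: 81 elements per disc with reduced
integration, 258 fascicles, 30 rigid degrees of freedom. Settling takes on
the order of ten seconds and a full 13-case validation sweep a few
minutes on one CPU. The coefficient-recovery check uses 40/30/25/20-sample
motion profiles for the four directions.
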