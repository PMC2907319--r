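---
title: "Models and methods behind stemstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stemstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemstab)
```

# The measurement problem

An in-vitro primary-stability test loads a femoral stem implanted in a
(composite) femur with cyclic hip-contact and muscle forces and asks two
questions about the implant-bone interface: how far the stem *migrates*
(permanently) and how much it *moves reversibly within each load cycle*
(micromotion). Both are tiny — micrometres and millidegrees — so the motion
is measured by an array of six single-axis displacement sensors (LVDTs)
watching a rigid target plate fixed to the stem, and the six readings are
inverted into a full 6-DOF pose of the implant relative to the bone.

stemstab implements that entire chain in software: the loading rig, the
specimen's mechanical response, the sensor array, the pose inversion, the
migration/micromotion extraction and the cohort statistics, so that every
stage can be validated against known ground truth.

# Coordinate conventions

All poses live in a right-handed femur-fixed frame: **+x medial, +y
anterior, +z distal**, origin at the stem reference point on the lateral
aspect of the stem (113 mm proximal of the stem tip). Rotations are
reported as angles projected in the three anatomical planes — frontal
(about the anterior axis), sagittal (about the medial axis) and transverse
(about the distal/long axis). Positive transverse rotation is anteversion;
retroversion is negative. Summary tables follow the orthopaedic convention
of reporting *lateral* translation, the negative of the core frame's
medial component.

The projected-angle composition order is fixed and documented: `R =
Rz(transverse) Rx(sagittal) Ry(frontal)` (extrinsic). At the sub-degree
rotations of a stability test any fixed order differs from any other by
less than 1e-5 degrees; fixing one makes
`projected_angles_from_rotation()` the exact inverse of
`rotation_from_projected_angles()`, which the tests verify to 1e-9
degrees. The *total rotational* resultant is the rotation angle about the
helical (screw) axis, `acos((trace(R) - 1) / 2)` — the one rotation
magnitude that is independent of the projection convention.

# The loading rig

Loads are expressed in multiples of body weight (BW; 75 kg, g = 9.81, so
735.75 N). The program is three sequential 1000-cycle phases of 1 Hz
sinusoids with in-phase peaks: the cranial-caudal hip contact force F_cc
swings 0.4–2.3 BW in every phase, while the anterior-posterior component
F_ap is 0, then −0.1 to +0.3 BW (walking), then −0.1 to +0.6 BW (stair
climbing). F_ap is applied as an actuator torque M = F_ap · d_off about
the head offset d_off. Each load traces
`min + (max − min)(1 + sin(2πft − π/2))/2`, so every cycle starts at its
minimum and all loads peak together mid-cycle; with an even number of
samples per cycle the analytic extrema are sampled exactly.

Without the abductor, the femur is potted at 13° of adduction and the
vertical actuator force is the hip contact force: at 13° to the femur
axis it decomposes into 2.2 BW axial and 0.5 BW medial-lateral components
(`decompose_frontal(2.3, 13)`).

With the abductor, a hinged lever presses on the femoral head at offset
d_off from the actuator axis while an abductor cable pulls at lever arm
d_m lateral of the head; fixing d_off = 0.83·d_m keeps the force ratios
identical across specimens (d_m of 46–49 mm gives d_off of 38–41 mm). The
planar free-body model in `lever_equilibrium()` closes with three
equations: lever vertical force balance, lever moment about the head
contact, and the femur's frontal-plane horizontal balance (the distal pot
rides a linear guide, so the head and cable forces alone must cancel
horizontally). The cable angle from vertical is a geometry parameter; its
default, 19.25°, was chosen once so that with the femur potted at 4° of
abduction the hip contact force again runs at 13° to the femur axis. The
resulting force ratio F_abd/F_cc is 0.475, within a percent of the
nominal 1.1/2.3 = 0.478, and every returned solution is re-inserted into
the balance equations (residual below 1e-9). The ~1° actuator rotation
observed during stair climbing can be emulated as a perturbation of the
cable angle; it is off by default.

# Sensor array and pose recovery

Each LVDT is an ideal point contact with a *fixed* measurement axis (the
axis does not rotate with the plate — standard frame-mounted metrology;
at rotations under 1.2° the cosine error is below 2e-4). The default
geometry is a documented stand-in: a 25 mm equilateral triangular plate
centred on the reference point carrying the classic 3-2-1
exact-constraint layout (three sensors normal to the plate along the
medial axis, two along the distal axis, one along the anterior axis). Its
6×6 small-displacement Jacobian — translations in µm, rotation vector in
mrad — has condition number ≈ 29.

Pose recovery is Gauss-Newton on the six pose parameters (translation +
rotation vector; the rotation-vector parameterisation avoids projection
degeneracies inside the solver), seeded by the linearized solve and
iterated to a residual of 1e-9 µm (two to four sweeps in practice, since
the problem is nearly linear over the study envelope). No smoothing or
filtering happens in recovery — the inverse map is deterministic; noise
handling belongs to the metrics stage. On noise-free synthetic readings
the round trip is exact to well below 0.01 µm and 1e-5°.

Rotation-error propagation follows the analytic worst-case logic: the
linearized inverse maps the hypercube of per-sensor errors (±e) to poses;
because the map is linear, the maximum helical rotation is attained at
one of the 2⁶ vertices, so exhaustive enumeration is exact and the bound
scales linearly in e. With the default geometry and the emulated system's
1.7 µm maximum single-sensor error the bound is ≈ 0.012°; the figure is
geometry-specific (a larger plate tightens it), so only its order of
magnitude is comparable across rigs.

# Migration and micromotion

From a recovered pose series sampled uniformly at `samples_per_cycle`
points per cycle:

* **Cycle summaries** — per cycle: the mean of each component, and the
  peak-minus-trough excursion evaluated at the samples of maximum and
  minimum applied F_cc. The cycle's linear drift is removed first, with
  the drift rate estimated from *adjacent cycle means*: a full-period
  sinusoid sums exactly to zero over a cycle, so cycle means carry drift
  alone. (A naive within-cycle least-squares detrend would absorb part of
  the sampled sinusoid — a bias of 6A/(n²−1) per sample, almost 10% of
  the excursion at 32 samples/cycle — which is why it is not used.)
* **Migration** — the difference in cycle-mean pose between cycle 100 and
  the last cycle of each step (cycles 1–100 are pre-conditioning);
  rotations are differenced as projected angles in the small-angle
  regime. Migration is cumulative and exactly additive over consecutive
  steps.
* **Micromotion** — the mean signed detrended peak-minus-trough excursion
  over each step's last 200 cycles. Whether "cyclic amplitude" means the
  full excursion or half of it is a genuine reading ambiguity; the full
  peak-to-trough reading is the default and a `half-amplitude` mode is a
  config flag.
* **Resultants** — translational totals are Euclidean norms of the three
  translation components; rotational totals are helical-axis angles (for
  migration, of `R(last)·R(100)⁻¹`; for micromotion, the cycle-averaged
  helical angle between detrended peak and trough poses).

The distal-dominance figure (distal migration as a share of the
translational resultant) is computed per specimen, not on group means.

# The synthetic specimen

No constitutive model of the bone-implant interface is given by the
physical experiments this package emulates, so the generator uses the
simplest model exhibiting the observed phenomenology:

* **Elastic response** — pose = C·(F_cc, F_ap, F_abd) with a 6×3
  compliance matrix, plus a threshold term C_x·max(F_ap − 0.3 BW, 0).
  The threshold term is needed because the transverse micromotion of the
  no-abductor group is strongly nonlinear between walking and
  stair-climbing torque (−6 vs −61 mdeg); physically it represents
  torque overcoming interface friction. With C_x = 0 the model reduces
  exactly to a linear compliance law.
* **Ratcheting drift** — each cycle adds
  `(base + gain · att · max(F_ap,peak − 0.3, 0)^e) · exp(−k/τ)` per
  component, with k the cycle index within the phase (drift settles
  exponentially within each step, τ = 300 cycles) and `att` the abductor
  attenuation applied to the load-excess gain only — so groups separate
  only above the F_ap threshold, which is exactly the observed
  interaction structure.
* **Noise** — i.i.d. Gaussian per sensor per sample, sd 0.5 µm, below
  the 0.7 µm resolution of the emulated measurement system (the only
  printed noise figure).
* **Cohort variability** — independent mean-one lognormal multipliers
  (sdlog 0.3) per specimen on the compliance and ratchet parameters.
  The true between-specimen covariance is unknowable from published
  summary tables; this assumption is recorded in the cohort manifest.
  sdlog 0.3 reproduces the scale of the reported 95% confidence
  intervals (CI half-width ≈ 1.05·sd at n = 6).

`reference_preset()` calibrates one template per group against the
bundled reference summary tables in closed form: compliance columns from
the micromotion rows, ratchet base from the first-phase migration, and
ratchet gain from the stair-climb increment, after removing the elastic
cycle-mean shifts (the calibration is the "tuning script" — it runs at
preset construction and is itself tested). The two groups get separate
templates because they genuinely differ in ratchet *direction* (opposite
transverse migration), which a single attenuation scalar cannot express;
the attenuation mechanism remains available and is exercised by tests
that perturb one template. The calibration places the analytic group
means of the distal and transverse components — migration and
micromotion, both groups, all three F_ap levels — inside the reference
95% CIs. Of the remaining components, all but one (anterior migration of
the no-abductor group at 0.3 BW) also land inside their intervals; the
second-phase means are not free parameters once the first and third
phases are matched, so this is the expected residual of a two-parameter
drift law. The preset is frozen with master seed 20100624; per-specimen
seeds derive from the master seed by fixed arithmetic hashing.

`programmed_step_metrics()` computes, in closed form, the metrics a
noise-free pipeline run should extract (geometric sums of the settling
drift, elastic excursions at the load extrema). It is the ground-truth
oracle for the simulate → recover → metrics round trip, and it doubles as
a fast metric-level cohort sampler (`sample_cohort_metrics()`) for
simulation studies — type-I error over hundreds of null cohorts, seed
sweeps of the qualitative pattern — where re-running the already
validated sensor chain hundreds of times would add nothing. The full
sensor-level chain is itself exercised end-to-end on whole cohorts in
the tests and the acceptance script.

# Statistics

`split_plot_anova()` computes the mixed two-factor ANOVA from first
principles on a balanced cohort: the abductor group is tested against
specimen-within-group variation (df 1, 10 at n = 6), the repeated F_ap
factor and the group × F_ap interaction against the specimen × F_ap
residual (df 2, 20). The SS decomposition is conserved to 1e-9 and the
implementation is cross-checked in the tests against R's stratified
`aov(Error(specimen/fap))` on the same data. Sphericity is assumed (not
corrected) by default, matching the unadjusted repeated-measures analysis
being reproduced; a Greenhouse-Geisser option exists. Unbalanced tables
raise an explicit error rather than being silently approximated.

Post hoc comparisons are Student-Newman-Keuls: means are ordered and the
observed studentized range of each span is compared to a critical value
that shrinks with the span; ranges that fail are homogeneous and protect
their inner pairs. Studentized-range probabilities are computed by the
package's own nested numerical quadrature (`ptukey_range()`, with
quantiles by root bracketing), validated against R's independent
implementation to 1e-4. Because the reference annotations mark group
differences *at* each F_ap level and level differences *within* each
group, SNK runs as simple effects: levels within group against the
within-subject error, and groups within level against the mixed error
`(MS_subjects + (b−1)·MS_error)/b` with Satterthwaite degrees of freedom.

"Significance level of 95%" is read as α = 0.05 throughout.

# Problem sizes and numerical choices

Default runs use 6 specimens per group, 3 × 1000 cycles, 32 samples per
cycle (96 000 samples per specimen) — a full cohort simulates, recovers
and analyses in well under two minutes. Pipeline-level unit tests use
reduced sizes (300-cycle phases, 8–16 samples per cycle), which preserve
every structural property; simulation studies use 500 null cohorts
(type-I error, binomial SE ≈ 1%) and 30-seed sweeps for the qualitative
pattern. Key tolerances: rotation orthogonality 1e-9; pose-recovery
residual 1e-9 µm, cap 50 iterations; equilibrium residual 1e-9;
studentized-range quadrature 1e-8 relative. Degenerate inputs fail
loudly: rank-deficient sensor geometries report the unconstrained pose
direction, gimbal-degenerate projections, incomplete cycles, unbalanced
ANOVA tables and sub-minimal summary cells all raise named errors.

# What passing tests do and do not show

The synthetic cohort reproduces the *statistical structure* of a real
stability test — settling drift, load-threshold nonlinearity,
between-specimen spread, sensor noise — but not bone-implant contact
mechanics, viscoelasticity, bone flexibility (the stem and femur are
treated as rigid at one measurement location), multi-location motion
fields, or stumbling-magnitude overloads. Agreement of the pipeline with
the generator's ground truth validates the measurement and analysis
chain, not any biomechanical prediction; empirical migration magnitudes
from physical specimens enter only through the reference summary tables
the preset is calibrated to.
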