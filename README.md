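# stemstab

Simulation and analysis of in-vitro primary-stability tests of
cementless femoral hip stems, for biomechanics researchers who design
or evaluate such tests. Primary stability — the immediate post-operative
fixation of a press-fit stem — is quantified by **migration** (the
permanent implant-bone displacement accumulated over load cycles) and
**micromotion** (the reversible cyclic displacement within a load
cycle), both measured at micrometre / millidegree scale by a six-LVDT
array watching a target plate on the stem.

The package implements the full measurement and analysis chain as
testable software:

* **Rigid-body kinematics** — poses in a femur-fixed frame
  (+medial, +anterior, +distal), anatomical-plane projected angles, and
  the helical-axis rotation angle
  `θ = acos((tr(R) − 1)/2)` used for rotational resultants.
* **Loading rig statics** — the three-phase sinusoidal load program
  (cranial-caudal hip contact force F_cc = 0.4–2.3 BW; anterior-posterior
  component F_ap = 0 / walking / stair-climbing; torque `M = F_ap·d_off`)
  and the planar equilibrium of the abductor lever
  (`d_off = 0.83·d_m`, abductor force F_abd = 1.1 BW).
* **Sensor forward model and pose recovery** — six fixed-axis point
  sensors; Gauss-Newton inversion of readings into the 6-DOF pose;
  exhaustive vertex enumeration of the worst-case rotation error.
* **Motion metrics** — migration between cycle 100 and each step's last
  cycle; micromotion as the drift-detrended peak-to-trough excursion
  averaged over each step's last 200 cycles; Euclidean and helical-axis
  resultants.
* **Synthetic cohorts** — specimens with elastic compliance, a torque
  threshold nonlinearity, exponentially settling ratchet drift,
  lognormal between-specimen variability and Gaussian sensor noise; a
  preset calibrated in closed form against bundled reference summary
  tables.
* **Statistics** — split-plot ANOVA (between: abductor group; within:
  repeated F_ap level) computed from first principles, with
  Student-Newman-Keuls post hoc comparisons using the package's own
  studentized-range quadrature.

## Worked example

```r
library(stemstab)

## the hip contact force at 13 deg to the femur axis
decompose_frontal(2.3, 13)
#>          axial_xBW medial_lateral_xBW
#>          2.2410511          0.5173874

## abductor-lever equilibrium at the reference geometry
g2 <- reference_geometry(abductor = TRUE)
probe <- lever_equilibrium(g2, body_weight_newtons())
eq <- lever_equilibrium(g2, 2.3 / probe$F_head_xBW * body_weight_newtons())
c(F_cc = eq$F_head_xBW, F_abd = eq$F_abd_xBW,
  angle = eq$head_angle_to_femur_deg)
#>      F_cc     F_abd     angle
#>  2.300000  1.091344 13.000166

## full pipeline on the calibrated synthetic cohort (~45 s)
run_pipeline(default_config(), "results_run")
pipeline_report("results_run")
#> == migration_distal_um == (excerpt)
#>   abductor     Fap 0.6:  200.8 +/- 69.7
#>   no_abductor  Fap 0.6:  390.4 +/- 92.6
#> == total_trans_migration_um ==
#>   ANOVA: group p=0.0988, fap p=4.19e-13, interaction p=4.6e-08
```

The excerpt shows the pattern the synthetic preset is calibrated to
reproduce: distal migration roughly doubles without the abductor under
stair-climbing torque (means fall inside the reference 95% confidence
intervals, 385 ± 147 µm and 191 ± 123 µm), while the abductor × F_ap
interaction is strongly significant even though the group main effect on
translational migration is not.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/stemstab.R run-all --out results_run --seed 7
```

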