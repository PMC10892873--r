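# spineval

Concurrent validation of instrumented spine motion measurement against an
optical motion-capture reference.

## What problem this solves

Training mannequins for spinal motion restriction (the techniques used to
immobilise suspected spinal-cord-injury patients during transfer) can carry
an instrumented spine: each segment — cervical (head relative to trunk) and
lumbar (trunk relative to pelvis) — is a serial chain of four encoder-read
revolute joints (two flexion, one lateral flexion, one axial rotation).
Before such a device can be trusted for training feedback or research, its
orientation measurements must be validated against a gold-standard
optoelectronic system. `spineval` implements that entire analysis for
biomechanics and simulation-engineering users:

* **Forward kinematics** — Denavit–Hartenberg chains
  (`T_i = Rot_z(θ_i) Rot_x(α_i)`, translation `(a cosθ, a sinθ, d)`)
  converting the four encoder channels into the segment's relative
  orientation, with both packaged chains neutral-identity at zero angles;
* **Calibration** — encoder zeroing from a static neutral window, and
  estimation of the constant frame rotations between the two systems by
  minimising the mean squared relative-rotation angle over a
  combined-motion trial;
* **Preprocessing** — slerp resampling, cross-correlation time
  synchronisation on the dominant anatomical plane, 120°/s outlier
  flagging, and 0.2 s-window slerp repair of occlusion artefacts;
* **Agreement statistics** — RMSE with interpretation bands
  (good ≤ 2° < acceptable ≤ 5° < tolerable ≤ 10°), Bland–Altman bias and
  95% limits of agreement (`bias ± 1.96 SD` of differences, Shapiro–Wilk
  screened), parallel-forms reliability with `SEM = SD·√(1−r)` and
  `MDC95 = 1.96·√2·SEM`, and a one-sided non-inferiority t-test of motion
  speed at α = 2.5%;
* **A synthetic study generator** — the full 80-trial, two-segment,
  four-condition, two-speed design with encoder quantization (0.0219°),
  mocap noise, occlusion bursts near amplitude extremes, unknown time lag
  and frame offsets, all recorded in a ground-truth ledger so every
  pipeline stage is testable without laboratory recordings.

See `vignettes/spine-validation-methods.Rmd` for the model, parameter
defaults and design decisions.

## Worked example

```r
library(spineval)

# encoder angles -> anatomical orientation
chain <- spine_chain("cervical")
T <- forward_kinematics(chain, c(10, 20, 5, 0))   # degrees, joints 1-4
global_rotation_angle(matrix_to_quaternion(T[1:3, 1:3]))
#> [1] 26.896
decompose_anatomical(T[1:3, 1:3], chain$convention)
#>    flexion lateral_flexion rotation degenerate
#> 1 24.66569        4.208543 9.079467      FALSE

# a reduced synthetic study, end to end
study  <- generate_study(study_design(reps_per_condition = 2, seed = 1),
                         noise_model())
report <- run_study(study, study_options(seed = 1))
print(report)
#> Agreement report: 16 trials analyzed, 0 discarded (of 16)
#>
#> Root-mean-square error (deg):
#>   segment           plane mean_rmse sd_rmse band n_trials
#>  cervical          global       0.1       0 Good        8
#>  cervical         flexion       0.1       0 Good        8
#>  ...
#> Non-inferiority of fast vs slow motion (global RMSE):
#>   segment mean_diff threshold  t_stat p_value reject_h0
#>  cervical     0.010      0.21 -25.131   0.000      TRUE
#>    lumbar     0.053      0.19  -5.602   0.006      TRUE
```

The joint angles `(10, 20, 5, 0)` mean: 10° axial rotation, 20° on the
first flexion joint, 5° on the second, none lateral — hence ~25° flexion
with the rotation partially redistributed by the non-commuting
decomposition, and a 26.9° global (axis-free) rotation. In the report, an
RMSE of 0.1° across all planes is the pipeline floor for the default
synthetic noise (0.2° mocap jitter, 0.0219° quantization): both systems'
anatomical angle traces agree to within band "Good", the limits of
agreement stay within ±0.3°, and the non-inferiority test rejects the
hypothesis that fast motion degrades accuracy by more than the minimal
detectable change.

A thin command-line wrapper lives at `inst/cli/spineval-cli.R`
(`simulate` / `analyze` verbs over a study directory).

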