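---
title: "Methods: validating instrumented spine motion against optical capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating instrumented spine motion against optical capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineval)
```

## The measurement problem

A training mannequin for spinal motion restriction carries an instrumented
spine: each segment (cervical = head relative to trunk, lumbar = trunk
relative to pelvis) is a serial chain of four revolute joints -- two in
flexion, one in lateral flexion, one in axial rotation -- each read by a
magnetic encoder with a 0.0219° grid. Encoder angles are not clinically
meaningful by themselves; they must be converted into the relative
anatomical orientation of the segment. Validating that conversion against
an optoelectronic reference system is the purpose of this package: forward
kinematics, cross-system calibration, stream preprocessing, and the
agreement statistics, exercised end to end on a synthetic study whose
ground truth is known exactly.

## Kinematic model

Each segment is described in the Denavit–Hartenberg convention: link $i$
carries four parameters $(a_i, \alpha_i, d_i, \theta_i)$ and contributes

$$T_i = \mathrm{Rot}_z(\theta_i)\,\mathrm{Rot}_x(\alpha_i)
\;\big|\; t_i = (a_i\cos\theta_i,\, a_i\sin\theta_i,\, d_i),$$

with the end effector relative to the base given by the ordered product
$T = T_1 T_2 \cdots T_n$. One presentation of this matrix in circulation
prints the $(2,3)$ element as $-\cos\alpha_i\sin\alpha_i$; the form
implemented here is the standard $-\cos\theta_i\sin\alpha_i$, which is the
only one consistent with $R = \mathrm{Rot}_z(\theta)\mathrm{Rot}_x(\alpha)$.

The two shipped chains (in `inst/extdata/chains/`) have a useful analytic
property, enforced as a hard test: at the all-zero joint configuration the
relative orientation is exactly the identity. The cervical chain achieves
this with a fifth, fixed virtual frame. A second property follows from the
chain structure: each joint moved alone produces a rotation about one fixed
axis whose magnitude equals the encoder angle. In the shared base frame
those axes are $z$ (axial rotation, joint 1), $-y$ (the two flexion joints)
and $x$ (lateral flexion). Link lengths $r_1, r_2, r_3$ are not published;
they default to 1 unit and affect only translation, never the orientation
that the whole analysis is built on -- also enforced as a test.

### Anatomical angles and their convention

Orientations are carried as scalar-first unit quaternions canonicalised to
$w \ge 0$. Two summaries are derived: the *global* rotation angle
$2\arccos|w|$, an axis-free range-of-motion score, and the *anatomical*
decomposition into flexion / lateral flexion / axial rotation. The source
material never states which Euler sequence realises "anatomical planes", so
the sequence is configuration, not a constant:
`anatomical_convention()` defaults to intrinsic flexion ($-y$) → lateral
flexion ($x$) → rotation ($z$), chosen to match the chains' joint axes so
that a pure single-joint motion reads as a pure single-plane angle. Within
0.5° of the middle-angle singularity (gimbal lock) the split is degenerate;
samples there are flagged (`degenerate = TRUE`) rather than silently
resolved, and excluded from recomposition guarantees.

## Calibration

Two constants link the systems:

* **Encoder zeros** — per-channel means over a quasi-static neutral window
  (≥ 0.5 s; stillness is checked on a 0.1 s stride so single-step
  quantization flicker is not mistaken for motion; limit 2°/s).
* **Frame alignment** — constant rotations $q_b$ (reference side) and $q_s$
  (body side) minimising the mean squared global angle between
  $q_b\, q_{\text{man}}(t)\, q_s$ and $q_{\text{ref}}(t)$ over one
  combined-motion trial per segment that excites all three planes (≥ 5° per
  plane enforced; less is ill-conditioned). The cost is smooth in the two
  rotation-vector parameters (6 dimensions, optionally +4 encoder-zero
  corrections), so BFGS with 8 seeded random restarts (±20° rotation
  vectors) is deterministic and reliable. Uniform sample weighting is the
  default; a neutral-weighted option
  ($w = e^{-(\theta_{\text{global}}/10^\circ)^2}$) exists because occlusion
  artefacts concentrate at amplitude extremes, making the neutral
  neighbourhood the more trustworthy region.

Whether the original analysis refined encoder zeros, model offsets, or only
frame rotations is not documented; both modes are provided
(`refine_encoder_zero`), neither asserted as canonical.

## Preprocessing

* **Resampling** to a common rate by slerp; a resampled point is valid only
  if both bracketing samples are (grid hits inherit the hit sample's
  validity).
* **Synchronisation** by normalised cross-correlation on the anatomical
  channel with the largest range of motion, over integer-sample shifts
  within ±2 s. Each trial starts with one second of neutral pose, which is
  enforced as *stillness* (not identity -- the reference stream carries the
  constant frame offsets even at rest). Sub-sample refinement is
  deliberately absent: at the rates involved, one sample (≤ 10 ms) is below
  any effect of interest.
* **Outlier detection**: instantaneous global velocity above 120°/s flags
  both samples bounding the step. All genuine mannequin motion is designed
  (and verified) to stay below this; only occlusion jitter crosses it.
* **Repair**: sliding 0.2 s windows with 50% overlap; a flagged sample
  covered by at least one window with < 50% flags is slerp-interpolated
  from its nearest clean neighbours and revalidated; denser corruption
  stays invalid. A sample is repaired if *any* containing window qualifies
  -- the rule's source names a "time span" without specifying the tiling,
  and the any-window reading is the more permissive of the two, erring
  toward reconstructing isolated noise while still refusing bursts.

A trial is **discarded** (with a recorded reason, never silently) when a
contiguous invalid span exceeds 1 s after repair or more than half its
samples are invalid. The quantitative rule is this package's own: the
motivating study reports discarding five trials for "prolonged loss" of a
rigid body without defining prolonged. Ordinary occlusion bursts (~0.15 s)
fall far below it; the synthetic prolonged-dropout injection (2 s) far
above.

## Agreement statistics

With $x_1$ the mannequin trace and $x_2$ the reference trace (per plane,
plus global):

* $\mathrm{RMSE} = \sqrt{\tfrac1n\sum_i (x_{1,i}-x_{2,i})^2}$, interpreted
  against the bands good ≤ 2° < acceptable ≤ 5° < tolerable ≤ 10° <
  unbearable (boundaries inclusive on the left band).
* **Bland–Altman**: bias = mean difference, limits of agreement
  $\pm 1.96\,\mathrm{SD}$ of differences; Shapiro–Wilk $W$ with the
  reporting convention $W > 0.96$ as a *soft* gate — approximately normal
  differences still support descriptive limits, so a low $W$ warns rather
  than aborts. Ten points are sampled per trial (uniform, without
  replacement, seeded) so fast and slow trials carry equal weight.
* **Reliability → SEM → MDC**: the two systems are parallel forms;
  $r$ = Pearson correlation of their sampled scores, SD = sample SD of the
  pooled motion scores (this is the reading consistent with published
  score-spread magnitudes of 10–25°, as opposed to the SD of differences),
  $\mathrm{SEM} = \mathrm{SD}\sqrt{1-r}$,
  $\mathrm{MDC}_{95} = 1.96\sqrt{2}\,\mathrm{SEM}$. These are the standard
  forms; the construct source names the quantities without printing
  formulas, and the forms reproduce the recomputable published cells at
  one-decimal half-up rounding. Published tables rounded to one decimal are
  not all mutually consistent under these formulas, so full-table
  reproduction is not asserted anywhere in the package.
* **Speed non-inferiority**: one-sided two-sample t-test (Welch by default;
  pairing is a flag, since the original pairing is undocumented) of
  $H_0: \overline{\mathrm{RMSE}}_{\text{fast}} -
  \overline{\mathrm{RMSE}}_{\text{slow}} \ge \delta$ at $\alpha = 2.5\%$,
  with $\delta$ defaulting to the segment's computed global MDC₉₅.
  Rejection means speed has no practically relevant effect on accuracy.

## The synthetic study and what it does (not) show

`generate_study()` reproduces the validation design: 2 segments × 4
conditions (flexion, lateral flexion, rotation, combined) × 10 repetitions
(5 fast at 1 s/cycle, 5 slow at 4 s/cycle), 3 cycles per trial, one second
of neutral prefix, one combined calibration trial per segment — 80
measurement trials. Defaults the design's source does not state, chosen
once as field-realistic and not revisited:

| parameter | default | rationale |
|---|---|---|
| waveform | raised cosine $\tfrac{A}{2}(1-\cos 2\pi t/T)$ | C¹, starts/ends neutral; cycles specified, waveform not |
| amplitude | 40° slow / 15° fast | keeps true peak velocity ($A\pi/T$ per plane) below the 120°/s outlier rule at both speeds |
| encoder rate / mocap rate | 100 / 120 Hz | typical encoder logging; PrimeX-class camera default |
| encoder quantization | 0.0219° | the encoder's claimed precision |
| mocap rotational noise | 0.2° RMS per sample (white) | optical rigid-body jitter scale; keeps baseline velocity noise below the outlier rule |
| inter-system lag | 0.25 s | unremarkable trigger offset, inside the ±2 s search |
| frame offsets | 7° about $z$ (base), 4° about $x$ (sensor) | few-degree mounting/ground-plane error |
| encoder zero offsets | SD 0.3° per segment | residual jig-zeroing error |
| occlusion bursts | p = 0.3 per peak excursion, 0.15 s, 5° jitter | "noise-like oscillations near maximum amplitude" |

The amplitude/velocity tension is worth stating: at fast speed a large-ROM
trial can legitimately exceed 120°/s, colliding with the outlier rule. True
amplitudes are unpublished; the generator caps true peak velocity below
threshold (hence the smaller fast amplitude) and `generate_trajectory()`
warns when a requested design breaks the cap. The tension is documented,
not resolved.

What the generator does *not* emulate: marker-level optics (it corrupts
orientations directly, not marker triangulation), soft-tissue or mounting
compliance, encoder non-linearity beyond quantization and optional backlash
hysteresis, and temporally correlated mocap noise. Passing tests therefore
demonstrate that the *pipeline* recovers known truth under a plausible
corruption model — not that the physical mannequin meets any accuracy
figure. Published headline accuracy values were computed from laboratory
recordings that are available only on request, and are deliberately not
asserted as targets; with the default synthetic noise the pipeline floor
(RMSE ≈ 0.1°) sits well below them.

## Numerical choices

* Quaternions: scalar-first, canonical $w \ge 0$; `slerp` switches to
  normalised linear interpolation within $10^{-10}$ of parallelism;
  rotation-vector → quaternion uses a series for the sinc term near zero so
  the alignment cost stays smooth at the optimum.
* Matrix → quaternion via Shepperd's largest-pivot branch; inputs are
  validated orthonormal (tolerance $10^{-8}$) with determinant +1.
* The Tait–Bryan decomposition is the generic closed form for all six
  distinct-axis sequences (validated against an independent implementation
  during development; in the test suite, by recomposition over random
  rotations). At gimbal lock the remaining freedom goes to the first angle
  and the third is zeroed, flagged.
* Angles are radians internally, degrees at every API boundary. Report
  tables round half-up to one decimal.
* CSV numerics are written at 15 significant digits, the precision at which
  decimal text round-trips doubles exactly — `write(read(x))` is
  byte-identical for canonical files (reading skips renormalisation for
  this reason).
* Full-scale analyses in the tests and the acceptance script use the
  default 80-trial design at 100 Hz; component Monte-Carlo checks use 50 Hz
  and 20 seeded replicates, sizes at which every sampling band in the test
  suite is stable across seeds.

## Known limitations

* Per-plane RMSE compares Euler angles decomposed with one shared
  convention for both systems; a laboratory using a different sequence will
  get different per-plane (not global) numbers.
* The alignment cost assumes the lag is constant within a trial; clock
  drift between systems is not modelled.
* Gimbal-flagged samples are excluded from recomposition guarantees but not
  from RMSE pooling; with the default convention and realistic spine ROM
  the middle angle never approaches 90°.
* The non-inferiority threshold defaults to the *computed* global MDC of
  the same data, mirroring the validation protocol's circularity; a
  pre-registered margin can (and for inference, should) be supplied via
  `study_options(ni_threshold = ...)`.

## Reproducing a full analysis

```{r, eval = FALSE}
library(spineval)
study <- generate_study(study_design(seed = 1), noise_model())
report <- run_study(study, study_options(seed = 1))
print(report)
write_report(report, "results/report")
```

`scripts/acceptance.R` runs exactly this, plus the worked examples and the
parameter-recovery checks, and writes the resulting numbers to JSON.
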