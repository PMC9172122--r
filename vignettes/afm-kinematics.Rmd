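---
title: "Multi-segment foot kinematics with afmkin: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-segment foot kinematics with afmkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmkin)
library(dplyr)
```

## The model

`afmkin` implements the Amsterdam Foot Model (AFM), a marker-based
multi-segment foot model for clinical gait analysis. The foot and lower leg
are described as rigid segments — shank, hindfoot (calcaneus), midfoot
(navicular, cuboid, cuneiforms), forefoot (metatarsals, optionally split
into a medial and lateral part around the second ray) and hallux — each
carrying an anatomical coordinate system built from palpable landmark
markers (`afm_markers()`, `afm_segments()`). Axes follow the ISB
convention: x anterior, y superior, z to the right in anatomical position.

Several axes are deliberately defined through *midpoints* of marker pairs
(the CALD/CALP midpoint for the hindfoot, the four metatarsal base/head
midpoints for the forefoot). Averaging two markers halves the orientation
error produced by misplacing either one, which is the model's central
robustness idea and the property the sensitivity module quantifies.

Joint angles for the seven model joints (`afm_joints()`) are the Cardan
z–x′–y″ ("floating axis") decomposition of the rotation from the proximal
to the distal anatomical frame: first about the proximal medio-lateral
axis (sagittal, dorsiflexion positive), then about the floating
anterior-posterior axis (frontal, inversion positive), last about the
distal vertical axis (transverse, internal rotation at the ankle and
adduction distally, positive). `cardan_zxy()` and its inverse
`rot_frame()` implement the pair; the compose–decompose round trip is
exact to well below 1e-8 degrees over (−90°, 90°)³.

Two planar arch angles complement the joint angles. The medial
longitudinal arch angle (MLA) is the angle at the navicular between the
floor-projected calcaneus point CAp and the floor-projected first
metatarsal head HM1p; a *larger* MLA means a *flatter* arch. The
transverse tarsal arch angle (TTA) is the angle between the BM1→BM2 and
BM2→BM5 vectors. We read "the vector between A and B" literally as B − A;
the complementary orientation would change the value to its supplement,
so the choice is recorded here and in `tta_angle()`.

### Tracking and calibration

During walking only a subset of markers is retained: segments are tracked
through three-marker technical frames (shank TT/ASHN/LSHN, hindfoot
CALD/ST/PT, forefoot BM1/HM2/BM5) chosen to avoid the markers with the
largest soft-tissue artifacts (lateral malleolus, proximal calcaneus).
`afm_calibrate()` averages a static standing trial, expresses each
anatomical frame in its technical frame, fixes CAp to the hindfoot and
HM1p to the forefoot, and measures calcaneal length (CALP to the ST/PT
midpoint). `reconstruct_frames()` rebuilds the anatomical frames each
frame; midfoot, medial/lateral forefoot and hallux are recomputed directly
since none of their markers is static-only. The technical frame is the
deterministic three-marker construction, which is exactly invertible on
rigid data (the calibration round trip is below 1e-9); a least-squares
(Kabsch) pose fit over the tracking markers is available with
`tracking = "least_squares"` for noisy data.

When the static trial is recorded without full foot contact the
floor-projected CAp is not meaningful; `cap_fallback()` substitutes a
reference position per unit calcaneal length. The packaged default
(`afm_cap_reference()`) is derived from the synthetic template foot and is
clearly labeled as synthetic, not population-based: laboratories with
their own reference data should pass their own ratio.

### Left feet

The published left-foot formulas flip the order of specific cross-product
subtractions. Algebraically this is identical to reflecting the marker set
across the lab sagittal plane and applying the right-foot formulas
(cross(Ma, Mb) = −M cross(a, b) for a reflection M), which is how the
package implements it. The consequence — verified by test, exact to
1e-9 — is that a mirrored left foot reports *identical* angle curves with
the clinical sign convention (dorsiflexion, inversion, adduction positive)
preserved on both sides.

### Resolved ambiguities in the segment definitions

Two printed formula cells are self-referential and were resolved from
their prose descriptions: the shank frame is built by projecting the
tibial tuberosity onto the quasi-frontal plane through the malleolar
midpoint, LM and FH (then Y toward the projection, X = Y × (LM − O), Z
completing), and the hallux medio-lateral axis is the right-handed
completion Z = X × Y of X = HLX − HM1 and Y = Z_medial-forefoot × X. With
a single hallux marker the hallux frontal plane is not observable; it is
computed internally but omitted from all outputs. All constructions are
re-orthonormalized through `build_frame()`: the primary axis is kept
exactly, the secondary vector fixes its plane, the third axis is the
normalized cross product.

## Gait events and normalization

`detect_gait_events()` follows the foot-velocity idea: the vertical
velocity of the CALD/HM2 midpoint (the foot center), low-pass filtered
with a zero-phase Butterworth filter (order 2 run forward and backward,
7 Hz default), shows one ascent and one descent lobe per swing. Toe-off
is placed at the start of the ascent lobe and initial contact just after
the end of the descent lobe; lobes must exceed a peak speed (100 mm/s
default) so standing trials produce zero events, and a 20 mm/s crossing
threshold fixes the event samples. The exact reference algorithm behind
the published analysis is not reproduced verbatim; this detector is fully
parameterized (markers, cutoff, thresholds, minimum event gap) and its
defaults are validated against the synthetic generator's exact event
times (within one frame at 100 Hz) — agreement with other detectors on
real data should be checked per laboratory. Odd-reflection padding
suppresses the filter's edge transients so trial boundaries do not emit
spurious events.

`normalize_gait_cycle()` resamples each initial-contact-to-initial-contact
interval to 101 points (0–100%, endpoints inclusive) by linear
interpolation, and `stride_average()` takes the pointwise mean.
`angle_rom()` is max − min per stride, averaged over strides.

## Marker-placement sensitivity

`marker_sensitivity()` virtually displaces one marker ±10 mm in 1 mm
steps (21 positions including zero) along the axes of a foot-specific
frame — anterior-posterior (horizontal heel-toe direction),
superior-inferior (lab vertical), medio-lateral — rebuilds the segment's
anatomical frame, decomposes the orientation error against the
undisplaced pose with the same z–x′–y″ sequence, and fits an ordinary
least-squares line per plane. The gradient (deg/mm) is reported as a
magnitude with the signed slope retained; the fit is on signed errors
(fitting absolute errors would bias slopes toward zero). The sequence
used to decompose single-segment orientation errors is not uniquely fixed
by convention; we use the same z–x′–y″ sequence as for joints, which
anyone comparing against other implementations should keep in mind.

On the packaged template foot the structure of the resulting table
reproduces the model's design intent: of the 36 hindfoot records only the
two frontal-plane responses to medio-lateral displacement of CALD/CALP
reach 0.5 deg/mm — the price of defining the clinically important
varus/valgus axis directly from two posterior-calcaneus markers 40 mm
apart — and no forefoot record reaches 1.0 deg/mm, because every forefoot
axis runs through midpoints. A useful closed form: when a marker pair a
distance d apart defines an axis, displacing one marker perpendicular to
the pair tilts the axis by (180/π)/d deg/mm (1.43 deg/mm at d = 40 mm).
On the template this holds exactly for the *mean* of the CALD and CALP
gradients (1.53 and 1.34 deg/mm); the split arises because the displaced
marker also shifts the frame origin by half the displacement, and the
hindfoot anterior axis' downward pitch (the calcaneal-pitch analogue)
couples that shift into the frontal component with opposite signs for the
two markers. On a pitch-free hindfoot geometry both markers match the
closed form within 2%.

Because the displacement axes are tied to the lab vertical and the
heel-toe direction, sensitivity gradients are invariant under
floor-preserving motions of the static trial (yaw and horizontal
translation) — the natural invariance for a standing calibration — and
scale inversely with uniform foot size.

## Two-configuration comparisons

`compare_marker_sets()` computes segment orientation errors and
joint-angle differences between two labeled marker sets of the same foot,
e.g. marker positions with and without soft-tissue displacement. Joint
angles are relative quantities; segment orientations are not, so by
default the best-fit rigid motion between the shared markers is removed
first (`align = TRUE`), making a globally repositioned but undeformed
foot read as zero error. Set `align = FALSE` when both sets are known to
share one coordinate system and the raw frame rotation is wanted.

## Repeatability statistics

For a test–retest design (two placements by tester A, one by tester B:
intra-tester pair A1/A2, inter-tester pair A1/B1), `repeatability()`
computes per subject and angle the two-measurement variability
σ = mean over the gait cycle of |a − b|/√2 (the n = 2 standard deviation
with denominator n − 1; the published description does not state the
denominator, and n − 1 is the conventional unbiased choice), and across
subjects the standard error of measurement SEM = √(mean within-pair
variance d²/2). For curves the SEM is computed per gait-cycle point and
then time-averaged, mirroring the σ computation; pooling each subject's
squared differences over the cycle first is available via
`sem_aggregation = "subject_first"` since the aggregation order is not
fixed by the definition. Group summaries test the σ values with
Shapiro–Wilk at α = 0.05 and report median [IQR] when non-normal, mean ±
SD otherwise — both are always retained. SEM is an agreement statistic:
unlike ICC it does not depend on the between-subject spread, which is
why no reliability coefficients are provided. A Monte-Carlo test with 200
simulated subject pairs (between-subject SD 5°, within-pair error SD 2°)
recovers the 2° error SD within 10% for scalar and curve quantities.

## The synthetic generator

`template_foot()` is a fixed (not random) set of neutral-standing marker
coordinates, anthropometrically plausible for roughly EU shoe size 41 —
about the adult mean in foot-model studies — with the floor at y = 0 and
a 40 mm CALD–CALP spacing; `scale` covers child to large adult
(0.7–1.4). Fixed coordinates make the sensitivity quantities
deterministic and citable.

`synthesize_gait()` prescribes anatomical-frame poses top-down: the
hindfoot is stationary and flat during stance (60% of a 1.1 s stride, a
typical adult value) and swings forward/upward along a smooth
zero-end-velocity profile (1.2 m stride, 45 mm foot lift); the shank pose
realizes the prescribed hindfoot-shank angles; midfoot, forefoot and
hallux follow their prescribed joint curves down the chain; each marker
rides exactly one rigid body. Prescribed curves are sinusoids
`offset + amplitude·sin(2πt/T + phase)` with default amplitudes of 12/4/3°
(hindfoot-shank), 4/3/3° (midfoot-hindfoot), 18°/3° (hallux sagittal and
transverse) — mid-range values for barefoot adult walking — oscillating
about the template's static angles.

One subtlety is inherent to the marker model, not the generator: the
midfoot coordinate system shares BM2 and BM5 with the forefoot, so
nonzero prescribed Lisfranc (FF-MF) motion deforms the NAV/BM2/BM5
triple and the computed midfoot frame no longer equals the prescribed
pose. The default profile therefore keeps the Lisfranc amplitudes at
zero, which makes *every* prescribed curve exactly recoverable — the
central end-to-end property, recovered below 1e-6 degrees noise-free —
while nonzero Lisfranc amplitudes are allowed and flagged
(`truth$exact = FALSE`). Similarly the hallux frontal prescription is
pinned to zero because the model cannot express it.

Perturbations emulate the real error sources: constant per-marker
misplacement offsets (the marker rides its body at a consistently wrong
location, while the returned ground truth stays that of the ideal
model), soft-tissue-artifact style offsets linear in the hindfoot-shank
sagittal deviation from static (enough to exercise the two-configuration
comparison; no claim of physiological fidelity), and seeded isotropic
Gaussian noise. What the generator does *not* emulate: genuine skin
deformation fields, marker occlusion/swap artifacts, soft-tissue
frequency content, or inter-subject anatomical variability — passing
tests demonstrate the correctness of the computations, not the clinical
accuracy of the model on real feet.

## Numerical choices and degenerate inputs

- Angles are reported in degrees, lengths in mm; radians are internal.
- Gimbal proximity (|frontal| within ~1e-6 rad of 90°): transverse is set
  to 0, the z–y rotation folds into sagittal, and the result is flagged.
- Degenerate frames ((anti)parallel axis vectors, angle below 1e-6 rad)
  raise errors naming the segment and markers; a queried-but-absent
  marker is always an explicit error, never a silent zero.
- Frames with missing tracking markers are flagged invalid and propagate
  as `NA` angles; nothing is interpolated.
- The floor plane is y = `floor_y` (configurable for raised walkways);
  "projected on the ground" sets the vertical coordinate to that value.
  Floor-referenced quantities (CAp, HM1p, MLA) are meaningful for a foot
  standing on that floor and are invariant under yaw and horizontal
  translation, not under arbitrary rotations.
- Static averaging is the arithmetic mean over gap-free frames.
- `full_foot_contact` is a user flag; no automatic detection is
  attempted.

## Problem sizes used in the shipped tests

The test-suite and acceptance computations run at desk scale by design:
walking trials of 1–4 strides at 100 Hz (a few hundred frames), 100-seed
noise loops for event robustness, 200 subject pairs for the SEM
Monte-Carlo, and the full 90-record hindfoot+forefoot sensitivity table.
The published repeatability tables from human cohorts are deliberately
not reproduced — they require the original datasets; the package instead
verifies every computational property those tables rest on.

## A worked pipeline

```{r pipeline, eval = FALSE}
syn <- synthesize_gait(n_strides = 3, noise_sd = 0.3, seed = 1)
cal <- afm_calibrate(synthesize_static(), side = "right")
curves <- afm_joint_angles(syn$trial, cal)
events <- detect_gait_events(syn$trial)
norm <- normalize_gait_cycle(curves, events)
angle_rom(norm)
plot_angle_curves(norm)
sensitivity_table(template_foot()) |> autoplot()
```
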