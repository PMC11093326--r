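---
title: "Tracking and geolocating herd animals from a hovering UAV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and geolocating herd animals from a hovering UAV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`herdtrack` implements the data-association, state-estimation and
evaluation layers of a drone-based herd-monitoring system. A detector is
deliberately *not* part of the package: per-frame detections enter as
MOTChallenge-format text files, and a synthetic scenario generator stands
in for real footage so that every component can be exercised and tested
end to end. This vignette records the models, the conventions, and the
design choices that were genuinely open.

## Two-stage association with a stranding area

Tracking-by-detection with purely greedy centre-distance matching loses
identities whenever an animal is occluded for more than a frame or two:
the track dies, and the re-appearing animal is minted a fresh id. The
tracker here runs two greedy passes per frame:

1. **Stage 1.** Detections, processed in descending confidence order, are
   matched to *active* tracks at their predicted centres (last centre plus
   motion vector). The gate radius is size-relative,
   $\kappa\sqrt{wh}$ of the candidate track's last box ($\kappa = 1$ by
   default), so large nearby animals gate wider than small distant ones.
2. **Stranding.** Active tracks that found no detection move to a holding
   buffer — the *stranding area* — with a health counter initialised to
   the lifespan $L_0 = 20$ frames. Each frame they drift by their frozen
   motion vector, simulating the occluded animal's continued movement, and
   lose one health point; at zero health they are terminated and their ids
   are never reused.
3. **Stage 2.** Detections left over from stage 1 are matched against the
   drifted stranded tracks with a wider gate ($\kappa_2 = 1.5\kappa$,
   since drifted positions are less certain). A hit restores the track —
   and its original identity — to the active set. Whatever still remains
   founds new tracks.

The motion vector is an exponential moving average of observed per-frame
centre displacements ($\alpha = 0.5$), initialised at the first observed
displacement so that a constant displacement is reproduced exactly; the
backward vector is its negation and can be selected for the stage-2 drift.
A learned displacement head could replace this estimator behind the same
interface, but the package is detector-free by design.

The lifespan default of 20 frames reflects the occlusion statistics of
grazing herds, where the large majority of mutual occlusions resolve
within about two seconds of video. Health decays linearly (one point per
frame): the simplest monotone rule consistent with "score decreasing over
time", and the one that makes the recoverable-gap length exactly
$L_0 - 1$ frames. Distance ties resolve to the lower track id, and ties in
confidence keep file order, so the tracker is fully deterministic.

Disabling stage 2 (`tracker$stage2 = FALSE`) terminates unmatched tracks
immediately, which is precisely the greedy baseline the two-stage design
improves on; the test suite checks the direction of that improvement on
seeded occlusion scenarios.

## The IMM particle filter

Ground-plane target state is $x = (X, Y, V_x, V_y)$ in metres (north,
east) with per-model dynamics $x_k = F x_{k-1} + G u_{k-1}$,
$u \sim \mathcal N(0, \sigma_a^2 I_2)$, and position observations
$z_k = H x_k + v_k$, $v \sim \mathcal N(0, \sigma_z^2 I_2)$. The default
model registry holds a nearly-constant-velocity model and two coordinated
turns at $\pm\omega_0$; the registry accepts user models of the same state
dimension. One recursion:

* **Interaction.** Mixing probabilities
  $\mu(i\,|\,j) = p_{ij}\,\mu(i) / b(j)$,
  $b(j) = \sum_i p_{ij}\,\mu(i)$. Each model's particle set is then redrawn
  systematically from the *mixture* of all model clouds with weights
  $\mu(\cdot\,|\,j)$. An alternative reading — replacing every particle by
  the convex combination of its cross-model states — was implemented first
  and rejected on evidence: the combination shrinks the cloud's variance
  by $\sum_i \mu(i|j)^2$ every frame, and the resulting overconfident
  filter measurably diverges on maneuvering targets. The mixture draw
  preserves the mixed distribution and reproduces each cloud exactly under
  an identity transition matrix.
* **Propagation and weighting.** Particles propagate with sampled process
  noise; raw weights are the observation-noise density of the residuals,
  normalised per model. If a model's weights all underflow, they reset to
  uniform and the step is flagged.
* **Resampling.** Systematic, every step, per model; the per-model
  estimate is the mean of the resampled set. (An effective-sample-size
  gate is a config option, off by default.)
* **Model probabilities.** Per model, the pooled covariance $S$ of
  predicted observations about their mean, *plus* the measurement-noise
  covariance $R$; the likelihood is the particle average of
  $\mathcal N(r^l; 0, S)$ on the residuals, and
  $\mu(j) \propto \Lambda(j)\, b(j)$. Including $R$ is deliberate: without
  it $S$ collapses with the process noise, the Gaussian spikes, and model
  probabilities degenerate to 0/1 noise — $S$ here is the sample analogue
  of the classical IMM innovation covariance $HPH^\top + R$. When $S$ is
  still near-singular it is ridged by $10^{-9}\,\mathrm{tr}(S)/d$ (with an
  absolute floor), and a zero overall likelihood leaves $\mu$ unchanged
  with a flag rather than dividing by zero.
* **Fusion.** $\hat x = \sum_m \hat x(m)\, \mu(m)$.

Missing observations (occluded frames, rays above the horizon) coast the
filter: particles propagate, weights and $\mu$ stay put.

Defaults and their reasoning:

| parameter | default | why |
|---|---|---|
| `n_particles` | 500/model | within a few percent of the Kalman optimum in the linear-Gaussian check |
| `self_prob` | 0.9 | ~1 s expected mode dwell at 10 fps |
| `turn_rate` | 0.4 rad/s | matches the simulator's turning mode; presets mirror their scenario value |
| `accel_noise` | 0.4 m/s² | *within-mode* residual acceleration of a walking/grazing animal; mode mismatch is the switching machinery's job, not inflated process noise |
| `jump_frac`, `jump_scale` | 0.05, 8 | heavy-tailed process noise: a small particle fraction draws 8× wider acceleration, so the filter re-acquires after abrupt events outside the model set (e.g. an animal wheeling around); without it a velocity reversal can outrun a tight cloud for hundreds of frames |
| `obs_noise` | 0.25 m | matches the geolocation error budget at 10 m altitude (attitude error ≈ 0.1 m, GPS ≈ 0.15 m, pixel noise ≈ 0.04 m) |
| `init_pos_spread`, `init_vel_spread` | 0.5 m, 1 m/s | particles start around the first observation with unknown velocity |

Each filter instance draws from one seeded RNG stream with draws in fixed
model order, so identical configuration and seed give bit-identical
estimates; per-model sub-streams were considered and dropped as R has no
lightweight independent streams, and determinism — the property the tests
rely on — does not need them. A constant-acceleration registry entry was
also considered and dropped: its 6-dimensional state cannot mix with the
4-dimensional CV/CT states, which share one state space by construction.

## Pixel to ground: frames and conventions

Three right-handed frames: camera **C** (z optical, x image-right, y
image-down), body/IMU **I** (x forward, y right, z down), and local
geographic **L** (north-east-down). At zero gimbal angles the camera looks
forward; the gimbal applies pan about body-z then tilt about the panned
y-axis (tilt −90° is nadir), and the attitude applies intrinsic
yaw–pitch–roll (Z–Y–X). These are the dominant airborne-gimbal
conventions; with all of them at their zero/nadir defaults, image-right
maps east, image-down maps south, and the optical axis maps straight
down, which the tests pin.

A pixel back-projects through the pinhole model to a unit line-of-sight
vector; in **L** its height angle is $\rho = \arccos v_Z$ (0 = straight
down, ground reachable only for $\rho < \pi/2$) and its azimuth
$\varepsilon = \operatorname{atan2}(v_Y, v_X)$ from north. The ground is a
flat plane at a known down-coordinate (pasture assumption; no terrain
model), so the intersection is a one-line scale-and-add; rays at or above
the horizon return an *invalid* point rather than an error, and the filter
coasts through those frames. Lever arms between camera, IMU and GPS
origins are neglected — centimetres against a 10 m altitude — and the
observation handed to the filter is the ground-plane position $(X, Y)$,
which keeps $H$ linear; an angle observation model can be plugged into the
registry instead.

## Evaluation

The CLEAR-MOT protocol is implemented with explicit conventions:

* correspondences persist from the previous frame while their IoU stays at
  or above the gate (0.5 by default);
* remaining boxes are paired by optimal bipartite matching — maximum
  number of pairs, then maximum total IoU — via a Jonker–Volgenant
  assignment solver written for the purpose (no weighted-matching solver
  ships with the available stack) and cross-checked against brute-force
  enumeration;
* identity-switch memory persists across gaps: a re-acquired trajectory
  counts a switch only if its new id differs from the last matched one;
* MOTP is reported on the IoU scale (and printed as a percentage);
* FM counts *interruptions* (tracked→untracked transitions inside a
  trajectory's annotated lifespan), not fragments — definitions vary in
  the literature, so this one is fixed here;
* MT/ML use the usual 80 % / 20 % tracked-fraction thresholds;
* IDF1 comes from a global trajectory-level assignment minimising identity
  mismatches, with per-frame agreement defined by the same IoU gate.

Empty ground truth makes MOTA/IDF1 undefined and raises an error rather
than returning a silent NaN.

## The scenario generator

The simulator produces what the tracker and filter assume, and nothing
more:

* **Targets** follow a first-order Markov chain over straight /
  turn-left / turn-right modes (switch probability 0.05 per frame at
  10 fps), at per-target speeds drawn from 0.5–1.5 m/s, with reflective
  arena boundaries. Footprints are 2.4 m × 0.9 m — adult-cattle scale, so
  boxes are tens of pixels at the default 10 m altitude and 400 px focal
  length, the small-target regime such systems operate in.
* **The UAV** hovers nadir-looking. The *true* pose is constant; the
  *measured* pose adds Gaussian GPS error (0.15 m) and INS attitude error
  (0.01 rad). Rendering projects through the true pose, geolocation
  consumes the measured one — that separation is what makes raw per-frame
  geolocation noisy, exactly as GPS/INS errors do in the field.
* **Ground truth** is the axis-aligned enclosure of the projected
  footprint corners; targets projecting outside the image are omitted.
* **Detections** corrupt ground truth in order: mutual-occlusion dropout
  (IoU above `occ_iou` drops the higher id — a nadir camera has no depth
  ordering, and the deterministic rule keeps scenarios reproducible),
  missed detections (p = 0.02), Gaussian centre noise (1.5 px), log-normal
  size noise, Beta(8,2) scores for true boxes, and Poisson false positives
  (0.1/frame) scored Beta(2,5).

Three presets ship with the package. `separated` (corruption off, parallel
lanes) must reproduce ground truth exactly. `maneuvering` scripts
straight legs alternating with coordinated turns for the filter
comparisons. `crossing` scripts an overtake between two targets on one
lane and solves the overtaking speed so that the occlusion lasts *exactly*
`gap` frames: two equal boxes offset by $s$ along their long axis have
$\mathrm{IoU} = (L - |s|)/(L + |s|)$, so the dropout window is
$|s| < c = L\,(1 - \tau)/(1 + \tau)$, and a step of $d = 2c/g$ with the
grid centred on (odd $g$) or half-step off (even $g$) the closest approach
puts exactly $g$ frames inside it. The crossing preset is fully
deterministic, down to constant detection scores — the occlusion-recovery
property is about the stranding area, and random score orderings would
test greedy tie-breaking instead.

What the simulator does *not* emulate: appearance (no re-identification
features, so nothing here validates appearance-based association), camera
motion over ground (the UAV hovers; camera-motion compensation is out of
scope), terrain relief, lens distortion, and correlated detector failure
modes. Passing tests therefore demonstrate the association, filtering and
geometry layers under honest noise — not detector robustness on real
video.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in about a minute: metric oracle checks on 200
random five-frame instances with up to four objects (small enough for
exhaustive assignment enumeration), tracker comparisons on 20 seeded
80-frame herd scenarios, filter comparisons on 20 seeds of 50–100-step
trajectories with 500–2000 particles per model. All randomness flows from
explicit seeds; scenario generation derives independent sub-seeds for
targets, poses and corruption from one master seed, and seed pools are
drawn up front wherever downstream calls reseed the global stream.

Degenerate inputs are handled explicitly rather than by accident: empty
frames advance the stranding area, empty detection files produce empty
(not invalid) tables, weight and likelihood collapse reset-and-flag, and
near-singular residual covariances are ridged. Known limitations worth
restating: the recoverable occlusion gap is bounded by the lifespan; the
stranding drift is only as good as the frozen motion vector, so targets
that turn *while* occluded may reappear outside the stage-2 gate; and the
flat-ground assumption biases geolocation on sloped terrain by roughly the
slope times the horizontal offset.
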