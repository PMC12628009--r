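---
title: "Replay-based annotation of tracked laparoscopic sessions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replay-based annotation of tracked laparoscopic sessions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surglabels)
```

## The problem and the model

An intraoperative augmented-reality (AR) system for laparoscopy already
maintains everything needed to label the surgery it supports: an infrared
tracker reports the poses of arrays rigidly mounted on the laparoscope, the
operating table and each instrument; hand-eye and pivot calibrations relate
those arrays to the camera's optical frame and the instrument tips; a rigid
patient registration ties preoperative anatomy (segmented meshes) to the
table. If the complete raw record of such a session is kept — transform
streams, calibrations, camera intrinsics, meshes, a video frame clock — the
3D scene can be replayed offline and converted into dense, frame-level
annotations with no manual labelling and no computer vision: semantic label
maps (render each structure with a fixed label id), instrument masks
(including *amodal* masks and instruments entirely outside the camera's
view), tip-to-tissue distance series, and rule-based surgical action
triplets (instrument, verb, target structure).

`surglabels` implements that replay-to-annotation pathway end to end,
together with a synthetic session generator that emulates the recording with
scripted ground truth, so every stage is testable without any recorded data.

The scene is a **coordinate-frame tree**: frames are nodes, and each edge
carries either a static rigid transform (a calibration or registration) or a
timestamped transform stream (a tracked pose). An edge's transform maps
child-frame coordinates into the parent frame; a transform acts on a point
as \(p' = Rp + t\), with rotations stored as unit quaternions
(`(w, x, y, z)`, Hamilton convention, renormalized after every
composition). All lengths are millimetres and all times seconds on a
session-relative clock — one clock for every stream, because mismatched
timestamp conventions are the classic failure mode of replay systems.
The graph is required to be a *tree*: redundant edges would make transform
resolution ambiguous, so they are rejected at load time.

## Replay: resampling and the gap policy

Annotations live on the video frame clock, so tracked poses must be
resampled onto it. A query time that coincides with a valid sample (within
1 ns) returns that sample bit-exactly. Otherwise the bracketing *valid*
samples interpolate the pose — translation linearly, rotation by
shortest-arc slerp — **iff** their spacing is at most `max_gap`
(default 0.2 s, about twelve samples at 60 Hz tracking). Longer gaps mean an
occluded tracking array; interpolating across them would fabricate data, so
those frames are emitted with an explicit `invalid` flag rather than
omitted, keeping the annotation table aligned with the video clock. Beyond
the first/last sample the endpoint pose is held only within half the median
sample interval. A chain through the frame tree is valid exactly when every
dynamic edge on its path is valid; adding a dropout can only turn valid
results invalid, never change a valid pose.

## Calibration chain

Three solvers reproduce the calibrations such a system depends on:

* **Pivot calibration** — poses of a tool pivoting about a fixed point give
  the stacked linear system \([R_i \mid -I]\,[tip; pivot] = -t_i\), solved
  by SVD. The condition number is reported, and values above \(10^6\)
  (all rotations equal or coaxial) are a hard error rather than a silently
  garbage tip offset.
* **Hand-eye calibration** — from paired relative motions satisfying
  \(A_iX = XB_i\) (relative motions avoid the world-frame ambiguity of
  absolute pose pairs). Rotation comes from the stacked linear quaternion
  system \((L(q_{a_i}) - R(q_{b_i}))\,q_x = 0\) via the smallest singular
  vector, translation from least squares of
  \((R_{a_i} - I)\,t_x = R_x t_{b_i} - t_{a_i}\). At least two motion pairs
  with rotation axes separated by \(\ge 5^\circ\) are required.
* **Point registration** — the closed-form SVD (Arun) solution with a sign
  correction on the smallest singular direction, so a mirrored point set can
  never produce a reflection. Used as the rigid stand-in for patient
  registration; the intensity-based 2D–3D registration a real system would
  use is out of scope, and its error is modelled instead as a constant rigid
  perturbation of the patient frame of stated magnitude
  (`perturb_registration()`, e.g. 8.2 mm, the registration error typical of
  such tracked AR setups).

All three recover noiseless synthetic inputs to numerical precision, and
their errors grow monotonically with injected noise — both properties are
enforced by tests against forward-simulation fixtures.

## Rendering

Label and depth maps come from a deterministic software z-buffer
(`src/raster.cpp`). The image convention is fixed: origin top-left, u right,
v down, pixel centres at integer coordinates, coverage when the pixel centre
lies inside the projected triangle with a top-left fill rule for ties —
identical scenes produce byte-identical rasters. The camera is a distorted
pinhole (OpenCV-style radial–tangential coefficients). Distortion is applied
to vertices rather than per-pixel rays; to bound the straight-edge error
this introduces, triangles whose projected edges exceed 16 px are
recursively split at the midpoint of their longest edge before distortion.
Triangles with any vertex nearer than \(z_{near} = 0.1\) mm are clipped.
Depth is camera-\(z\) in mm, perspective-correct (interpolating \(1/z\)),
with 0 encoding "empty"; on disk it is a 16-bit PNG in 0.1 mm units. The
sphere-silhouette test pins rendering accuracy: an on-axis icosphere's
labelled area must match the analytic silhouette area
\(\pi (f r / \sqrt{z^2 - r^2})^2\) within 1 % at 640×480.

Instrument masks are rendered from the shaft mesh if one is supplied, else
from a capsule of `tool_radius` around the tip-to-array segment truncated at
`shaft_length` (the physical shaft runs from the tip toward the tracked
array). `amodal = TRUE` ignores anatomy occlusion — the full silhouette,
something pixel-based annotation cannot produce; `amodal = FALSE` removes
pixels where the anatomy depth is nearer by more than 1 mm. Anatomy and
instrument rasters are kept separate, so both occlusion-resolved and
combined views can be derived. Pseudo-chromadepth maps depth linearly onto
the HSV hue ramp red (near) → green → blue (far), clamped to
\([z_{min}, z_{max}]\), background black.

## Event rules

The closeness metric is the unsigned distance from the **tip point** to each
anatomy mesh — not the full shaft — matching how such demonstrators pick
"the tissue closest to the instrument tips". Distances are computed on every
frame for every instrument regardless of camera visibility; off-screen
interactions are annotated identically to on-screen ones.

Per frame and instrument, the target is the structure at minimal distance
(exact ties broken by `structure_priority`, then name order). Contact uses
hysteresis: it begins below `tau_enter` (3 mm) and persists until the
distance exceeds `tau_exit` (5 mm). Beyond `tau_far` (20 mm) the instrument
has no target and is idle. The verb is a lookup in a per-archetype table by
(contact?, speed class), with speed classes split at `s_static` = 2 mm/s and
`s_active` = 8 mm/s; non-contact states always map to `idle`, so only
genuine proximity produces events. Confidence is
\(\max(0, 1 - d/\tau_{enter})\) in contact. Runs of identical
(instrument, verb, target) become events; identical events separated by at
most `merge_gap` (0.2 s) merge — regardless of what lies in the gap, which
is what rescues a long interaction from a two-frame flicker; events shorter
than `min_duration` (0.5 s) are dropped.

Two numerical choices matter under realistic tracking noise, and both were
made as design decisions rather than left to chance:

* **Velocity estimation window.** Tip speed is the norm of a local
  least-squares linear fit of position over `kinematics_window` frames. At
  30 fps with 1 mm tracking jitter, a 5-frame window yields ~10 mm/s of
  speed noise — the 2 and 8 mm/s class boundaries would be decided by noise.
  The default window is therefore 15 frames (0.5 s), matching
  `min_duration`: speed is resolved at the same timescale as the events it
  drives, and the residual noise (~2 mm/s) leaves the `s_active` boundary
  three standard deviations away for a stationary tip.
* **Smoothed closeness for the contact decision.** The hysteresis thresholds
  are compared against a running median of the minimum distance over the
  same window (raw distances are still what the records report). A median
  leaves a noiseless monotone approach and a constant dwell untouched, so
  clean data is unaffected; under jitter it stops the first noise spike from
  opening or closing a contact a second early or late.

A known limitation is inherited deliberately: a tool merely *resting* on
tissue is labelled as interacting. Proximity, direction and speed cannot
distinguish passive contact from active engagement; that would require
instrument state signals (e.g. energy activation) or force sensing, which
the rule model does not claim to provide.

## The synthetic world

`generate_session()` emulates a recorded session with a fully scripted,
analytically known world — the stand-in for preclinical recordings:

* **Scene** (patient frame, mm): a gallbladder-like icosphere (r = 12 at the
  origin), a liver-like icosphere (r = 20 at (45, 20, 0)) and a ureter-like
  capped tube (r = 4, length 70, at (−110, 0, 0)). Icospheres use
  subdivision 4 (5120 faces); their chord (sagitta) tolerance, computed from
  the actual mesh, is what distance oracles use.
* **Camera**: a laparoscope 150 mm from the scene centre on a gentle
  ±8° arc (period = session length), fx = fy = 800 px at 640×480 (tests run
  at this size; FullHD output is a flag away). The demo camera is
  distortion-free so the silhouette and off-screen geometry stay analytic;
  distortion is exercised separately in unit tests.
* **Tracking**: 60 Hz streams for scope, table and instrument arrays,
  composed through fixed "true" calibrations (hand-eye, tip offsets of
  (0, 0, 150) mm, table-to-patient registration). The video clock runs at
  30 fps.
* **Scripts**: two instruments (a grasper and scissors) execute six contact
  events, purely radial against their target: fast approach from a 25 mm
  standoff to 3.5 mm (2 s), creep-in at 1 mm/s to a 1.5 mm dwell clearance
  (held 3 s), creep-out at 1.5 mm/s to 5.5 mm, fast retreat. The margins are
  the stated world: dwell below `tau_enter` − 1 mm, outside-event distance
  above `tau_exit` + 2 mm, and in-contact speeds below `s_static`. One
  grasper event targets the ureter tube, which lies entirely outside the
  camera frustum throughout — the out-of-view interaction case that makes
  replay-based annotation more than a segmentation trick.
* **Noise** (all default 0): Gaussian jitter on stream translations
  (`jitter_sigma_t`, mm) and rotations (`jitter_sigma_r`, deg), Bernoulli
  per-sample dropouts, and a constant rigid registration offset in a seeded
  random direction. Each consumer draws from its own seeded substream
  (jitter: seed+1, dropouts: seed+2, registration direction: seed+3), so
  toggling one noise source never changes another.

Ground-truth events are derived from the *analytic* distance profile with
the same hysteresis the rule engine applies — independent of meshes,
rasterization and the transform chain — so pipeline closure (precision =
recall = 1 on the noiseless demo) is a genuine end-to-end check, not a
self-comparison.

What the generator does **not** emulate: tissue deformation (anatomy is
rigid in the patient frame), instrument articulation, shaft–tissue contact,
video pixels, and correlated tracking error (jitter is white). A green test
therefore establishes that the *geometry and rule pipeline* is correct under
the stated noise model; it says nothing about deformable registration error
or about how well proximity rules capture surgical semantics on real tissue.

## Determinism and formats

Sessions are plain inspectable files: a JSON manifest, CSV transform streams
(`t,qw,qx,qy,qz,tx,ty,tz,valid`), binary little-endian PLY meshes (doubles,
lossless), a CSV frame clock. Writing uses fixed key order and fixed
9-significant-digit float formatting, so writing the same session twice is
byte-identical. Rasters are PNGs written by a small built-in zlib codec with
a fixed filter and compression level — identical scenes give byte-identical
files, which is what makes the end-to-end pipeline reproducibility test
meaningful. Video pixels are never stored: the frame clock plus the camera
model fully determine every annotation raster.

## Known limitations

* Rigid anatomy only; deformable registration is out of scope.
* The rule vocabulary ships four archetypes (grasper, scissors, hook,
  stapler) and is deliberately small; it is configuration, not a claim about
  surgical taxonomy.
* Triplets are inferred per instrument independently — no bimanual compound
  verbs.
* Containment (`point_in_mesh`) requires watertight meshes; open anatomy
  meshes get unsigned distances only, which is why distance and containment
  are separate predicates throughout.
* The `surglabels score` matcher is greedy by interval IoU among
  label-identical pairs; it is an evaluation harness, not an optimal
  assignment.
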